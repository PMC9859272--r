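# domain_coords: coordinate conventions, paralog position table,
# segregation profile.

sox18 <- domain_annotation("SOX18", "HMG", 85, 163)
sox4 <- domain_annotation("SOX4", "HMG", 59, 137)

test_that("protein-to-domain mapping follows the zero-free convention", {
  expect_equal(to_domain_position(137, sox18), 53)
  expect_equal(to_domain_position(58, sox4), -1)
  expect_equal(to_domain_position(59, sox4), 1)
  expect_equal(to_domain_position(85, sox18), 1)
  expect_error(to_domain_position(0, sox18), ">= 1")
})

test_that("from_domain_position inverts the mapping and rejects zero", {
  expect_equal(from_domain_position(53, sox18), 137)
  expect_equal(from_domain_position(1, sox4), 59)
  expect_equal(from_domain_position(-1, sox4), 58)
  expect_error(from_domain_position(0, sox18), "0")
})

test_that("round-trip is the identity over a random grid, never zero", {
  set.seed(13)
  starts <- sample.int(1000L, 40L)
  pos <- sample.int(10000L, 500L)
  for (s in starts) {
    a <- domain_annotation("g", "d", s, s + 50L)
    d <- to_domain_position(pos, a)
    expect_true(all(d != 0L))
    expect_identical(from_domain_position(d, a), pos)
  }
})

test_that("alternate numbering offsets by 2 and skips zero from below", {
  expect_equal(to_alternate_numbering(53), 55)
  expect_equal(to_alternate_numbering(56), 58)
  expect_message(v <- to_alternate_numbering(-1), "zero skipped")
  expect_equal(v, 2)
  expect_silent(expect_equal(to_alternate_numbering(-5), -3))
  expect_error(to_alternate_numbering(0), "0")
})

test_that("paralog table counts amino-acid usage across the family", {
  # 4 identical domains: usage 1 everywhere covered
  prots <- stats::setNames(rep(paste0("MM", "RKWAQ", "NN"), 4L),
                           paste0("g", 1:4))
  anns <- lapply(names(prots), function(g)
    domain_annotation(g, "d", 3L, 7L, protein_length = 9L))
  names(anns) <- names(prots)
  tab <- build_paralog_table(prots, anns, flank_up = 2L, flank_down = 2L)
  expect_true(all(tab$positions$aa_used == 1L))
  expect_false(any(tab$positions$domain_pos == 0L))
  expect_true(all(tab$positions$n_paralogs == 4L))

  # inject variability at domain position 2
  prots2 <- prots
  substr(prots2["g2"], 4, 4) <- "E"
  substr(prots2["g3"], 4, 4) <- "D"
  tab2 <- build_paralog_table(prots2, anns, flank_up = 0L, flank_down = 0L)
  row <- tab2$positions[tab2$positions$domain_pos == 2L, ]
  expect_equal(row$aa_used, 3L)
  expect_equal(row$aa_set, "DEK")
})

test_that("paralog usage counts match a brute-force oracle on random input", {
  set.seed(29)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_genes <- 6L
  plen <- 40L
  prots <- stats::setNames(
    vapply(seq_len(n_genes), function(i)
      paste(sample(aas, plen, replace = TRUE), collapse = ""),
      character(1)),
    paste0("g", seq_len(n_genes)))
  starts <- stats::setNames(sample(5:20, n_genes, replace = TRUE),
                            names(prots))
  anns <- lapply(names(prots), function(g)
    domain_annotation(g, "d", starts[[g]], starts[[g]] + 9L,
                      protein_length = plen))
  names(anns) <- names(prots)
  tab <- build_paralog_table(prots, anns, flank_up = 4L, flank_down = 6L)
  for (i in seq_len(nrow(tab$positions))) {
    dp <- tab$positions$domain_pos[i]
    residues <- character(0)
    for (g in names(prots)) {
      pp <- if (dp > 0) starts[[g]] + dp - 1L else starts[[g]] + dp
      if (pp >= 1L && pp <= plen) {
        residues <- c(residues, substring(prots[[g]], pp, pp))
      }
    }
    expect_equal(tab$positions$aa_used[i], length(unique(residues)))
    expect_lte(tab$positions$aa_used[i], n_genes)
    expect_gte(tab$positions$n_paralogs[i], 1L)
  }
})

test_that("paralog table uses each gene's own conservation score", {
  prots <- c(g1 = "AKW", g2 = "AKW")
  anns <- list(g1 = domain_annotation("g1", "d", 1L, 3L),
               g2 = domain_annotation("g2", "d", 1L, 3L))
  profs <- list(
    g1 = data.frame(codon_index = 1:3, score = c(2, 1, 0)),
    g2 = data.frame(codon_index = 1:3, score = c(1, 1, 1)))
  tab <- build_paralog_table(prots, anns, profs, flank_up = 0L,
                             flank_down = 0L)
  expect_equal(tab$positions$cons_mean, c(1.5, 1, 0.5))
  expect_equal(tab$positions$cons_sd,
               c(stats::sd(c(2, 1)), 0, stats::sd(c(0, 1))))
})

test_that("domain length mismatch across paralogs is an error", {
  prots <- c(g1 = "AKWAA", g2 = "AKWAA")
  anns <- list(g1 = domain_annotation("g1", "d", 1L, 3L),
               g2 = domain_annotation("g2", "d", 1L, 4L))
  expect_error(build_paralog_table(prots, anns), "length differs")
})

test_that("segregation profile signs follow residue identity", {
  score <- c(2, 1, 1, 0.5, 1.5)
  focal <- "AKWDE"
  same <- c(sib1 = "AKWDE")
  diff <- c(sib1 = "GGGGG")
  prof_same <- segregation_profile(focal, same, score)
  expect_equal(prof_same$sib1, score)
  expect_equal(prof_same$additive, score)
  prof_diff <- segregation_profile(focal, diff, score)
  expect_equal(prof_diff$sib1, -score)

  # mixed hand computation with two siblings
  sibs <- c(a = "AKGDE", b = "GKWDG")
  prof <- segregation_profile(focal, sibs, score)
  expect_equal(prof$a, c(2, 1, -1, 0.5, 1.5))
  expect_equal(prof$b, c(-2, 1, 1, 0.5, -1.5))
  expect_equal(prof$additive, prof$a + prof$b)

  expect_error(segregation_profile(focal, c(x = "AK"), score), "equal length")
})
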