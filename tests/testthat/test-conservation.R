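# conservation_core: filtering, per-column counts, dN-dS signal, score,
# window, normalization.

test_that("filter_sequences applies the ambiguity and missing-data rules", {
  clean <- strrep("ACGTGA", 5L) # 30 nt
  seqs <- stats::setNames(rep(clean, 5L), c("hum", paste0("s", 1:4)))
  res <- filter_sequences(seqs, "hum")
  expect_length(res$kept, 5L)
  expect_equal(nrow(res$rejections), 0L)

  seqs["s2"] <- paste0(substr(clean, 1, 10), "N", substr(clean, 12, 30))
  res <- filter_sequences(seqs, "hum")
  expect_setequal(names(res$kept), c("hum", "s1", "s3", "s4"))
  expect_equal(res$rejections$id, "s2")
  expect_equal(res$rejections$rule, "ambiguity")

  # reference failing a rule is a hard error, not a removal
  bad <- seqs
  bad["hum"] <- seqs[["s2"]]
  expect_error(filter_sequences(bad, "hum"), "ambiguity")
})

test_that("missing-data rule depends on column occupancy", {
  clean <- strrep("ACGTGACGTGACGTGACGTGACGTGACGTG", 1L) # 30 nt
  gapped <- paste0(strrep("-", 12L), substr(clean, 13, 30))

  # case A: 19/20 sequences occupy columns 1-12 (occupancy 0.95 > 0.9)
  seqs_a <- stats::setNames(c(rep(clean, 19L), gapped),
                            c("hum", paste0("s", 1:19)))
  occ_a <- colMeans(do.call(rbind, strsplit(seqs_a, "")) != "-")
  expect_true(all(occ_a[1:12] > 0.9)) # independent occupancy check
  res_a <- filter_sequences(seqs_a, "hum")
  expect_equal(res_a$rejections$id, "s19")
  expect_equal(res_a$rejections$rule, "missing_dense_columns")

  # case B: 10/20 gapped at the same columns (occupancy 0.5): all kept
  seqs_b <- stats::setNames(c(rep(clean, 10L), rep(gapped, 10L)),
                            c("hum", paste0("s", 1:19)))
  occ_b <- colMeans(do.call(rbind, strsplit(seqs_b, "")) != "-")
  expect_true(all(occ_b[1:12] <= 0.9))
  res_b <- filter_sequences(seqs_b, "hum")
  expect_length(res_b$kept, 20L)

  # boundary: exactly 9 missing nucleotides at dense columns is tolerated
  gap9 <- paste0(strrep("-", 9L), substr(clean, 10, 30))
  seqs_c <- stats::setNames(c(rep(clean, 19L), gap9),
                            c("hum", paste0("s", 1:19)))
  expect_length(filter_sequences(seqs_c, "hum")$kept, 20L)
})

test_that("column substitution counts classify syn/nonsyn against the reference", {
  # ref GCT (A); identical, synonymous GCC (A), nonsynonymous GTT (V)
  aln <- toy_alignment(c("GCT", "ATG"), c("GCT", "ATG"), c("GCC", "ATG"),
                       c("GTT", "ATG"))
  got <- column_substitution_counts(aln, 1L)
  expect_equal(got$s, 1L)
  expect_equal(got$n, 1L)
  expect_equal(got$aa_match_fraction, 2 / 3)
  expect_equal(got$n_compared, 3L)

  # invariant column
  got2 <- column_substitution_counts(aln, 2L)
  expect_equal(c(got2$s, got2$n), c(0L, 0L))
  expect_equal(got2$aa_match_fraction, 1)

  expect_error(column_substitution_counts(aln, 3L), "out of range")
})

test_that("single-codon amino acids (M, W) can never show synonymous change", {
  # reference ATG: every differing codon is nonsynonymous
  aln <- toy_alignment(c("ATG"), c("ATA"), c("ACG"), c("ATG"))
  got <- column_substitution_counts(aln, 1L)
  expect_equal(got$s, 0L)
  expect_equal(got$n, 2L)
})

test_that("gapped and ambiguous codons are excluded from the denominator", {
  aln <- toy_alignment(c("GCT", "AAA"), c("---", "AAA"), c("GCN", "AAA"),
                       c("GCC", "AAA"))
  got <- column_substitution_counts(aln, 1L)
  expect_equal(got$n_compared, 1L)
  expect_equal(got$s, 1L)
})

test_that("codon_site_counts matches an independent neighbor enumeration", {
  # enumeration oracle: per-position fraction of non-stop single-nt
  # changes that are synonymous
  oracle <- function(codon) {
    code <- stats::setNames(as.character(Biostrings::GENETIC_CODE),
                            names(Biostrings::GENETIC_CODE))
    chars <- strsplit(codon, "")[[1]]
    s <- 0; n <- 0
    for (p in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), chars[p])
      aa <- vapply(alts, function(b) {
        x <- chars; x[p] <- b; unname(code[paste(x, collapse = "")])
      }, character(1))
      keep <- aa != "*"
      if (!any(keep)) next
      s <- s + sum(aa[keep] == code[[codon]]) / sum(keep)
      n <- n + sum(aa[keep] != code[[codon]]) / sum(keep)
    }
    c(s_sites = s, n_sites = n)
  }
  for (cdn in c("GCT", "ATG", "TGG", "TTA", "CGA", "AGA", "TAT")) {
    expected <- oracle(cdn)
    got <- codon_site_counts(cdn)
    expect_equal(got$s_sites, unname(expected["s_sites"]), info = cdn)
    expect_equal(got$n_sites, unname(expected["n_sites"]), info = cdn)
  }
  # four-fold degenerate third position, no stop neighbors
  gct <- codon_site_counts("GCT")
  expect_equal(gct$s_sites, 1)
  expect_equal(gct$n_sites, 2)
  expect_error(codon_site_counts("TAA"), "sense")
})

test_that("dN-dS z-scores are negative for synonymous-only codons in a
           nonsynonymous background", {
  set.seed(42)
  # codon 1: ref GCT with only synonymous variation; codons 2-6:
  # nonsynonymous variation
  ref <- c("GCT", "AAA", "CCC", "GGG", "TTT", "CAA")
  make_seq <- function() {
    c(sample(c("GCC", "GCA", "GCG"), 1L),
      vapply(ref[-1], function(cdn) {
        nb <- setdiff(sense_codons(), cdn)
        aa <- codon_to_aa(nb)
        nb[aa != codon_to_aa(cdn)][1L]
      }, character(1)))
  }
  aln <- toy_alignment(ref, make_seq(), make_seq(), make_seq(), make_seq())
  prof <- gene_dnds_profile(aln)
  expect_lt(prof$dnds_z[1L], 0)
  expect_true(all(prof$dnds_z[-1L] > prof$dnds_z[1L]))

  # fully invariant gene: zero variance path
  inv <- toy_alignment(ref, ref, ref, ref)
  expect_warning(prof0 <- gene_dnds_profile(inv), "zero variance")
  expect_equal(prof0$dnds_z, rep(0, length(ref)))
})

test_that("conservation_score follows the quantized rubric", {
  expect_equal(conservation_score(0, 0.5, 0), 0)
  expect_equal(conservation_score(0, 1.0, 0), 1)
  expect_equal(conservation_score(20, 1.0, -2.5), 2)
  expect_equal(conservation_score(5, 0.95, 0), 1.25)
  expect_equal(conservation_score(15, 0.95, -1), 1.75)
  # boundary: 0.90 match earns the base point
  expect_equal(conservation_score(0, 0.9, 0), 1)
  # NA dN-dS contributes nothing
  expect_equal(conservation_score(15, 0.95, NA), 1.5)
  # quantization and cap
  scores <- conservation_score(c(0, 4, 5, 14, 15, 100), 1, -3)
  expect_true(all(scores %in% seq(0, 2, by = 0.25)))
  expect_equal(max(scores), 2)
})

test_that("conservation_score is monotone in s and in -dnds_z", {
  set.seed(7)
  for (i in 1:50) {
    aa <- stats::runif(1)
    z <- stats::rnorm(1)
    s <- sample(0:30, 2L)
    s <- sort(s)
    expect_lte(conservation_score(s[1], aa, z),
               conservation_score(s[2], aa, z))
    zz <- sort(stats::rnorm(2))
    s1 <- sample(0:30, 1L)
    expect_gte(conservation_score(s1, aa, zz[1]),
               conservation_score(s1, aa, zz[2]))
  }
})

test_that("sliding window sums truncate at the termini", {
  const <- rep(1, 50)
  w <- sliding_window(const)
  expect_equal(w[25], 21)
  expect_equal(w[1], 11)
  expect_equal(w[50], 11)
  expect_equal(w, window_oracle(const))
})

test_that("normalization maps the maximum window to 1", {
  set.seed(11)
  w <- sliding_window(sample(seq(0, 2, 0.25), 40, replace = TRUE))
  nw <- normalize_profile(w)
  expect_equal(max(nw), 1)
  expect_true(all(nw >= 0 & nw <= 1))
  expect_warning(z <- normalize_profile(rep(0, 5)), "zero")
  expect_equal(z, rep(0, 5))
})

test_that("conservation_profile assembles all columns coherently", {
  cfg <- small_sim_config(seed = 5L)
  sim <- simulate_orthologs(cfg)
  prof <- conservation_profile(sim$alignments[[1L]])
  expect_equal(nrow(prof), cfg$protein_length)
  expect_equal(prof$window_sum, window_oracle(prof$score))
  expect_equal(prof$normalized_window, prof$window_sum / max(prof$window_sum))
  expect_true(all(prof$score %in% seq(0, 2, 0.25)))
  expect_true(all(prof$s + prof$n <= cfg$species_per_gene - 1L))
})
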