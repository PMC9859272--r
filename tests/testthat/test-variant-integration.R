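# variant_integration: readers, site aggregation, overlap partition,
# enrichment.

test_that("p.-style protein notation parses including multi-alt", {
  p <- parse_protein_change(c("E137K", "M112V/R/T/I", "garbage", "H58P"))
  expect_equal(p$protein_pos, c(137L, 112L, NA, 58L))
  expect_equal(p$ref_aa, c("E", "M", NA, "H"))
  expect_equal(p$alt_aa, c("K", "V", NA, "P"))
  expect_equal(p$n_alt, c(1L, 4L, NA, 1L))
})

test_that("read_variants_tsv enforces schemas and rejects bad rows", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.tsv")
  writeLines(c("gene\tvariant\tallele_count",
               "SOX18\tE137K\t274",
               "SOX18\tE137E\t5",       # ref == alt
               "SOX18\tnota-var\t1"),   # unparseable
             p)
  rec <- read_variants_tsv(p, "gnomad")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$protein_pos, 137L)
  expect_equal(rec$allele_count, 274)
  rej <- attr(rec, "rejections")
  expect_equal(rej$line, c(3L, 4L))
  expect_setequal(rej$reason, c("ref_aa == alt_aa",
                                "unparseable protein change"))

  # empty table with header
  p2 <- file.path(d, "empty.tsv")
  writeLines("gene\tprotein_pos\tref_aa\talt_aa\tsignificance", p2)
  expect_equal(nrow(read_variants_tsv(p2, "clinvar")), 0L)

  # missing mandatory schema column
  p3 <- file.path(d, "bad.tsv")
  writeLines("gene\tvariant", p3)
  expect_error(read_variants_tsv(p3, "geno2mp"), "cadd")
  expect_error(read_variants_tsv(p, "nonsense"))
})

test_that("annotate_sites groups records per residue with domain context", {
  ann <- list(SOX18 = domain_annotation("SOX18", "HMG", 85, 163,
                                        protein_length = 384))
  prof <- list(SOX18 = data.frame(codon_index = 1:200,
                                  score = rep(c(0, 2), 100),
                                  window_sum = seq(1, 200)))
  rec <- bind_variant_records(
    toy_records("SOX18", 137, "gnomad", allele_count = 274),
    toy_records("SOX18", 137, "geno2mp", cadd = 28.6,
                hpo_profile_count = 16),
    toy_records("SOX18", 10, "clinvar", ref = "A", alt = "T"))
  sm <- annotate_sites(rec, ann, prof)
  expect_equal(nrow(sm), 2L)
  s137 <- sm[sm$protein_pos == 137, ]
  expect_equal(s137$sources, "geno2mp+gnomad")
  expect_true(s137$in_domain)
  expect_equal(s137$domain_pos, 53L)
  expect_equal(s137$max_cadd, 28.6)
  expect_equal(s137$allele_count, 274)
  expect_equal(s137$hpo_profiles, 16)
  s10 <- sm[sm$protein_pos == 10, ]
  expect_false(s10$in_domain)
  expect_equal(s10$domain_pos, -75L)
  expect_equal(s10$score, 2)

  # missing annotation/profile warns and yields NA context
  w <- capture_warnings(sm2 <- annotate_sites(toy_records("SOX1", 5, "gnomad",
                                                          allele_count = 1)))
  expect_match(w, "no domain annotation", all = FALSE)
  expect_match(w, "no conservation profile", all = FALSE)
  expect_true(is.na(sm2$in_domain))
})

test_that("distinct alternate alleles are tracked per source", {
  rec <- bind_variant_records(
    toy_records("G", 10, "clinvar", alt = "K"),
    toy_records("G", 10, "clinvar", alt = "Q"),
    toy_records("G", 10, "gnomad", alt = "K", allele_count = 2))
  sm <- suppressWarnings(annotate_sites(rec))
  expect_equal(sm$n_alt, 2L)
  expect_equal(sm$n_alt_clinvar, 2L)
  expect_equal(sm$n_alt_gnomad, 1L)
})

test_that("overlap categories partition the sites", {
  set.seed(5)
  genes <- paste0("g", 1:4)
  rec <- do.call(bind_variant_records, lapply(1:200, function(i) {
    toy_records(sample(genes, 1L), sample.int(50L, 1L),
                sample(c("gnomad", "clinvar", "geno2mp"), 1L))
  }))
  sm <- suppressWarnings(annotate_sites(rec))
  cats <- overlap_categories(sm)
  expect_equal(sum(cats$n_sites), nrow(sm))
  # brute-force partition oracle
  key <- paste(sm$gene, sm$protein_pos)
  expect_equal(anyDuplicated(key), 0L)
  oracle <- table(sm$sources)
  expect_setequal(cats$category, names(oracle))
  expect_equal(cats$n_sites[match(names(oracle), cats$category)],
               as.integer(oracle))
  # single-source records give singleton categories
  rec1 <- toy_records(c("a", "b"), c(1, 2), "gnomad", allele_count = 1)
  sm1 <- suppressWarnings(annotate_sites(rec1))
  expect_equal(overlap_categories(sm1)$category, "gnomad")
})

test_that("enrichment follows its definition and a counting oracle", {
  ann <- domain_annotation("g", "d", 21, 40, protein_length = 100)
  # proportional placement: 20% of variants inside a 20%-length domain
  rec <- toy_records("g", c(25, 30, 35, 38, 1:16), "gnomad",
                     allele_count = 1)
  expect_equal(hmg_enrichment(rec, "g", "gnomad", ann), 1.0)
  # all inside a 20% domain
  rec2 <- toy_records("g", c(21, 25, 40), "gnomad", allele_count = 1)
  expect_equal(hmg_enrichment(rec2, "g", "gnomad", ann), 5.0)
  # no variants: missing, not zero
  expect_true(is.na(hmg_enrichment(rec2, "g", "cosmic", ann)))

  # random placement vs direct counting; duplication invariance
  set.seed(31)
  for (i in 1:20) {
    pos <- sample.int(100L, sample(3:30, 1L), replace = TRUE)
    r <- toy_records("g", pos, "cosmic", tissue = "t", histology = "h")
    expected <- (mean(pos >= 21 & pos <= 40)) / 0.2
    expect_equal(hmg_enrichment(r, "g", "cosmic", ann), expected)
    expect_equal(hmg_enrichment(rbind(r, r), "g", "cosmic", ann), expected)
  }
})
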