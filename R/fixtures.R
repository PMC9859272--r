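# Packaged curated reference tables.
#
# Four small TSVs ship with the package, transcribed from published curated
# summaries of SOX-family variant annotation:
#   table1 - literature-curated disease variants (clinical channel);
#   table3 - ClinVar variants within the HMG box, in the dual domain
#            numbering, with cross-paralog amino-acid usage and per-variant
#            synonymous/nonsynonymous counts and conservation scores;
#   table4 - Geno2MP variants within the HMG box with CADD, phenotype
#            profiles, and conservation scores;
#   table5 - high-ranking variants outside the HMG box with selection
#            scores and 21-codon window sums.
# They serve as worked-example inputs: the prioritization rules recompute
# the published headline counts from them.

.ov_fixture_names <- c("table1", "table3", "table4", "table5")

#' Load a packaged curated reference table
#'
#' @param name One of `"table1"`, `"table3"`, `"table4"`, `"table5"`.
#' @return The parsed, schema-validated data frame. `table3` gains derived
#'   columns `gene`, `ref_aa`, `protein_pos`, `alt_aa`, `alts`, `n_alt`
#'   parsed from its variant notation; `table4` and `table5` likewise gain
#'   parsed variant fields.
#' @export
load_fixture <- function(name) {
  if (!name %in% .ov_fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.ov_fixture_names, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "orthovar")
  if (!nzchar(path)) stop("fixture file missing from installation: ", name)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)

  check <- function(cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("fixture ", name, " lacks column(s): ", paste(miss, collapse = ", "))
    }
  }
  if (name == "table1") {
    check(c("hmg_box_aa", "protein_pos", "ref_aa", "alt_aa", "gene",
            "disease"))
    df$domain_pos <- suppressWarnings(
      as.integer(sub("/.*$", "", df$hmg_box_aa)))
  } else if (name == "table3") {
    check(c("uniprot_pos", "bk_pos", "aa_used", "aa_set", "cons_mean",
            "cons_sd", "gene", "variant", "syn", "nonsyn", "score"))
    parsed <- parse_protein_change(df$variant)
    df <- cbind(df, parsed[c("ref_aa", "protein_pos", "alt_aa", "alts",
                             "n_alt")])
  } else if (name == "table4") {
    check(c("gene", "variant", "hmg_pos", "clinvar_genes_n", "phenotype",
            "hpo_profiles", "cadd", "gnomad_count", "syn", "nonsyn",
            "score"))
    parsed <- parse_protein_change(df$variant)
    df <- cbind(df, parsed[c("ref_aa", "protein_pos", "alt_aa")])
  } else if (name == "table5") {
    check(c("gene", "codon", "ref_aa", "variant", "phenotype", "syn",
            "nonsyn", "score", "window21", "aa_conservation"))
    parsed <- parse_protein_change(df$variant)
    df$protein_pos <- parsed$protein_pos
    df$alt_aa <- parsed$alt_aa
  }
  df
}

#' Clinical variant sites in domain coordinates from the curated table
#'
#' Reshapes the in-domain ClinVar fixture (`table3`) into the
#' clinical-site table consumed by [cross_paralog_clinvar_positions()]:
#' one row per (gene, domain position) with the number of distinct
#' alternate alleles.
#'
#' @return Data frame with `gene`, `domain_pos`, `n_alt`, `score`.
#' @export
fixture_clinical_sites <- function() {
  t3 <- load_fixture("table3")
  data.frame(gene = t3$gene, domain_pos = t3$uniprot_pos, n_alt = t3$n_alt,
             score = t3$score, stringsAsFactors = FALSE)
}

#' Geno2MP in-domain sites from the curated table
#'
#' Reshapes the in-domain Geno2MP fixture (`table4`) into the site table
#' consumed by [filter_geno2mp_hmg()].
#'
#' @return Data frame with `gene`, `protein_pos`, `domain_pos`,
#'   `in_domain`, `cadd`, `score`, `hpo_profiles`, `phenotype`.
#' @export
fixture_geno2mp_sites <- function() {
  t4 <- load_fixture("table4")
  data.frame(gene = t4$gene, protein_pos = t4$protein_pos,
             domain_pos = t4$hmg_pos, in_domain = TRUE,
             cadd = t4$cadd, score = t4$score,
             hpo_profiles = t4$hpo_profiles, phenotype = t4$phenotype,
             stringsAsFactors = FALSE)
}

#' Outside-domain sites from the curated table
#'
#' Reshapes the outside-domain fixture (`table5`) into the site table
#' consumed by [prioritize_outside_domain()]. A row's sources are taken
#' from its populated columns: a clinical phenotype annotation implies the
#' clinical channel, a positive population count implies gnomad, and a
#' phenotype-profile variant implies geno2mp.
#'
#' @return Data frame with `gene`, `protein_pos`, `in_domain`, `score`,
#'   `window_sum`, `sources`, `cadd`.
#' @export
fixture_outside_sites <- function() {
  t5 <- load_fixture("table5")
  gnomad_n <- suppressWarnings(as.numeric(t5$gnomad_count))
  sources <- mapply(function(pheno, gn, g2m) {
    src <- character(0)
    if (!is.na(pheno) && nzchar(trimws(pheno))) src <- c(src, "clinvar")
    if (!is.na(gn) && gn > 0) src <- c(src, "gnomad")
    if (!is.na(g2m) && nzchar(trimws(g2m))) src <- c(src, "geno2mp")
    paste(sort(src), collapse = "+")
  }, t5$phenotype, gnomad_n, t5$geno2mp_var, USE.NAMES = FALSE)
  data.frame(gene = t5$gene, protein_pos = t5$protein_pos,
             in_domain = FALSE, score = t5$score, window_sum = t5$window21,
             sources = sources,
             cadd = suppressWarnings(as.numeric(t5$cadd)),
             stringsAsFactors = FALSE)
}

#' Headline counts from the curated reference tables
#'
#' Recomputes, from the packaged fixtures alone, the four headline numbers
#' of the family-wide analysis: domain positions with clinical variants in
#' two or more paralogs, domain positions with multiple distinct changes
#' within one gene, Geno2MP in-domain variants passing the CADD/selection
#' filter, and outside-domain variants passing the conserved-context rule.
#'
#' @param cadd_min,score_min,window_min Rule thresholds (defaults 20, 1,
#'   10).
#' @return Named list: `n_multi_paralog`, `n_multi_change`, `n_geno2mp`,
#'   `n_outside`, plus the underlying result objects `cross_paralog`,
#'   `geno2mp_calls`, `outside_calls`.
#' @export
fixture_report <- function(cadd_min = 20, score_min = 1, window_min = 10) {
  cp <- cross_paralog_clinvar_positions(fixture_clinical_sites())
  g2m <- filter_geno2mp_hmg(fixture_geno2mp_sites(), cadd_min = cadd_min,
                            score_min = score_min,
                            clinvar_positions = cp$position_genes)
  out <- prioritize_outside_domain(fixture_outside_sites(),
                                   score_min = score_min,
                                   window_min = window_min)
  list(n_multi_paralog = cp$n_multi_paralog,
       n_multi_change = cp$n_multi_change,
       n_geno2mp = nrow(g2m),
       n_outside = nrow(out),
       cross_paralog = cp, geno2mp_calls = g2m, outside_calls = out)
}
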