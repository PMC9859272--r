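# Variant prioritization rules.
#
# Four rules transfer or combine evidence across the family:
#   cross_paralog_clinvar  - domain positions where two or more paralogs
#                            carry clinical (ClinVar or literature) variants,
#                            and sites with multiple distinct changes in one
#                            gene;
#   geno2mp_hmg_filter     - in-domain phenotype-profile variants passing a
#                            CADD and conservation-score filter;
#   outside_domain_conserved - variants outside the domain at conserved
#                            residues within a conserved 21-codon context;
#   cosmic_at_clinical_site - somatic variants restricted to domain
#                            positions with clinical evidence, summarized by
#                            tissue and histology.

# Clinical sources feeding the cross-paralog evidence channel.
.ov_clinical_sources <- c("clinvar", "literature")

.ov_has_source <- function(sources, wanted) {
  vapply(strsplit(sources, "+", fixed = TRUE),
         function(s) any(s %in% wanted), logical(1))
}

#' Cross-paralog clinical evidence at domain positions
#'
#' From clinical (ClinVar/literature) variant sites mapped to the shared
#' domain coordinate system, identifies (a) domain positions where two or
#' more paralogs carry a clinical variant, and (b) (gene, position) sites
#' where one gene carries two or more distinct alternate alleles.
#'
#' @param clinical_sites Data frame with columns `gene`, `domain_pos`, and
#'   `n_alt` (distinct alternate alleles for that gene at that position;
#'   assumed 1 when absent). Typically built from [annotate_sites()] output
#'   restricted to clinical sources, or from the packaged clinical-domain
#'   fixture.
#' @param min_paralogs Paralog threshold for rule (a) (default 2).
#' @return List with elements `position_genes` (data frame `domain_pos`,
#'   `genes`, `n_paralogs`), `multi_paralog_positions` (integer vector),
#'   `multi_change_sites` (data frame `gene`, `domain_pos`, `n_alt`),
#'   `multi_change_positions` (integer vector), and headline counts
#'   `n_multi_paralog` and `n_multi_change`.
#' @export
cross_paralog_clinvar_positions <- function(clinical_sites,
                                            min_paralogs = 2L) {
  if (!all(c("gene", "domain_pos") %in% names(clinical_sites))) {
    stop("clinical_sites needs columns gene and domain_pos")
  }
  cs <- clinical_sites[!is.na(clinical_sites$domain_pos), , drop = FALSE]
  if (!"n_alt" %in% names(cs)) cs$n_alt <- rep(1L, nrow(cs))
  if (nrow(cs) == 0L) {
    return(list(
      position_genes = data.frame(domain_pos = integer(0),
                                  genes = character(0),
                                  n_paralogs = integer(0)),
      multi_paralog_positions = integer(0),
      multi_change_sites = data.frame(gene = character(0),
                                      domain_pos = integer(0),
                                      n_alt = integer(0)),
      multi_change_positions = integer(0),
      n_multi_paralog = 0L, n_multi_change = 0L))
  }

  by_pos <- split(cs, cs$domain_pos)
  position_genes <- do.call(rbind, lapply(by_pos, function(d) {
    g <- sort(unique(d$gene))
    data.frame(domain_pos = d$domain_pos[1L],
               genes = paste(g, collapse = ","),
               n_paralogs = length(g), row.names = NULL)
  }))
  position_genes <- position_genes[order(position_genes$domain_pos), ,
                                   drop = FALSE]
  rownames(position_genes) <- NULL
  multi_paralog <- position_genes$domain_pos[
    position_genes$n_paralogs >= min_paralogs]

  # distinct alternate alleles per (gene, position): sum over rows in case
  # the same site arrives split across records
  key <- interaction(cs$gene, cs$domain_pos, drop = TRUE)
  per_site <- do.call(rbind, lapply(split(cs, key), function(d) {
    data.frame(gene = d$gene[1L], domain_pos = d$domain_pos[1L],
               n_alt = sum(d$n_alt), row.names = NULL)
  }))
  multi_change_sites <- per_site[per_site$n_alt >= 2L, , drop = FALSE]
  multi_change_sites <- multi_change_sites[
    order(multi_change_sites$domain_pos, multi_change_sites$gene), ,
    drop = FALSE]
  rownames(multi_change_sites) <- NULL
  multi_change_positions <- sort(unique(multi_change_sites$domain_pos))

  list(position_genes = position_genes,
       multi_paralog_positions = sort(multi_paralog),
       multi_change_sites = multi_change_sites,
       multi_change_positions = multi_change_positions,
       n_multi_paralog = length(multi_paralog),
       n_multi_change = length(multi_change_positions))
}

#' CADD/selection filter for in-domain phenotype-profile variants
#'
#' Keeps in-domain Geno2MP-style sites with `cadd > cadd_min` (strict) and
#' conservation score `>= score_min` (inclusive). When cross-paralog
#' clinical evidence is supplied, each call records the paralogs with
#' clinical variants at its domain position.
#'
#' @param sites Data frame with columns `gene`, `in_domain`, `cadd` (or
#'   `max_cadd`), `score`, and `domain_pos`. Typically [annotate_sites()]
#'   output restricted to the geno2mp source, or the packaged fixture.
#' @param cadd_min CADD threshold, exclusive (default 20).
#' @param score_min Conservation-score threshold, inclusive (default 1).
#' @param clinvar_positions Optional `position_genes` data frame from
#'   [cross_paralog_clinvar_positions()].
#' @return Data frame of calls with `rule = "geno2mp_hmg_filter"` and a
#'   `clinvar_genes` evidence column.
#' @export
filter_geno2mp_hmg <- function(sites, cadd_min = 20, score_min = 1,
                               clinvar_positions = NULL) {
  cadd <- if ("cadd" %in% names(sites)) sites$cadd else sites$max_cadd
  if (is.null(cadd)) stop("sites needs a cadd or max_cadd column")
  keep <- sites$in_domain %in% TRUE &
    !is.na(cadd) & cadd > cadd_min &
    !is.na(sites$score) & sites$score >= score_min
  out <- sites[keep, , drop = FALSE]
  out$cadd <- cadd[keep]
  out$rule <- rep("geno2mp_hmg_filter", nrow(out))
  out$clinvar_genes <- rep("", nrow(out))
  if (!is.null(clinvar_positions) && nrow(out) > 0L) {
    m <- match(out$domain_pos, clinvar_positions$domain_pos)
    out$clinvar_genes <- ifelse(is.na(m), "", clinvar_positions$genes[m])
  }
  rownames(out) <- NULL
  out
}

#' Outside-domain conserved-context rule
#'
#' Keeps sites outside the domain whose residue conservation score is at
#' least `score_min` and whose 21-codon window sum is at least
#' `window_min`, observed in any of the clinical, phenotype-profile, or
#' population sources. The window condition operationalizes "additional
#' amino acids around the site conserved".
#'
#' @param sites Data frame with columns `in_domain`, `score`, `window_sum`,
#'   `sources`.
#' @param score_min Site conservation-score threshold, inclusive
#'   (default 1).
#' @param window_min 21-codon window-sum threshold, inclusive (default 10).
#' @param sources Source tags that qualify (default clinvar, geno2mp,
#'   gnomad).
#' @return Data frame of calls with `rule = "outside_domain_conserved"`.
#' @export
prioritize_outside_domain <- function(sites, score_min = 1, window_min = 10,
                                      sources = c("clinvar", "geno2mp",
                                                  "gnomad")) {
  keep <- !(sites$in_domain %in% TRUE) &
    !is.na(sites$score) & sites$score >= score_min &
    !is.na(sites$window_sum) & sites$window_sum >= window_min &
    .ov_has_source(sites$sources, sources)
  out <- sites[keep, , drop = FALSE]
  out$rule <- rep("outside_domain_conserved", nrow(out))
  rownames(out) <- NULL
  out
}

#' Somatic variants at clinically annotated domain positions
#'
#' Restricts in-domain somatic (COSMIC-style) variant records to domain
#' positions carrying clinical evidence in any paralog, then groups by
#' (tissue, histology), reporting the retained variant count and the gene
#' with the largest share of each group.
#'
#' @param cosmic_records Data frame with columns `gene`, `domain_pos`,
#'   `in_domain`, `tissue`, `histology` (one row per variant record).
#' @param clinical_positions Integer vector of domain positions with
#'   clinical evidence (e.g. `position_genes$domain_pos` from
#'   [cross_paralog_clinvar_positions()]).
#' @return List with `groups` (data frame `tissue`, `histology`, `n`,
#'   `top_gene`, `top_gene_share`, ranked by `n`) and `n_retained`.
#' @export
cosmic_highrisk_summary <- function(cosmic_records, clinical_positions) {
  keep <- cosmic_records$in_domain %in% TRUE &
    cosmic_records$domain_pos %in% clinical_positions
  kept <- cosmic_records[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(groups = data.frame(tissue = character(0),
                                    histology = character(0),
                                    n = integer(0),
                                    top_gene = character(0),
                                    top_gene_share = numeric(0)),
                n_retained = 0L))
  }
  key <- interaction(kept$tissue, kept$histology, drop = TRUE)
  groups <- do.call(rbind, lapply(split(kept, key), function(d) {
    tab <- sort(table(d$gene), decreasing = TRUE)
    data.frame(tissue = d$tissue[1L], histology = d$histology[1L],
               n = nrow(d), top_gene = names(tab)[1L],
               top_gene_share = as.numeric(tab[1L]) / nrow(d),
               row.names = NULL)
  }))
  groups <- groups[order(-groups$n, groups$tissue, groups$histology), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  list(groups = groups, n_retained = nrow(kept))
}
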