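# Per-codon conservation statistics and the 21-codon sliding-window profile.
#
# All statistics are anchored on the human reference sequence: each ortholog
# codon is compared against the reference codon at the same reference codon
# index. An ortholog codon that differs counts as one synonymous (same amino
# acid) or nonsynonymous (different amino acid) substitution. Sequences that
# are gapped or ambiguous at a column are excluded from that column's
# denominator.

# Logical matrices describing each non-reference codon cell: comparable
# (no gap, no ambiguity) and its translation.
.ov_column_comparison <- function(aln) {
  mat <- .ov_ref_codon_matrix(aln)
  others <- mat[rownames(mat) != aln$ref_id, , drop = FALSE]
  ref <- mat[aln$ref_id, ]
  comparable <- !is.na(codon_to_aa(others))
  dim(comparable) <- dim(others)
  list(others = others, ref = ref, comparable = comparable)
}

#' Substitution counts at one codon column
#'
#' Compares every non-reference sequence against the reference codon at a
#' reference codon index. A differing codon encoding the same amino acid
#' counts toward `s`, a differing codon encoding a different amino acid
#' toward `n`. Sequences gapped or ambiguous at the column are excluded
#' from `n_compared`.
#'
#' @param aln A [codon_alignment()].
#' @param codon_index Reference codon index (1-based). May be a vector.
#' @return Data frame with columns `codon_index`, `s`, `n`,
#'   `aa_match_fraction`, `n_compared`.
#' @export
column_substitution_counts <- function(aln, codon_index) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (any(codon_index < 1L | codon_index > aln$n_codons)) {
    stop("codon_index out of range 1..", aln$n_codons)
  }
  all_stats <- alignment_column_stats(aln)
  all_stats[codon_index, c("codon_index", "s", "n", "aa_match_fraction",
                           "n_compared")]
}

#' Substitution counts for every codon column
#'
#' Vectorized form of [column_substitution_counts()] over all reference
#' codon indices, with the reference codon and amino acid attached.
#'
#' @param aln A [codon_alignment()].
#' @return Data frame with one row per reference codon: `codon_index`,
#'   `ref_codon`, `ref_aa`, `s`, `n`, `aa_match_fraction`, `n_compared`.
#' @export
alignment_column_stats <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cmp <- .ov_column_comparison(aln)
  ref_aa <- codon_to_aa(cmp$ref)
  other_aa <- codon_to_aa(cmp$others)
  dim(other_aa) <- dim(cmp$others)

  differs <- sweep(cmp$others, 2L, cmp$ref, FUN = "!=") & cmp$comparable
  same_aa <- sweep(other_aa, 2L, ref_aa, FUN = "==") & cmp$comparable

  n_compared <- as.integer(colSums(cmp$comparable))
  s <- as.integer(colSums(differs & same_aa))
  n <- as.integer(colSums(differs & !same_aa))
  aa_match_fraction <- ifelse(n_compared > 0L, colSums(same_aa) / n_compared,
                              NA_real_)
  data.frame(
    codon_index = seq_len(aln$n_codons),
    ref_codon = unname(cmp$ref),
    ref_aa = unname(ref_aa),
    s = unname(s), n = unname(n),
    aa_match_fraction = unname(aa_match_fraction),
    n_compared = unname(n_compared),
    row.names = NULL
  )
}

#' Per-codon standardized dN-dS signal for one gene
#'
#' A reference-anchored counting estimator of codon-level selection. For
#' each reference codon, `raw = n / n_sites - s / s_sites`, where `s_sites`
#' and `n_sites` are the reference codon's synonymous and nonsynonymous
#' site counts from single-nucleotide pathway counting
#' ([codon_site_counts()]); a term with zero sites contributes zero.
#' `dnds_z` standardizes `raw` over the gene's codons, so negative values
#' mark codons with an excess of synonymous change relative to the gene:
#' the signature of purifying selection. Codons compared against fewer than
#' `min_compared` sequences are flagged and get `dnds_z = NA`.
#'
#' @param aln A [codon_alignment()].
#' @param min_compared Minimum informative sequences for a codon to enter
#'   the standardization (default 3).
#' @return Data frame with `codon_index`, `raw`, `dnds_z`, `flagged`.
#' @export
gene_dnds_profile <- function(aln, min_compared = 3L) {
  stats <- alignment_column_stats(aln)
  if (nrow(aln$codons) < min_compared) {
    stop("gene_dnds_profile() needs at least ", min_compared,
         " comparable sequences")
  }
  sites <- codon_site_counts(stats$ref_codon)
  s_rate <- ifelse(sites$s_sites > 0, stats$s / sites$s_sites, 0)
  n_rate <- ifelse(sites$n_sites > 0, stats$n / sites$n_sites, 0)
  raw <- n_rate - s_rate
  flagged <- stats$n_compared < min_compared
  usable <- raw[!flagged]
  mu <- mean(usable)
  sdev <- stats::sd(usable)
  if (!is.finite(sdev) || sdev == 0) {
    warning("zero variance in raw dN-dS for gene '", aln$gene,
            "'; dnds_z set to 0")
    z <- rep(0, length(raw))
  } else {
    z <- (raw - mu) / sdev
  }
  z[flagged] <- NA_real_
  data.frame(codon_index = stats$codon_index, raw = raw, dnds_z = z,
             flagged = flagged, row.names = NULL)
}

#' Quantized per-codon conservation score
#'
#' Combines amino-acid conservation with substitution-pattern evidence into
#' a score on `{0, 0.25, ..., 2}`:
#' base 1 when `aa_match_fraction >= aa_conserved_min` (else 0), plus 0.25
#' for each of `s >= 5`, `s >= 15`, `dnds_z <= -1`, `dnds_z <= -2`, capped
#' at 2. High synonymous-only divergence at a conserved residue therefore
#' pushes the score toward 2. `NA` `dnds_z` contributes nothing.
#'
#' @param s Synonymous substitution count (vector).
#' @param aa_match_fraction Fraction of orthologs with the reference amino
#'   acid (vector).
#' @param dnds_z Standardized dN-dS (vector; `NA` allowed).
#' @param aa_conserved_min Amino-acid conservation threshold for the base
#'   point (default 0.9).
#' @return Numeric vector of scores in steps of 0.25.
#' @export
conservation_score <- function(s, aa_match_fraction, dnds_z,
                               aa_conserved_min = 0.9) {
  z <- ifelse(is.na(dnds_z), 0, dnds_z)
  score <- ifelse(aa_match_fraction >= aa_conserved_min, 1, 0) +
    0.25 * (s >= 5) + 0.25 * (s >= 15) +
    0.25 * (z <= -1) + 0.25 * (z <= -2)
  pmin(round(score / 0.25) * 0.25, 2)
}

#' 21-codon sliding-window sum
#'
#' `window_sum(i)` adds the score at codon `i` and its `half_width`
#' upstream and downstream neighbors; windows are truncated at the gene
#' termini (fewer terms, no padding).
#'
#' @param score Numeric vector of per-codon scores.
#' @param half_width Codons on each side (default 10, i.e. a 21-codon
#'   window).
#' @return Numeric vector of window sums, same length as `score`.
#' @export
sliding_window <- function(score, half_width = 10L) {
  n <- length(score)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(c(0, score))
  idx <- seq_len(n)
  lo <- pmax(idx - half_width, 1L)
  hi <- pmin(idx + half_width, n)
  cs[hi + 1L] - cs[lo]
}

#' Normalize a window profile to its gene maximum
#'
#' Divides each window sum by the gene's maximum window sum, so the most
#' conserved motif has value 1. An all-zero profile maps to all zeros with
#' a warning.
#'
#' @param window_sum Numeric vector of window sums.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_profile <- function(window_sum) {
  if (length(window_sum) == 0L) return(numeric(0))
  m <- max(window_sum)
  if (m <= 0) {
    warning("all window sums are zero; normalized profile is all zero")
    return(rep(0, length(window_sum)))
  }
  window_sum / m
}

#' Full conservation profile for one gene
#'
#' Runs the per-codon statistics, the standardized dN-dS signal, the
#' quantized conservation score, the 21-codon sliding window, and the
#' per-gene normalization, and returns them as one table.
#'
#' @param aln A [codon_alignment()].
#' @param half_width Sliding-window half width (default 10).
#' @param aa_conserved_min Amino-acid conservation threshold for the score
#'   base point (default 0.9).
#' @return Data frame with columns `gene`, `codon_index`, `ref_aa`, `s`,
#'   `n`, `aa_match_fraction`, `dnds_z`, `score`, `window_sum`,
#'   `normalized_window`.
#' @export
conservation_profile <- function(aln, half_width = 10L,
                                 aa_conserved_min = 0.9) {
  stats <- alignment_column_stats(aln)
  dnds <- gene_dnds_profile(aln)
  score <- conservation_score(stats$s, stats$aa_match_fraction, dnds$dnds_z,
                              aa_conserved_min = aa_conserved_min)
  wsum <- sliding_window(score, half_width = half_width)
  norm <- normalize_profile(wsum)
  data.frame(
    gene = aln$gene,
    codon_index = stats$codon_index,
    ref_aa = stats$ref_aa,
    s = stats$s, n = stats$n,
    aa_match_fraction = stats$aa_match_fraction,
    dnds_z = dnds$dnds_z,
    score = score,
    window_sum = wsum,
    normalized_window = norm,
    row.names = NULL
  )
}
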