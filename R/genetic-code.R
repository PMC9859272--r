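# Codon-level utilities built on the standard genetic code.
#
# All downstream statistics are reference-anchored: they compare ortholog
# codons against the human reference codon, so the only genetic-code
# machinery needed is translation, single-nucleotide neighborhoods, and
# Nei-Gojobori-style synonymous/nonsynonymous site counts.

.ov_bases <- c("A", "C", "G", "T")

.ov_code_env <- new.env(parent = emptyenv())

.ov_genetic_code <- function() {
  if (is.null(.ov_code_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .ov_code_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  .ov_code_env$code
}

#' Translate codons to one-letter amino acids
#'
#' Vectorized lookup in the standard genetic code. Stop codons translate to
#' `"*"`; codons containing gaps or ambiguity characters return `NA`.
#'
#' @param codons Character vector of 3-letter codon strings (case-insensitive).
#' @return Character vector of one-letter amino acid codes.
#' @examples
#' codon_to_aa(c("ATG", "GCT", "TAA"))
#' @export
codon_to_aa <- function(codons) {
  code <- .ov_genetic_code()
  out <- unname(code[toupper(codons)])
  out
}

#' All sense (non-stop) codons
#'
#' @return Character vector of the 61 codons encoding an amino acid.
#' @export
sense_codons <- function() {
  code <- .ov_genetic_code()
  names(code)[code != "*"]
}

# The 9 single-nucleotide neighbors of a codon.
.ov_codon_neighbors <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(.ov_bases, chars[p])) {
      alt <- chars
      alt[p] <- b
      out <- c(out, paste(alt, collapse = ""))
    }
  }
  out
}

# Cache per-codon neighbor classifications, keyed by codon.
.ov_neighbor_table <- function() {
  if (is.null(.ov_code_env$neighbors)) {
    code <- .ov_genetic_code()
    tab <- lapply(names(code), function(cdn) {
      nb <- .ov_codon_neighbors(cdn)
      aa <- unname(code[nb])
      ref_aa <- unname(code[cdn])
      list(
        syn = nb[aa == ref_aa & aa != "*"],
        nonsyn = nb[aa != ref_aa & aa != "*"],
        stop = nb[aa == "*"]
      )
    })
    names(tab) <- names(code)
    .ov_code_env$neighbors <- tab
  }
  .ov_code_env$neighbors
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts mutational opportunity at a codon by classifying each of its nine
#' single-nucleotide neighbors. Sites are fractional in the Nei-Gojobori
#' sense: each codon position contributes the fraction of its possible
#' changes that are synonymous (to `s_sites`) and nonsynonymous (to
#' `n_sites`). Changes that create a stop codon are excluded from both
#' numerator and denominator, so `s_sites + n_sites <= 3` with equality when
#' no neighbor is a stop.
#'
#' For example `GCT` (alanine, four-fold degenerate third position) has
#' `s_sites = 1` and `n_sites = 2`.
#'
#' @param codons Character vector of sense codons.
#' @return Data frame with columns `codon`, `s_sites`, `n_sites`.
#' @export
codon_site_counts <- function(codons) {
  codons <- toupper(codons)
  code <- .ov_genetic_code()
  bad <- !(codons %in% names(code)) | code[codons] == "*"
  if (any(bad)) {
    stop("codon_site_counts() requires sense codons; offending: ",
         paste(unique(codons[bad]), collapse = ", "))
  }
  res <- t(vapply(codons, function(cdn) {
    chars <- strsplit(cdn, "")[[1]]
    ref_aa <- unname(code[cdn])
    s <- 0
    n <- 0
    for (p in 1:3) {
      nb <- vapply(setdiff(.ov_bases, chars[p]), function(b) {
        alt <- chars
        alt[p] <- b
        paste(alt, collapse = "")
      }, character(1))
      aa <- unname(code[nb])
      keep <- aa != "*"
      if (!any(keep)) next
      s <- s + sum(aa[keep] == ref_aa) / sum(keep)
      n <- n + sum(aa[keep] != ref_aa) / sum(keep)
    }
    c(s, n)
  }, numeric(2)))
  data.frame(codon = codons, s_sites = res[, 1], n_sites = res[, 2],
             row.names = NULL)
}

# Single-nucleotide neighbors of `codon` in a substitution class.
# class one of "syn", "nonsyn". Stop-producing neighbors are never returned.
.ov_class_neighbors <- function(codon, class) {
  .ov_neighbor_table()[[toupper(codon)]][[class]]
}
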