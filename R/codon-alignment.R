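# Reference-anchored codon alignments.
#
# A codon_alignment holds one gene's ortholog open reading frames, aligned,
# with one designated (human) reference. The reference defines the codon
# index set: alignment codon columns where the reference is gapped carry no
# codon index. Gaps are expected in whole-codon triplets; a partially gapped
# triplet is treated like an ambiguous codon and excluded from statistics.

#' Construct a codon alignment
#'
#' @param sequences Named character vector of aligned nucleotide strings
#'   (equal length, length divisible by 3). Case-insensitive; stored
#'   uppercase. `-` and `.` are gap characters.
#' @param ref_id Name of the reference (human) sequence.
#' @param gene Gene identifier.
#' @return An object of class `codon_alignment` with elements `gene`,
#'   `ref_id`, `codons` (matrix of codon strings, sequences in rows, aligned
#'   codon columns in columns), `ref_codon_col` (alignment codon column of
#'   each reference codon index), and `n_codons`.
#' @export
codon_alignment <- function(sequences, ref_id, gene = "gene") {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be a named character vector")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence names in alignment for gene ", gene)
  }
  if (!ref_id %in% names(sequences)) {
    stop("reference '", ref_id, "' not present in alignment for gene ", gene)
  }
  sequences <- toupper(gsub(".", "-", sequences, fixed = TRUE))
  widths <- unique(nchar(sequences))
  if (length(widths) != 1L) {
    stop("aligned sequences must all have equal length (gene ", gene, ")")
  }
  if (widths %% 3L != 0L) {
    stop("alignment length must be divisible by 3 (gene ", gene, ")")
  }
  n_col <- widths %/% 3L
  starts <- seq.int(1L, widths, by = 3L)
  codons <- do.call(rbind, lapply(sequences, function(s)
    substring(s, starts, starts + 2L)))
  rownames(codons) <- names(sequences)
  ref_codons <- codons[ref_id, ]
  ref_codon_col <- which(ref_codons != "---")
  if (any(grepl("-", ref_codons[ref_codon_col]))) {
    stop("reference sequence has partially gapped codons (gene ", gene, ")")
  }
  structure(
    list(gene = gene, ref_id = ref_id, codons = codons,
         ref_codon_col = ref_codon_col,
         n_codons = length(ref_codon_col)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d sequences, %d reference codons (ref: %s)\n",
              x$gene, nrow(x$codons), x$n_codons, x$ref_id))
  invisible(x)
}

# Codon matrix restricted to reference-indexed columns: one column per
# reference codon index 1..n_codons.
.ov_ref_codon_matrix <- function(aln) {
  aln$codons[, aln$ref_codon_col, drop = FALSE]
}

#' Reference codons and their translation
#'
#' @param aln A [codon_alignment()].
#' @return Data frame with `codon_index`, `ref_codon`, `ref_aa`.
#' @export
reference_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  codons <- aln$codons[aln$ref_id, aln$ref_codon_col]
  data.frame(codon_index = seq_along(codons), ref_codon = unname(codons),
             ref_aa = codon_to_aa(codons), row.names = NULL)
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path FASTA file of equal-length aligned ORF sequences.
#' @param ref_id Reference sequence name. Defaults to the first name
#'   matching `ref_pattern`.
#' @param ref_pattern Regular expression used to locate the reference when
#'   `ref_id` is not given.
#' @param gene Gene identifier; defaults to the file name without extension.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, ref_id = NULL, ref_pattern = "human",
                                 gene = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(dna), names(dna))
  if (is.null(gene)) {
    gene <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(ref_id)) {
    hit <- grep(ref_pattern, names(seqs), value = TRUE)
    if (length(hit) == 0L) {
      stop("no sequence name matches ref_pattern '", ref_pattern, "' in ", path)
    }
    ref_id <- hit[[1L]]
  }
  codon_alignment(seqs, ref_id = ref_id, gene = gene)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1L, paste, collapse = "")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- rownames(aln$codons)
  Biostrings::writeXStringSet(dna, filepath = path, width = 80L)
  invisible(path)
}

#' Filter ortholog sequences before conservation analysis
#'
#' Applies two removal rules to an aligned sequence set:
#' \enumerate{
#'   \item any sequence containing an ambiguity character (anything other
#'     than `A`, `C`, `G`, `T`, or a gap) is removed;
#'   \item any sequence missing (gapped) more than `max_missing` nucleotides
#'     at alignment columns occupied by more than `occupancy` of all
#'     sequences is removed.
#' }
#' The reference is never removed: if the reference itself fails either
#' rule, this is an error.
#'
#' @param sequences Named character vector of equal-length aligned sequences.
#' @param ref_id Name of the reference sequence.
#' @param max_missing Missing-nucleotide tolerance at high-occupancy columns
#'   (default 9: strictly more than 9 missing triggers removal).
#' @param occupancy Column occupancy fraction defining "found in most
#'   sequences" (default 0.9, strict).
#' @return List with `kept` (named character vector) and `rejections`
#'   (data frame `id`, `rule`, `detail`).
#' @export
filter_sequences <- function(sequences, ref_id, max_missing = 9,
                             occupancy = 0.9) {
  if (length(sequences) < 1L) stop("no sequences supplied")
  if (!ref_id %in% names(sequences)) stop("reference '", ref_id, "' absent")
  sequences <- toupper(gsub(".", "-", sequences, fixed = TRUE))
  widths <- unique(nchar(sequences))
  if (length(widths) != 1L) stop("aligned sequences must have equal length")

  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- names(sequences)
  is_gap <- mat == "-"
  is_ambig <- !is_gap & !(mat %in% .ov_bases)

  ambiguous <- rowSums(is_ambig) > 0L
  col_occ <- colMeans(!is_gap)
  dense_cols <- col_occ > occupancy
  missing_dense <- rowSums(is_gap[, dense_cols, drop = FALSE])
  too_sparse <- missing_dense > max_missing

  if (ambiguous[ref_id]) {
    stop("reference '", ref_id, "' contains ambiguity characters")
  }
  if (too_sparse[ref_id]) {
    stop("reference '", ref_id, "' is missing more than ", max_missing,
         " nucleotides at high-occupancy columns")
  }

  drop <- ambiguous | too_sparse
  rejections <- data.frame(
    id = names(sequences)[drop],
    rule = ifelse(ambiguous[drop], "ambiguity", "missing_dense_columns"),
    detail = ifelse(
      ambiguous[drop],
      paste0(rowSums(is_ambig)[drop], " ambiguous nucleotide(s)"),
      paste0(missing_dense[drop], " nucleotides missing at columns occupied by >",
             round(100 * occupancy), "% of sequences")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  kept <- sequences[!drop]
  if (length(kept) == 0L) stop("all sequences removed by filtering")
  list(kept = kept, rejections = rejections)
}
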