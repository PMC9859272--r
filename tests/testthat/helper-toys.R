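# Hand-built miniature alignments and records used across test files.

# Alignment from a list of codon vectors; first sequence is the reference.
toy_alignment <- function(..., gene = "toy") {
  rows <- list(...)
  seqs <- vapply(rows, paste, character(1), collapse = "")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    names(seqs) <- c("ref_human", paste0("sp", seq_len(length(rows) - 1L)))
  } else {
    names(seqs) <- names(rows)
  }
  codon_alignment(seqs, ref_id = names(seqs)[1L], gene = gene)
}

# Small record table in the shape read_variants_tsv() produces.
toy_records <- function(gene, pos, source, alt = "K", ref = "E", ...) {
  n <- max(length(gene), length(pos), length(source))
  data.frame(gene = rep_len(gene, n), protein_pos = rep_len(pos, n),
             ref_aa = rep_len(ref, n), alt_aa = rep_len(alt, n),
             source = rep_len(source, n), ..., stringsAsFactors = FALSE)
}

# Direct loop-summation oracle for the sliding window.
window_oracle <- function(score, half_width = 10L) {
  n <- length(score)
  vapply(seq_len(n), function(i) {
    sum(score[max(1L, i - half_width):min(n, i + half_width)])
  }, numeric(1))
}

# A fast small simulation config for property loops.
small_sim_config <- function(seed, ...) {
  family_sim_config(n_genes = 1L, species_per_gene = 12L,
                    protein_length = 30L, domain_start = 8L,
                    domain_end = 22L, seed = seed, ...)
}
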