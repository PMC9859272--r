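# Shared domain coordinate system across paralogs.
#
# Every family member carries the same domain (for SOX proteins, the HMG
# box), so a residue can be addressed by its position within the domain
# rather than in any one protein. Domain positions are 1-based inside the
# domain and strictly negative immediately upstream; position zero does not
# exist (the residue before domain position 1 is -1). An alternate
# numbering convention used in parts of the field is offset by +2.

#' Domain annotation for one gene
#'
#' @param gene Gene identifier.
#' @param domain Domain name (e.g. `"HMG"`).
#' @param start,end 1-based inclusive protein positions of the domain.
#' @param protein_length Optional protein length (residues).
#' @return A `domain_annotation` list.
#' @export
domain_annotation <- function(gene, domain, start, end,
                              protein_length = NA_integer_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("domain_annotation requires 1 <= start <= end")
  }
  if (!is.na(protein_length) && end > protein_length) {
    stop("domain end exceeds protein length for gene ", gene)
  }
  structure(list(gene = gene, domain = domain, start = start, end = end,
                 protein_length = as.integer(protein_length)),
            class = "domain_annotation")
}

#' Read domain annotations from TSV
#'
#' Expects columns `gene`, `domain`, `start`, `end` and optionally
#' `protein_length`.
#'
#' @param path TSV file with a header row.
#' @return Named list of [domain_annotation()] objects, keyed by gene.
#' @export
read_domain_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "domain", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"protein_length" %in% names(df)) df$protein_length <- NA_integer_
  out <- lapply(seq_len(nrow(df)), function(i) {
    domain_annotation(df$gene[i], df$domain[i], df$start[i], df$end[i],
                      df$protein_length[i])
  })
  stats::setNames(out, df$gene)
}

#' Map a protein position to its domain position
#'
#' Residues at or after the domain start map to `protein_pos - start + 1`
#' (the first domain residue is position 1); residues upstream map to the
#' negative offset `protein_pos - start` (the residue immediately before
#' the domain is -1). Zero is never produced.
#'
#' @param protein_pos 1-based protein position(s).
#' @param annotation A [domain_annotation()].
#' @return Integer vector of domain positions (never 0).
#' @export
to_domain_position <- function(protein_pos, annotation) {
  stopifnot(inherits(annotation, "domain_annotation"))
  protein_pos <- as.integer(protein_pos)
  if (any(protein_pos < 1L, na.rm = TRUE)) stop("protein_pos must be >= 1")
  ifelse(protein_pos >= annotation$start,
         protein_pos - annotation$start + 1L,
         protein_pos - annotation$start)
}

#' Map a domain position back to the protein position
#'
#' Exact inverse of [to_domain_position()].
#'
#' @param domain_pos Domain position(s); zero is an error.
#' @param annotation A [domain_annotation()].
#' @return Integer vector of 1-based protein positions.
#' @export
from_domain_position <- function(domain_pos, annotation) {
  stopifnot(inherits(annotation, "domain_annotation"))
  domain_pos <- as.integer(domain_pos)
  if (any(domain_pos == 0L, na.rm = TRUE)) {
    stop("domain position 0 does not exist")
  }
  ifelse(domain_pos > 0L,
         annotation$start + domain_pos - 1L,
         annotation$start + domain_pos)
}

#' Convert to the alternate (offset) domain numbering
#'
#' The alternate convention is shifted by `offset` (+2 by default) relative
#' to the primary numbering, e.g. domain position 53 is written 53/55.
#' Because neither convention has a position zero, a negative position
#' whose shifted value would land on or beyond zero skips it: position -1
#' with offset 2 becomes 2 (-1 -> 1 -> 2). The skip rule for upstream
#' positions is this package's convention and is logged via a message.
#'
#' @param domain_pos Domain position(s); zero is an error.
#' @param offset Numbering offset (default 2, non-negative).
#' @return Integer vector in the alternate numbering.
#' @export
to_alternate_numbering <- function(domain_pos, offset = 2L) {
  domain_pos <- as.integer(domain_pos)
  offset <- as.integer(offset)
  if (offset < 0L) stop("offset must be non-negative")
  if (any(domain_pos == 0L, na.rm = TRUE)) {
    stop("domain position 0 does not exist")
  }
  out <- domain_pos + offset
  crossed <- !is.na(domain_pos) & domain_pos < 0L & out >= 0L
  if (any(crossed)) {
    message("alternate numbering crossed zero for ", sum(crossed),
            " position(s); zero skipped")
    out[crossed] <- out[crossed] + 1L
  }
  out
}

#' Cross-paralog amino-acid usage and conservation per domain position
#'
#' For every domain position from `-flank_up` to `L + flank_down` (L =
#' domain length, no position zero), collects the residue used by each
#' paralog at the corresponding protein position, the set and count of
#' distinct residues, and the mean and standard deviation of the paralogs'
#' own conservation scores at that position. Domains must have equal
#' length across paralogs (the cross-paralog alignment frame is gap-free).
#'
#' @param proteins Named character vector: one full-length protein sequence
#'   per gene.
#' @param annotations Named list of [domain_annotation()], same genes.
#' @param profiles Optional named list of per-gene conservation profiles
#'   (data frames from [conservation_profile()]); when absent, conservation
#'   columns are `NA`.
#' @param flank_up,flank_down Flank extent reported upstream/downstream of
#'   the domain (defaults 10 and 25).
#' @return List with `positions` (data frame `domain_pos`, `aa_set`,
#'   `aa_used`, `cons_mean`, `cons_sd`, `n_paralogs`) and `per_paralog`
#'   (long data frame `domain_pos`, `gene`, `protein_pos`, `aa`, `score`).
#' @export
build_paralog_table <- function(proteins, annotations, profiles = NULL,
                                flank_up = 10L, flank_down = 25L) {
  genes <- names(proteins)
  if (is.null(genes) || !all(genes %in% names(annotations))) {
    stop("every protein needs a matching domain annotation")
  }
  lens <- vapply(genes, function(g) {
    a <- annotations[[g]]
    a$end - a$start + 1L
  }, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("domain length differs across paralogs: ",
         paste(unique(lens), collapse = ", "))
  }
  L <- unique(lens)
  dpos <- setdiff(seq.int(-flank_up, L + flank_down), 0L)

  per <- do.call(rbind, lapply(genes, function(g) {
    a <- annotations[[g]]
    ppos <- from_domain_position(dpos, a)
    plen <- nchar(proteins[[g]])
    ok <- ppos >= 1L & ppos <= plen
    aa <- rep(NA_character_, length(dpos))
    aa[ok] <- substring(proteins[[g]], ppos[ok], ppos[ok])
    score <- rep(NA_real_, length(dpos))
    if (!is.null(profiles) && g %in% names(profiles)) {
      prof <- profiles[[g]]
      m <- match(ppos[ok], prof$codon_index)
      score[ok] <- prof$score[m]
    }
    data.frame(domain_pos = dpos, gene = g, protein_pos = ppos, aa = aa,
               score = score, row.names = NULL)
  }))
  per <- per[!is.na(per$aa), , drop = FALSE]

  agg <- lapply(split(per, factor(per$domain_pos, levels = dpos)), function(d) {
    aas <- sort(unique(d$aa))
    sc <- d$score[!is.na(d$score)]
    data.frame(
      domain_pos = d$domain_pos[1L],
      aa_set = paste(aas, collapse = ""),
      aa_used = length(aas),
      cons_mean = if (length(sc)) mean(sc) else NA_real_,
      cons_sd = if (length(sc) > 1L) stats::sd(sc) else NA_real_,
      n_paralogs = nrow(d),
      row.names = NULL
    )
  })
  agg <- agg[vapply(agg, nrow, integer(1)) > 0L]
  positions <- do.call(rbind, agg)
  rownames(positions) <- NULL
  positions <- positions[order(positions$domain_pos), , drop = FALSE]
  list(positions = positions, per_paralog = per)
}

#' Conservation-weighted segregation profile of a focal paralog
#'
#' Compares a focal protein against sibling paralogs over a shared,
#' equal-length alignment frame. At each position a sibling contributes
#' `+score` when its residue matches the focal residue and `-score` when it
#' differs, where `score` is the focal gene's conservation score at that
#' position; the additive value sums over siblings. Positions where a
#' sibling is gapped contribute 0 for that sibling.
#'
#' @param focal Focal protein sequence (character scalar).
#' @param siblings Named character vector of sibling sequences, each the
#'   same length as `focal`.
#' @param focal_score Numeric vector of focal conservation scores, one per
#'   position of `focal`.
#' @return Data frame with `position`, `focal_aa`, one signed column per
#'   sibling, and `additive`.
#' @export
segregation_profile <- function(focal, siblings, focal_score) {
  n <- nchar(focal)
  if (length(focal_score) != n) {
    stop("focal_score must have one value per focal position")
  }
  if (any(nchar(siblings) != n)) {
    stop("siblings must share the focal alignment frame (equal length)")
  }
  fa <- strsplit(focal, "")[[1]]
  out <- data.frame(position = seq_len(n), focal_aa = fa, row.names = NULL)
  vals <- sapply(names(siblings), function(sib) {
    sa <- strsplit(siblings[[sib]], "")[[1]]
    v <- ifelse(sa == fa, focal_score, -focal_score)
    v[sa == "-" | fa == "-"] <- 0
    v
  })
  vals <- matrix(vals, nrow = n,
                 dimnames = list(NULL, names(siblings)))
  out <- cbind(out, as.data.frame(vals))
  out$additive <- rowSums(vals)
  out
}
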