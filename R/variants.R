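# Variant table ingestion and per-residue integration across databases.
#
# Four TSV schemas are supported, emulating the exports of the common
# human variant resources: population allele counts (gnomad), clinical
# significance (clinvar), rare-disease phenotype profiles with CADD
# (geno2mp), and somatic tissue/histology (cosmic). A fifth source tag,
# "literature", shares the clinvar schema and is merged with clinvar in
# the clinical-evidence channel. All coordinates are protein residues of
# the gene's canonical transcript.

.ov_sources <- c("gnomad", "clinvar", "geno2mp", "cosmic", "literature")

# Mandatory columns per source, beyond the shared core. The core is either
# (protein_pos, ref_aa, alt_aa) or a single p.-style `variant` column.
.ov_schema_extras <- list(
  gnomad = c("allele_count"),
  clinvar = c("significance"),
  literature = c("significance"),
  geno2mp = c("cadd", "hpo_profile_count"),
  cosmic = c("tissue", "histology")
)

#' Parse p.-style protein change notation
#'
#' Parses strings like `"E137K"` (one-letter reference amino acid, 1-based
#' protein position, one-letter alternate). Multiple alternates may be
#' slash-separated, e.g. `"M112V/R/T/I"`; the first is returned in
#' `alt_aa` and the full set in `alts`.
#'
#' @param x Character vector of protein-change strings.
#' @return Data frame with `ref_aa`, `protein_pos`, `alt_aa`, `alts`
#'   (slash-joined), `n_alt`. Unparseable strings give `NA` rows.
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z](?:/[A-Za-z])*)$",
                             as.character(x)))
  out <- lapply(m, function(g) {
    if (length(g) != 4L) {
      return(data.frame(ref_aa = NA_character_, protein_pos = NA_integer_,
                        alt_aa = NA_character_, alts = NA_character_,
                        n_alt = NA_integer_))
    }
    alts <- strsplit(g[4], "/", fixed = TRUE)[[1]]
    data.frame(ref_aa = toupper(g[2]), protein_pos = as.integer(g[3]),
               alt_aa = toupper(alts[1]),
               alts = paste(toupper(alts), collapse = "/"),
               n_alt = length(alts))
  })
  do.call(rbind, out)
}

#' Read one variant table
#'
#' Reads a TSV in one of the supported source schemas into typed variant
#' records. Rows may carry explicit `protein_pos`, `ref_aa`, `alt_aa`
#' columns or a single `variant` column in p.-style notation. Malformed
#' rows (unparseable notation, `ref_aa == alt_aa`, non-positive position)
#' are rejected with line-numbered log entries rather than aborting.
#'
#' @param path TSV file with a header row.
#' @param source One of `"gnomad"`, `"clinvar"`, `"geno2mp"`, `"cosmic"`,
#'   `"literature"`.
#' @return Data frame of records with attribute `"rejections"` (data frame
#'   `line`, `reason`). Always contains columns `gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `source`, plus the schema's extras.
#' @export
read_variants_tsv <- function(path, source) {
  source <- match.arg(source, .ov_sources)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"gene" %in% names(df)) {
    stop("variant table ", path, " lacks mandatory column 'gene'")
  }
  has_triplet <- all(c("protein_pos", "ref_aa", "alt_aa") %in% names(df))
  has_notation <- "variant" %in% names(df)
  if (!has_triplet && !has_notation) {
    stop("variant table ", path,
         " needs either protein_pos/ref_aa/alt_aa or a 'variant' column")
  }
  extras <- .ov_schema_extras[[source]]
  missing_extras <- setdiff(extras, names(df))
  if (length(missing_extras)) {
    stop("variant table ", path, " (", source, ") lacks column(s): ",
         paste(missing_extras, collapse = ", "))
  }

  n <- nrow(df)
  rejections <- data.frame(line = integer(0), reason = character(0))
  if (n == 0L) {
    out <- data.frame(gene = character(0), protein_pos = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      source = character(0))
    attr(out, "rejections") <- rejections
    return(out)
  }

  if (has_triplet) {
    pos <- suppressWarnings(as.integer(df$protein_pos))
    ref <- toupper(df$ref_aa)
    alt <- toupper(df$alt_aa)
  } else {
    parsed <- parse_protein_change(df$variant)
    pos <- parsed$protein_pos
    ref <- parsed$ref_aa
    alt <- parsed$alt_aa
  }
  bad_parse <- is.na(pos) | is.na(ref) | is.na(alt)
  bad_pos <- !bad_parse & pos < 1L
  bad_same <- !bad_parse & !bad_pos & ref == alt
  bad <- bad_parse | bad_pos | bad_same
  if (any(bad)) {
    # +1 for the header row: report physical file lines
    rejections <- data.frame(
      line = which(bad) + 1L,
      reason = ifelse(bad_parse[bad], "unparseable protein change",
                      ifelse(bad_pos[bad], "protein_pos < 1",
                             "ref_aa == alt_aa")))
  }

  out <- data.frame(gene = df$gene, protein_pos = pos, ref_aa = ref,
                    alt_aa = alt, source = source,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  numeric_cols <- c("allele_count", "allele_frequency", "cadd",
                    "hpo_profile_count")
  for (col in setdiff(names(df), c("gene", "protein_pos", "ref_aa",
                                   "alt_aa", "variant"))) {
    vals <- df[[col]][!bad]
    out[[col]] <- if (col %in% numeric_cols) {
      suppressWarnings(as.numeric(vals))
    } else {
      vals
    }
  }
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Combine variant records from several sources
#'
#' @param ... Record data frames from [read_variants_tsv()] (or built in
#'   code with the same core columns).
#' @return One data frame with the union of columns.
#' @export
bind_variant_records <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (length(dfs) == 0L) {
    return(data.frame(gene = character(0), protein_pos = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      source = character(0)))
  }
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    d[cols]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' Aggregate variant records into per-residue site summaries
#'
#' A variant site is a residue, identified by (gene, protein position);
#' distinct alternate alleles at one residue belong to one site. Each
#' summary carries the set of sources observing the site, the domain
#' membership and domain position from the gene's annotation, the codon
#' conservation score and 21-codon window sum from the gene's profile, and
#' per-source roll-ups (maximum CADD, total allele count, total phenotype
#' profiles, distinct alternate alleles per source).
#'
#' @param records Data frame of variant records (see
#'   [read_variants_tsv()]).
#' @param annotations Named list of [domain_annotation()] per gene; genes
#'   without an annotation get `in_domain = NA` with a warning.
#' @param profiles Named list of per-gene [conservation_profile()] data
#'   frames; genes without a profile get `NA` conservation with a warning.
#' @return Data frame with one row per site: `gene`, `protein_pos`,
#'   `ref_aa`, `sources` (`+`-joined, sorted), `n_sources`, `in_domain`,
#'   `domain_pos`, `score`, `window_sum`, `max_cadd`, `allele_count`,
#'   `hpo_profiles`, `n_alt`, and `n_alt_<source>` columns.
#' @export
annotate_sites <- function(records, annotations = list(), profiles = list()) {
  if (nrow(records) == 0L) {
    return(data.frame(gene = character(0), protein_pos = integer(0),
                      ref_aa = character(0), sources = character(0),
                      n_sources = integer(0), in_domain = logical(0),
                      domain_pos = integer(0), score = numeric(0),
                      window_sum = numeric(0), max_cadd = numeric(0),
                      allele_count = numeric(0), hpo_profiles = numeric(0),
                      n_alt = integer(0)))
  }
  no_annot <- setdiff(unique(records$gene), names(annotations))
  if (length(no_annot)) {
    warning("no domain annotation for gene(s): ",
            paste(no_annot, collapse = ", "))
  }
  no_prof <- setdiff(unique(records$gene), names(profiles))
  if (length(no_prof)) {
    warning("no conservation profile for gene(s): ",
            paste(no_prof, collapse = ", "))
  }
  key <- interaction(records$gene, records$protein_pos, drop = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    gene <- g$gene[1L]
    pos <- g$protein_pos[1L]
    ann <- annotations[[gene]]
    prof <- profiles[[gene]]
    in_domain <- if (is.null(ann)) NA else (pos >= ann$start & pos <= ann$end)
    dpos <- if (is.null(ann)) NA_integer_ else to_domain_position(pos, ann)
    score <- NA_real_
    wsum <- NA_real_
    if (!is.null(prof)) {
      m <- match(pos, prof$codon_index)
      if (!is.na(m)) {
        score <- prof$score[m]
        wsum <- prof$window_sum[m]
      }
    }
    srcs <- sort(unique(g$source))
    num <- function(col) {
      if (!col %in% names(g)) return(NA_real_)
      v <- suppressWarnings(as.numeric(g[[col]]))
      if (all(is.na(v))) NA_real_ else v
    }
    cadd <- num("cadd")
    ac <- num("allele_count")
    hpo <- num("hpo_profile_count")
    row <- data.frame(
      gene = gene, protein_pos = pos, ref_aa = g$ref_aa[1L],
      sources = paste(srcs, collapse = "+"), n_sources = length(srcs),
      in_domain = in_domain, domain_pos = dpos,
      score = score, window_sum = wsum,
      max_cadd = if (all(is.na(cadd))) NA_real_ else max(cadd, na.rm = TRUE),
      allele_count = if (all(is.na(ac))) NA_real_ else sum(ac, na.rm = TRUE),
      hpo_profiles = if (all(is.na(hpo))) NA_real_ else sum(hpo, na.rm = TRUE),
      n_alt = length(unique(g$alt_aa)),
      stringsAsFactors = FALSE
    )
    for (src in .ov_sources) {
      row[[paste0("n_alt_", src)]] <-
        length(unique(g$alt_aa[g$source == src]))
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$protein_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition sites by their exact source combination
#'
#' Every site belongs to exactly one category, the `+`-joined sorted set of
#' sources observing it. Reports per category the number of sites, the
#' number inside the domain, and their ratio.
#'
#' @param summaries Site summaries from [annotate_sites()].
#' @return Data frame `category`, `n_sites`, `n_in_domain`, `ratio`,
#'   ordered by decreasing `n_sites`.
#' @export
overlap_categories <- function(summaries) {
  if (nrow(summaries) == 0L) {
    return(data.frame(category = character(0), n_sites = integer(0),
                      n_in_domain = integer(0), ratio = numeric(0)))
  }
  sp <- split(summaries, summaries$sources)
  out <- do.call(rbind, lapply(sp, function(d) {
    n_in <- sum(d$in_domain %in% TRUE)
    data.frame(category = d$sources[1L], n_sites = nrow(d),
               n_in_domain = n_in, ratio = n_in / nrow(d),
               row.names = NULL)
  }))
  out <- out[order(-out$n_sites, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain enrichment of a gene's variants
#'
#' The fraction of a gene's variants (from one source) that fall inside
#' the domain, divided by the fraction of the protein the domain occupies.
#' A value of 1 is the random expectation; values above 1 mean the domain
#' carries more variants than its length predicts.
#'
#' @param records Variant records.
#' @param gene Gene to assess.
#' @param source Source to assess.
#' @param annotation The gene's [domain_annotation()].
#' @param protein_length Protein length in residues; defaults to the
#'   annotation's `protein_length`.
#' @return Enrichment ratio, or `NA` when the gene/source has no variants.
#' @export
hmg_enrichment <- function(records, gene, source, annotation,
                           protein_length = annotation$protein_length) {
  stopifnot(inherits(annotation, "domain_annotation"))
  if (is.na(protein_length) || protein_length < 1) {
    stop("protein_length required for enrichment")
  }
  sel <- records$gene == gene & records$source == source
  n_total <- sum(sel)
  if (n_total == 0L) return(NA_real_)
  pos <- records$protein_pos[sel]
  n_in <- sum(pos >= annotation$start & pos <= annotation$end)
  dom_frac <- (annotation$end - annotation$start + 1) / protein_length
  (n_in / n_total) / dom_frac
}
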