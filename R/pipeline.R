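# End-to-end pipeline driver.
#
# Orchestrates the analysis in the order the statistics depend on each
# other: sequence filtering -> conservation profiles -> paralog position
# table -> variant integration -> prioritization -> enrichment. All file
# outputs are deterministic for a given configuration and inputs;
# timestamps are confined to the log.

#' Pipeline configuration
#'
#' @param alignments_dir Directory of per-gene aligned FASTA files
#'   (`<gene>.fasta`).
#' @param annotations Path to the domain annotation TSV (`gene`, `domain`,
#'   `start`, `end`, `protein_length`).
#' @param variant_tables Named character vector of variant TSV paths; names
#'   are source tags (`gnomad`, `clinvar`, `geno2mp`, `cosmic`,
#'   `literature`). May be empty.
#' @param out_dir Output directory for the report bundle.
#' @param ref_pattern Regular expression locating the reference sequence in
#'   each alignment (default `"human"`).
#' @param cadd_min,score_min,window_min,aa_conserved_min Rule thresholds.
#' @param flank_up,flank_down Paralog-table flank extent.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignments_dir, annotations,
                            variant_tables = character(0),
                            out_dir,
                            ref_pattern = "human",
                            cadd_min = 20, score_min = 1, window_min = 10,
                            aa_conserved_min = 0.9,
                            flank_up = 10L, flank_down = 25L) {
  if (!dir.exists(alignments_dir)) {
    stop("alignments directory does not exist: ", alignments_dir)
  }
  if (!file.exists(annotations)) {
    stop("annotation file does not exist: ", annotations)
  }
  if (length(variant_tables)) {
    if (is.null(names(variant_tables)) ||
        !all(names(variant_tables) %in% .ov_sources)) {
      stop("variant_tables must be named with source tags: ",
           paste(.ov_sources, collapse = ", "))
    }
    missing <- variant_tables[!file.exists(variant_tables)]
    if (length(missing)) {
      stop("variant table file(s) missing: ", paste(missing, collapse = ", "))
    }
  }
  if (score_min < 0 || window_min < 0 || aa_conserved_min < 0 ||
      aa_conserved_min > 1) {
    stop("thresholds out of documented range")
  }
  structure(list(alignments_dir = alignments_dir, annotations = annotations,
                 variant_tables = variant_tables, out_dir = out_dir,
                 ref_pattern = ref_pattern, cadd_min = cadd_min,
                 score_min = score_min, window_min = window_min,
                 aa_conserved_min = aa_conserved_min,
                 flank_up = as.integer(flank_up),
                 flank_down = as.integer(flank_down)),
            class = "pipeline_config")
}

.ov_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reads the per-gene alignments, filters sequences, computes conservation
#' profiles, builds the cross-paralog position table, integrates the
#' variant tables into site summaries, applies the prioritization rules,
#' computes per-gene/per-source domain enrichment, and writes the report
#' bundle: `profiles.tsv`, `paralog_table.tsv`, `site_summaries.tsv`,
#' `overlap_categories.tsv`, `priority_calls.tsv`, `enrichment.tsv`,
#' `filter_log.tsv`, `summary.json`, and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  fasta <- sort(list.files(config$alignments_dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  if (length(fasta) == 0L) {
    stop("no FASTA alignments found in ", config$alignments_dir)
  }
  annotations <- read_domain_annotations(config$annotations)

  profiles <- list()
  alignments <- list()
  filter_log <- list()
  for (path in fasta) {
    gene <- tools::file_path_sans_ext(basename(path))
    dna <- Biostrings::readDNAStringSet(path)
    seqs <- stats::setNames(as.character(dna), names(dna))
    ref_hits <- grep(config$ref_pattern, names(seqs), value = TRUE)
    if (length(ref_hits) == 0L) {
      stop("no reference matching '", config$ref_pattern, "' in ", path)
    }
    flt <- filter_sequences(seqs, ref_id = ref_hits[[1L]])
    if (nrow(flt$rejections)) {
      filter_log[[gene]] <- cbind(gene = gene, flt$rejections)
    }
    aln <- codon_alignment(flt$kept, ref_id = ref_hits[[1L]], gene = gene)
    alignments[[gene]] <- aln
    profiles[[gene]] <- conservation_profile(
      aln, aa_conserved_min = config$aa_conserved_min)
  }
  profile_tab <- do.call(rbind, unname(profiles))
  filter_tab <- if (length(filter_log)) {
    do.call(rbind, unname(filter_log))
  } else {
    data.frame(gene = character(0), id = character(0), rule = character(0),
               detail = character(0))
  }

  genes <- names(alignments)
  proteins <- vapply(genes, function(g) {
    paste(reference_codons(alignments[[g]])$ref_aa, collapse = "")
  }, character(1))
  have_ann <- intersect(genes, names(annotations))
  paralog <- build_paralog_table(proteins[have_ann],
                                 annotations[have_ann],
                                 profiles[have_ann],
                                 flank_up = config$flank_up,
                                 flank_down = config$flank_down)

  records <- do.call(bind_variant_records, c(
    lapply(names(config$variant_tables), function(src) {
      read_variants_tsv(config$variant_tables[[src]], src)
    })
  ))
  summaries <- annotate_sites(records, annotations, profiles)
  categories <- overlap_categories(summaries)

  clinical <- summaries[.ov_has_source(summaries$sources,
                                       .ov_clinical_sources) &
                          summaries$in_domain %in% TRUE, , drop = FALSE]
  cp <- cross_paralog_clinvar_positions(
    clinical[c("gene", "domain_pos", "n_alt")])

  g2m_sites <- summaries[.ov_has_source(summaries$sources, "geno2mp"), ,
                         drop = FALSE]
  g2m_calls <- filter_geno2mp_hmg(g2m_sites, cadd_min = config$cadd_min,
                                  score_min = config$score_min,
                                  clinvar_positions = cp$position_genes)
  outside_calls <- prioritize_outside_domain(
    summaries, score_min = config$score_min,
    window_min = config$window_min)

  cosmic <- records[records$source == "cosmic", , drop = FALSE]
  if (nrow(cosmic)) {
    ann_start <- vapply(cosmic$gene, function(g) {
      a <- annotations[[g]]
      if (is.null(a)) NA_integer_ else a$start
    }, integer(1))
    ann_end <- vapply(cosmic$gene, function(g) {
      a <- annotations[[g]]
      if (is.null(a)) NA_integer_ else a$end
    }, integer(1))
    cosmic$in_domain <- cosmic$protein_pos >= ann_start &
      cosmic$protein_pos <= ann_end
    cosmic$domain_pos <- ifelse(
      is.na(ann_start), NA_integer_,
      ifelse(cosmic$protein_pos >= ann_start,
             cosmic$protein_pos - ann_start + 1L,
             cosmic$protein_pos - ann_start))
  } else {
    cosmic$in_domain <- logical(0)
    cosmic$domain_pos <- integer(0)
    cosmic$tissue <- character(0)
    cosmic$histology <- character(0)
  }
  cosmic_summary <- cosmic_highrisk_summary(
    cosmic, cp$position_genes$domain_pos)

  enrichment <- do.call(rbind, lapply(have_ann, function(g) {
    ann <- annotations[[g]]
    plen <- if (!is.na(ann$protein_length)) ann$protein_length else
      nchar(proteins[[g]])
    srcs <- unique(records$source[records$gene == g])
    if (length(srcs) == 0L) return(NULL)
    data.frame(gene = g, source = srcs,
               enrichment = vapply(srcs, function(s) {
                 hmg_enrichment(records, g, s, ann, protein_length = plen)
               }, numeric(1)), row.names = NULL)
  }))
  if (is.null(enrichment)) {
    enrichment <- data.frame(gene = character(0), source = character(0),
                             enrichment = numeric(0))
  }

  calls <- bind_variant_records(
    if (nrow(g2m_calls)) g2m_calls else NULL,
    if (nrow(outside_calls)) outside_calls else NULL)

  summary <- list(
    n_genes = length(genes),
    n_sequences_removed = nrow(filter_tab),
    n_variant_records = nrow(records),
    n_variant_sites = nrow(summaries),
    n_multi_paralog = cp$n_multi_paralog,
    n_multi_change = cp$n_multi_change,
    n_geno2mp_calls = nrow(g2m_calls),
    n_outside_calls = nrow(outside_calls),
    n_cosmic_retained = cosmic_summary$n_retained
  )

  out <- config$out_dir
  files <- c(
    profiles = .ov_write_tsv(profile_tab, file.path(out, "profiles.tsv")),
    paralog_table = .ov_write_tsv(paralog$positions,
                                  file.path(out, "paralog_table.tsv")),
    site_summaries = .ov_write_tsv(summaries,
                                   file.path(out, "site_summaries.tsv")),
    overlap_categories = .ov_write_tsv(
      categories, file.path(out, "overlap_categories.tsv")),
    priority_calls = .ov_write_tsv(calls,
                                   file.path(out, "priority_calls.tsv")),
    enrichment = .ov_write_tsv(enrichment,
                               file.path(out, "enrichment.tsv")),
    filter_log = .ov_write_tsv(filter_tab,
                               file.path(out, "filter_log.tsv"))
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(files = as.list(files),
                   summary = "summary.json",
                   thresholds = list(cadd_min = config$cadd_min,
                                     score_min = config$score_min,
                                     window_min = config$window_min,
                                     aa_conserved_min =
                                       config$aa_conserved_min))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(alignments = alignments, profiles = profiles,
                 paralog_table = paralog, records = records,
                 summaries = summaries, categories = categories,
                 cross_paralog = cp, geno2mp_calls = g2m_calls,
                 outside_calls = outside_calls,
                 cosmic_summary = cosmic_summary,
                 enrichment = enrichment, filter_log = filter_tab,
                 summary = summary))
}
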