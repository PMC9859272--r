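# Synthetic paralog-family generator with full ground truth.
#
# The generator emulates the statistical structure the pipeline is built
# for: a family of ~20 genes, each with ~50-150 ortholog ORFs, sharing a
# highly conserved ~79-codon domain with variable flanks. Evolution is
# simulated on a star tree - each ortholog mutated independently from the
# human reference - because every downstream statistic is
# reference-anchored, which also keeps the recorded truth exactly equal to
# what the counting statistics must return. Each codon of each ortholog
# undergoes at most one substitution event, drawn uniformly from the
# single-nucleotide neighbors of the reference codon in the required
# synonymous/nonsynonymous class; when the class is empty (e.g. no
# synonymous neighbor of ATG) the codon is left unchanged and the truth
# records the failed draw.

#' Configuration for the synthetic family generator
#'
#' Defaults state the emulated world: 20 paralogs, 100 species each, a
#' 79-codon conserved domain (positions 61-139 of a 200-codon protein)
#' under strong purifying selection (5% of substitutions nonsynonymous)
#' with permissive flanks (80% nonsynonymous), 30% per-codon per-species
#' substitution probability in both regions.
#'
#' @param n_genes Number of paralogs.
#' @param species_per_gene Sequences per gene including the reference.
#' @param protein_length Codons per protein (must be >= 21, the sliding
#'   window width).
#' @param domain_start,domain_end 1-based codon bounds of the conserved
#'   domain.
#' @param p_sub_domain,p_sub_flank Per-codon per-species substitution
#'   probabilities by region.
#' @param omega_domain,omega_flank Fraction of substitutions that are
#'   nonsynonymous by region.
#' @param n_variants_per_source Named integer vector of planted variant
#'   counts for sources gnomad, clinvar, geno2mp, cosmic.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(n_genes = 20L,
                              species_per_gene = 100L,
                              protein_length = 200L,
                              domain_start = 61L,
                              domain_end = 139L,
                              p_sub_domain = 0.3,
                              p_sub_flank = 0.3,
                              omega_domain = 0.05,
                              omega_flank = 0.8,
                              n_variants_per_source = c(gnomad = 40L,
                                                        clinvar = 12L,
                                                        geno2mp = 25L,
                                                        cosmic = 30L),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              species_per_gene = as.integer(species_per_gene),
              protein_length = as.integer(protein_length),
              domain_start = as.integer(domain_start),
              domain_end = as.integer(domain_end),
              p_sub_domain = p_sub_domain, p_sub_flank = p_sub_flank,
              omega_domain = omega_domain, omega_flank = omega_flank,
              n_variants_per_source = n_variants_per_source,
              seed = as.integer(seed))
  if (cfg$protein_length < 21L) {
    stop("protein_length must be >= 21 (the sliding window is undefined below)")
  }
  if (!(cfg$domain_start >= 1L && cfg$domain_start <= cfg$domain_end &&
        cfg$domain_end <= cfg$protein_length)) {
    stop("need 1 <= domain_start <= domain_end <= protein_length")
  }
  probs <- c(cfg$p_sub_domain, cfg$p_sub_flank,
             cfg$omega_domain, cfg$omega_flank)
  if (any(probs < 0 | probs > 1)) {
    stop("substitution probabilities and omegas must lie in [0, 1]")
  }
  if (cfg$n_genes < 1L || cfg$species_per_gene < 2L) {
    stop("need at least 1 gene and 2 species per gene")
  }
  wanted <- c("gnomad", "clinvar", "geno2mp", "cosmic")
  if (!all(wanted %in% names(cfg$n_variants_per_source))) {
    stop("n_variants_per_source must name: ", paste(wanted, collapse = ", "))
  }
  class(cfg) <- "family_sim_config"
  cfg
}

# Region label per codon: "domain" or "flank".
.ov_region_labels <- function(cfg) {
  region <- rep("flank", cfg$protein_length)
  region[cfg$domain_start:cfg$domain_end] <- "domain"
  region
}

#' Simulate ortholog codon alignments for a synthetic family
#'
#' @param config A [family_sim_config()].
#' @return List with `alignments` (named list of [codon_alignment()], one
#'   per gene) and `truth` (list with `counts`: data frame `gene`,
#'   `codon_index`, `region`, `s`, `n`, `n_failed`; and `config`).
#' @export
simulate_orthologs <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  sense <- sense_codons()
  region <- .ov_region_labels(config)
  p_sub <- ifelse(region == "domain", config$p_sub_domain, config$p_sub_flank)
  omega <- ifelse(region == "domain", config$omega_domain, config$omega_flank)
  L <- config$protein_length
  n_orth <- config$species_per_gene - 1L

  alignments <- vector("list", config$n_genes)
  counts <- vector("list", config$n_genes)
  gene_ids <- sprintf("GENE%02d", seq_len(config$n_genes))

  for (gi in seq_len(config$n_genes)) {
    gene <- gene_ids[gi]
    ref <- sample(sense, L, replace = TRUE)
    mat <- matrix(rep(ref, each = n_orth), nrow = n_orth)

    hit <- matrix(stats::runif(n_orth * L), nrow = n_orth) <
      matrix(rep(p_sub, each = n_orth), nrow = n_orth)
    is_nonsyn <- matrix(stats::runif(n_orth * L), nrow = n_orth) <
      matrix(rep(omega, each = n_orth), nrow = n_orth)

    s_count <- integer(L)
    n_count <- integer(L)
    fail_count <- integer(L)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      # order events by codon then species so draws are reproducible
      idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
      for (k in seq_len(nrow(idx))) {
        row <- idx[k, 1L]
        col <- idx[k, 2L]
        cls <- if (is_nonsyn[row, col]) "nonsyn" else "syn"
        nb <- .ov_class_neighbors(ref[col], cls)
        if (length(nb) == 0L) {
          fail_count[col] <- fail_count[col] + 1L
        } else {
          mat[row, col] <- nb[sample.int(length(nb), 1L)]
          if (cls == "syn") {
            s_count[col] <- s_count[col] + 1L
          } else {
            n_count[col] <- n_count[col] + 1L
          }
        }
      }
    }

    seqs <- c(
      stats::setNames(paste(ref, collapse = ""), paste0(gene, "_human")),
      stats::setNames(apply(mat, 1L, paste, collapse = ""),
                      sprintf("%s_sp%03d", gene, seq_len(n_orth)))
    )
    alignments[[gi]] <- codon_alignment(seqs, ref_id = paste0(gene, "_human"),
                                        gene = gene)
    counts[[gi]] <- data.frame(gene = gene, codon_index = seq_len(L),
                               region = region, s = s_count, n = n_count,
                               n_failed = fail_count, row.names = NULL)
  }
  names(alignments) <- gene_ids
  list(alignments = alignments,
       truth = list(counts = do.call(rbind, counts), config = config))
}

.ov_sim_tissues <- c("large_intestine", "lung", "skin", "stomach", "breast")
.ov_sim_histologies <- c("adenocarcinoma", "squamous_cell_carcinoma",
                         "carcinoma_NS")
.ov_sim_significance <- c("Pathogenic", "Likely_pathogenic",
                          "Uncertain_significance", "Benign")

#' Simulate variant tables in the four database schemas
#'
#' Plants variant sites on the simulated reference proteins and emits one
#' table per source schema. Sites are drawn from a shared pool so that
#' cross-database overlap categories are populated; each source samples
#' its sites without replacement from the pool. Attributes are drawn per
#' schema: geometric-tailed allele counts (gnomad), CADD-like scores and
#' phenotype-profile counts (geno2mp), a significance string (clinvar),
#' tissue/histology labels (cosmic).
#'
#' @param config The [family_sim_config()] used for [simulate_orthologs()].
#' @param sim The result of [simulate_orthologs()].
#' @return List with `tables` (named list of data frames: gnomad, clinvar,
#'   geno2mp, cosmic) and `truth` (data frame of planted sites with
#'   `gene`, `protein_pos`, `ref_aa`, `alt_aa`, `region`, `in_domain`,
#'   `sources`).
#' @export
simulate_variant_tables <- function(config, sim) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed + 1000003L)
  nv <- config$n_variants_per_source
  aas <- setdiff(unique(unname(codon_to_aa(sense_codons()))), "*")

  # shared site pool so source memberships overlap
  pool_size <- max(sum(nv) %/% 2L, max(nv), 1L)
  genes <- names(sim$alignments)
  pool_gene <- genes[sample.int(length(genes), pool_size, replace = TRUE)]
  pool_pos <- sample.int(config$protein_length, pool_size, replace = TRUE)
  key <- paste(pool_gene, pool_pos)
  dup <- duplicated(key)
  pool_gene <- pool_gene[!dup]
  pool_pos <- pool_pos[!dup]
  pool_size <- length(pool_gene)
  pool_ref <- vapply(seq_len(pool_size), function(i) {
    ref <- reference_codons(sim$alignments[[pool_gene[i]]])
    ref$ref_aa[pool_pos[i]]
  }, character(1))
  pool_alt <- vapply(pool_ref, function(r) {
    sample(setdiff(aas, r), 1L)
  }, character(1), USE.NAMES = FALSE)

  pick <- function(n) {
    if (n == 0L) return(integer(0))
    sample.int(pool_size, min(n, pool_size))
  }
  membership <- lapply(c(gnomad = "gnomad", clinvar = "clinvar",
                         geno2mp = "geno2mp", cosmic = "cosmic"),
                       function(src) pick(nv[[src]]))

  base_cols <- function(i) {
    data.frame(gene = pool_gene[i], protein_pos = pool_pos[i],
               ref_aa = pool_ref[i], alt_aa = pool_alt[i],
               stringsAsFactors = FALSE)
  }
  empty_base <- data.frame(gene = character(0), protein_pos = integer(0),
                           ref_aa = character(0), alt_aa = character(0))

  tables <- list()
  i <- membership$gnomad
  tables$gnomad <- if (length(i)) {
    ac <- stats::rgeom(length(i), prob = 0.1) + 1L
    cbind(base_cols(i),
          allele_count = ac,
          allele_frequency = signif(ac / 140000, 3),
          rsid = sprintf("rs%07d", seq_along(i)))
  } else cbind(empty_base, allele_count = numeric(0),
               allele_frequency = numeric(0), rsid = character(0))

  i <- membership$clinvar
  tables$clinvar <- if (length(i)) {
    cbind(base_cols(i),
          significance = sample(.ov_sim_significance, length(i),
                                replace = TRUE),
          condition = "simulated condition")
  } else cbind(empty_base, significance = character(0),
               condition = character(0))

  i <- membership$geno2mp
  tables$geno2mp <- if (length(i)) {
    cbind(base_cols(i),
          cadd = round(stats::runif(length(i), 5, 45), 1),
          hpo_profile_count = stats::rpois(length(i), 1) + 1L)
  } else cbind(empty_base, cadd = numeric(0), hpo_profile_count = numeric(0))

  i <- membership$cosmic
  tables$cosmic <- if (length(i)) {
    cbind(base_cols(i),
          tissue = sample(.ov_sim_tissues, length(i), replace = TRUE),
          histology = sample(.ov_sim_histologies, length(i), replace = TRUE))
  } else cbind(empty_base, tissue = character(0), histology = character(0))

  planted <- sort(unique(unlist(membership)))
  region <- .ov_region_labels(config)
  truth <- if (length(planted)) {
    data.frame(
      gene = pool_gene[planted], protein_pos = pool_pos[planted],
      ref_aa = pool_ref[planted], alt_aa = pool_alt[planted],
      region = region[pool_pos[planted]],
      in_domain = region[pool_pos[planted]] == "domain",
      sources = vapply(planted, function(i) {
        paste(sort(names(membership)[vapply(membership, function(m)
          i %in% m, logical(1))]), collapse = "+")
      }, character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), protein_pos = integer(0),
               ref_aa = character(0), alt_aa = character(0),
               region = character(0), in_domain = logical(0),
               sources = character(0))
  }
  list(tables = tables, truth = truth)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the simulated family as pipeline-ready files: one aligned FASTA
#' per gene under `alignments/`, a domain annotation TSV, the four variant
#' TSVs, the ground-truth tables, a flat key=value copy of the
#' configuration, and copies of the packaged curated reference tables.
#'
#' @param config A [family_sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_fixtures <- function(config, outdir) {
  stopifnot(inherits(config, "family_sim_config"))
  dir.create(file.path(outdir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)

  sim <- simulate_orthologs(config)
  var <- simulate_variant_tables(config, sim)

  paths <- list()
  for (gene in names(sim$alignments)) {
    p <- file.path(outdir, "alignments", paste0(gene, ".fasta"))
    write_codon_alignment(sim$alignments[[gene]], p)
    paths[[paste0("alignment_", gene)]] <- p
  }

  ann <- data.frame(gene = names(sim$alignments), domain = "DOMAIN",
                    start = config$domain_start, end = config$domain_end,
                    protein_length = config$protein_length)
  paths$annotations <- file.path(outdir, "annotations.tsv")
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  for (src in names(var$tables)) {
    p <- file.path(outdir, paste0("variants_", src, ".tsv"))
    utils::write.table(var$tables[[src]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("variants_", src)]] <- p
  }

  paths$truth_counts <- file.path(outdir, "truth_counts.tsv")
  utils::write.table(sim$truth$counts, paths$truth_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth_variants <- file.path(outdir, "truth_variants.tsv")
  utils::write.table(var$truth, paths$truth_variants, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  flat <- config[c("n_genes", "species_per_gene", "protein_length",
                   "domain_start", "domain_end", "p_sub_domain",
                   "p_sub_flank", "omega_domain", "omega_flank", "seed")]
  cfg_lines <- c(paste0(names(flat), "=", unlist(flat)),
                 paste0("n_variants_", names(config$n_variants_per_source),
                        "=", config$n_variants_per_source))
  paths$config <- file.path(outdir, "config.txt")
  writeLines(cfg_lines, paths$config)

  for (fx in c("table1", "table3", "table4", "table5")) {
    src <- system.file("extdata", paste0(fx, ".tsv"), package = "orthovar")
    if (nzchar(src)) {
      p <- file.path(outdir, paste0(fx, ".tsv"))
      file.copy(src, p, overwrite = TRUE)
      paths[[fx]] <- p
    }
  }
  invisible(paths)
}
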