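#' Pipeline configuration
#'
#' Bundles every tunable of the per-genome and cohort stages with its
#' documented default. The configuration (and its hash) is echoed into
#' every report and output file for provenance.
#'
#' @param drop_terminal_stop Exclude a terminal stop codon from frequency
#'   counting? Default `FALSE` (count every complete codon).
#' @param min_genes Minimum usable genes per genome, default 50.
#' @param k_range Candidate cluster counts for model selection, default 2:9.
#' @param seed Clustering seed, default 20170326.
#' @param n_restarts K-means restarts, default 50.
#' @param silhouette_subsample_cap Subsample cap for silhouette scoring;
#'   `Inf` (default) scores every point.
#' @param threshold_mode Overrepresentation threshold mode, `"relative"`
#'   (default) or `"absolute"`.
#' @param threshold Overrepresentation threshold, default 0.05.
#' @param category_policy Multi-letter counting policy, `"first_letter"`
#'   (default) or `"all_letters"`.
#' @param min_genomes_per_phylum Strict lower bound for phylum retention,
#'   default 10.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' pipeline_config(n_restarts = 10)
#' @export
pipeline_config <- function(drop_terminal_stop = FALSE,
                            min_genes = 50L,
                            k_range = 2:9,
                            seed = 20170326L,
                            n_restarts = 50L,
                            silhouette_subsample_cap = Inf,
                            threshold_mode = c("relative", "absolute"),
                            threshold = 0.05,
                            category_policy = c("first_letter", "all_letters"),
                            min_genomes_per_phylum = 10L) {
  cfg <- list(
    drop_terminal_stop = isTRUE(drop_terminal_stop),
    min_genes = as.integer(min_genes),
    k_range = as.integer(k_range),
    seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    silhouette_subsample_cap = silhouette_subsample_cap,
    threshold_mode = match.arg(threshold_mode),
    threshold = threshold,
    category_policy = match.arg(category_policy),
    min_genomes_per_phylum = as.integer(min_genomes_per_phylum)
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("codonclust pipeline config (hash", config_hash(x), ")\n")
  for (nm in names(x)) {
    cat(sprintf("  %-25s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1L, 12L)
}

# resolve the `genes` argument of run_genome to a (tibble, genome_id) pair
resolve_genes <- function(genes, genome_id) {
  if (inherits(genes, "synthetic_genome")) {
    return(list(genes = genes$genes,
                genome_id = genome_id %||% genes$genome_id))
  }
  if (is.character(genes) && length(genes) == 1L) {
    tbl <- read_cds_fasta(genes, genome_id = genome_id)
    return(list(genes = tbl,
                genome_id = genome_id %||% tbl$genome_id[1]))
  }
  stopifnot(is.data.frame(genes))
  list(genes = genes, genome_id = genome_id %||% "genome")
}

resolve_annotation <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  if (is.character(annotation) && length(annotation) == 1L) {
    return(read_cog_annotation(annotation))
  }
  stopifnot(is.data.frame(annotation))
  annotation
}

#' Run the full per-genome pipeline
#'
#' Frequency profiling, clustering with silhouette model selection, and —
#' when an annotation is supplied — COG category enrichment, optionally
#' writing every stage's output files. Progress is logged with
#' [message()] so machine outputs stay clean.
#'
#' @param genes A CDS FASTA path, a tibble with `gene_id`/`sequence`
#'   columns, or a [simulate_genome()] result.
#' @param annotation A COG annotation path (`.ptt` or two-column TSV), a
#'   tibble from [read_cog_annotation()], or `NULL` for clustering-only.
#' @param config A [pipeline_config()].
#' @param genome_id Genome identifier; inferred from the input when `NULL`.
#' @param out_dir If non-`NULL`, the frequency TSV, cluster assignment
#'   TSV, centroid TSV, silhouette JSON and (given annotation) enrichment
#'   JSON + TSV are written there, each stamped with the package version
#'   and configuration hash.
#' @return An object of class `genome_report`: a list with `genome_id`,
#'   `freqs`, `clustering`, `enrichment` (`NULL` without annotation) and
#'   `config`.
#' @examples
#' g <- simulate_genome("demo", n_genes = 150, seed = 3)
#' rep <- run_genome(g, genome_annotation(g),
#'                   config = pipeline_config(n_restarts = 10, k_range = 2:4))
#' rep$clustering$optimal_k
#' @export
run_genome <- function(genes, annotation = NULL, config = pipeline_config(),
                       genome_id = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gin <- resolve_genes(genes, genome_id)
  ann <- resolve_annotation(annotation)
  n_in <- nrow(gin$genes)
  freqs <- genome_frequency_table(gin$genes,
                                  drop_terminal_stop = config$drop_terminal_stop,
                                  min_genes = config$min_genes)
  message(gin$genome_id, ": ", n_in, " genes read, ", nrow(freqs), " usable")
  clustering <- cluster_genome(freqs, genome_id = gin$genome_id,
                               k_range = config$k_range, seed = config$seed,
                               n_restarts = config$n_restarts,
                               subsample_cap = config$silhouette_subsample_cap)
  message(gin$genome_id, ": optimal K = ", clustering$optimal_k,
          ", small/large = ", clustering$small_size, "/",
          clustering$large_size)
  enrichment <- NULL
  if (!is.null(ann)) {
    enrichment <- enrich_genome(clustering, ann,
                                policy = config$category_policy,
                                threshold_mode = config$threshold_mode,
                                threshold = config$threshold,
                                genome_id = gin$genome_id)
    message(gin$genome_id, ": chi-squared p = ",
            format(enrichment$chi2$p_value, digits = 3))
  } else {
    message(gin$genome_id, ": no annotation supplied, clustering outputs only")
  }
  report <- structure(
    list(genome_id = gin$genome_id, freqs = freqs, clustering = clustering,
         enrichment = enrichment, config = config),
    class = "genome_report"
  )
  if (!is.null(out_dir)) write_genome_report(report, out_dir)
  report
}

write_genome_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gid <- report$genome_id
  h <- config_hash(report$config)
  v <- as.character(utils::packageVersion("codonclust"))
  write_frequency_table(report$freqs,
                        file.path(out_dir, paste0(gid, "_freqs.tsv")),
                        config_hash = h)
  cl <- report$clustering
  p1 <- file.path(out_dir, paste0(gid, "_clusters.tsv"))
  writeLines(provenance_comment(h), p1)
  readr::write_tsv(cl$assignments, p1, append = TRUE, col_names = TRUE)
  p2 <- file.path(out_dir, paste0(gid, "_centroids.tsv"))
  writeLines(provenance_comment(h), p2)
  readr::write_tsv(cl$centroids, p2, append = TRUE, col_names = TRUE)
  sil <- as.list(stats::setNames(cl$silhouette$per_k$silhouette,
                                 as.character(cl$silhouette$per_k$k)))
  sil$optimal_k <- cl$optimal_k
  sil$codonclust_version <- v
  sil$config_hash <- h
  jsonlite::write_json(sil, file.path(out_dir, paste0(gid, "_silhouette.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$enrichment)) {
    e <- report$enrichment
    cats <- lapply(seq_len(nrow(e$table)), function(i) {
      r <- e$table[i, ]
      list(n_small = r$n_small, n_large = r$n_large,
           F_small = r$F_small, F_large = r$F_large,
           ind_small = r$ind_small, ind_large = r$ind_large)
    })
    names(cats) <- e$table$category
    jsonlite::write_json(
      list(genome_id = gid, chi2 = e$chi2$statistic, dof = e$chi2$dof,
           p = e$chi2$p_value,
           dropped_categories = as.list(e$chi2$dropped_categories),
           n_small = e$n_small_total, n_large = e$n_large_total,
           policy = e$policy, threshold_mode = e$threshold_mode,
           threshold = e$threshold, categories = cats,
           codonclust_version = v, config_hash = h),
      file.path(out_dir, paste0(gid, "_enrichment.json")),
      auto_unbox = TRUE, digits = NA
    )
    p3 <- file.path(out_dir, paste0(gid, "_enrichment.tsv"))
    writeLines(provenance_comment(h), p3)
    readr::write_tsv(e$table, p3, append = TRUE, col_names = TRUE)
  }
  invisible(out_dir)
}

# enumerate genome inputs of a cohort: returns a list of
# list(genome_id, genes, annotation) triples plus the metadata tibble
resolve_cohort <- function(cohort, metadata) {
  if (inherits(cohort, "synthetic_cohort")) {
    inputs <- lapply(cohort$genomes, function(sim) {
      list(genome_id = sim$genome_id, genes = sim,
           annotation = genome_annotation(sim))
    })
    return(list(inputs = inputs, metadata = metadata %||% cohort$metadata))
  }
  stopifnot(is.character(cohort), length(cohort) == 1L, dir.exists(cohort))
  if (is.null(metadata)) {
    mp <- file.path(cohort, "metadata.tsv")
    if (!file.exists(mp)) {
      abort("cohort directory has no metadata.tsv and no metadata was supplied",
            class = "codonclust_input_error")
    }
    metadata <- readr::read_tsv(mp, col_types = readr::cols())
  } else if (is.character(metadata)) {
    metadata <- readr::read_tsv(metadata, col_types = readr::cols())
  }
  subdirs <- list.dirs(cohort, recursive = FALSE)
  inputs <- list()
  for (d in subdirs) {
    fasta <- list.files(d, pattern = "\\.(ffn|fna|fa|fasta)$",
                        full.names = TRUE)
    if (length(fasta) == 0L) next
    ann <- list.files(d, pattern = "(cog\\.tsv|\\.ptt)$", full.names = TRUE)
    gid <- basename(d)
    inputs[[gid]] <- list(genome_id = gid, genes = fasta[1L],
                          annotation = if (length(ann)) ann[1L] else NULL)
  }
  if (length(inputs) == 0L) {
    abort("no genome subdirectory with a FASTA file found",
          class = "codonclust_input_error")
  }
  list(inputs = inputs, metadata = metadata)
}

#' Run the pipeline over a cohort and aggregate
#'
#' Runs [run_genome()] on every genome (a genome that fails — e.g. too
#' few usable genes — is recorded in `skipped` and the cohort completes),
#' then aggregates the per-genome verdicts: chi-squared significance
#' summary, cumulative per-category overrepresentation, per-phylum ratios
#' and the cross-phylum consistency classification.
#'
#' @param cohort A [simulate_cohort()] result, or a directory with one
#'   subdirectory per genome (each holding a CDS FASTA and optionally a
#'   `*.cog.tsv` / `*.ptt` annotation) and a `metadata.tsv`.
#' @param metadata A tibble or TSV path with `genome_id`, `phylum`
#'   columns; optional when the cohort carries its own metadata. Genomes
#'   without a metadata row are an error listing the orphans.
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, per-genome outputs go to
#'   `out_dir/<genome_id>/` and the four cohort summary TSVs to `out_dir`.
#' @return An object of class `cohort_report`: a list with `reports`
#'   (per-genome [run_genome()] bundles), `verdicts`, `significance`,
#'   `cumulative`, `phylum_ratios`, `consistency` (`NULL` with fewer than
#'   2 phyla), `skipped` (tibble `genome_id`, `reason`) and `config`.
#' @export
run_cohort <- function(cohort, metadata = NULL, config = pipeline_config(),
                       out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rc <- resolve_cohort(cohort, metadata)
  reports <- list()
  skipped <- list()
  for (inp in rc$inputs) {
    rep <- tryCatch(
      run_genome(inp$genes, inp$annotation, config = config,
                 genome_id = inp$genome_id,
                 out_dir = if (is.null(out_dir)) NULL
                           else file.path(out_dir, inp$genome_id)),
      error = function(e) {
        warn(paste0("skipping genome ", inp$genome_id, ": ",
                    conditionMessage(e)))
        NULL
      }
    )
    if (is.null(rep)) {
      skipped[[inp$genome_id]] <- tibble(genome_id = inp$genome_id,
                                         reason = "failed")
    } else {
      reports[[inp$genome_id]] <- rep
    }
  }
  with_enrichment <- purrr::keep(reports, ~ !is.null(.x$enrichment))
  if (length(with_enrichment) == 0L) {
    abort("no genome produced an enrichment result; cannot aggregate",
          class = "codonclust_input_error")
  }
  verdicts <- cohort_verdicts(with_enrichment, rc$metadata)
  significance <- significance_summary(verdicts)
  cumulative <- cumulative_overrepresentation(verdicts)
  ratios <- phylum_ratios(verdicts, min_genomes = config$min_genomes_per_phylum)
  consistency <- NULL
  if (nrow(ratios) > 0L && n_distinct(ratios$phylum) >= 2L) {
    consistency <- consistency_matrix(ratios)
  }
  out <- structure(
    list(reports = reports, verdicts = verdicts, significance = significance,
         cumulative = cumulative, phylum_ratios = ratios,
         consistency = consistency,
         skipped = if (length(skipped)) bind_rows(skipped)
                   else tibble(genome_id = character(), reason = character()),
         config = config),
    class = "cohort_report"
  )
  if (!is.null(out_dir)) write_cohort_report(out, out_dir)
  out
}

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(report$config)
  wr <- function(tbl, name) {
    p <- file.path(out_dir, name)
    writeLines(provenance_comment(h), p)
    readr::write_tsv(tbl, p, append = TRUE, col_names = TRUE)
  }
  wr(report$significance, "cohort_significance.tsv")
  wr(report$cumulative, "cohort_cumulative.tsv")
  wr(report$phylum_ratios, "cohort_phylum_ratios.tsv")
  if (!is.null(report$consistency)) {
    wr(report$consistency, "cohort_consistency.tsv")
  }
  if (nrow(report$skipped) > 0L) wr(report$skipped, "cohort_skipped.tsv")
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report:", length(x$reports), "genomes analyzed,",
      nrow(x$skipped), "skipped\n")
  print(x$significance)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
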