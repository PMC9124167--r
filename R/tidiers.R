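#' Tidy a genome clustering
#'
#' @param x A [cluster_genome()] result.
#' @param ... Unused.
#' @return The per-gene assignment tibble: `gene_id`, `fA2`, `fT2`,
#'   `cluster`.
#' @export
#' @exportS3Method generics::tidy
tidy.genome_clustering <- function(x, ...) {
  x$assignments
}

#' One-row summary of a genome clustering
#'
#' @param x A [cluster_genome()] result.
#' @param ... Unused.
#' @return A one-row tibble: `genome_id`, `n_genes`, `optimal_k`,
#'   `small_size`, `large_size`, `silhouette_k2` (mean silhouette of the
#'   K = 2 partition), `inertia_k2`.
#' @export
#' @exportS3Method generics::glance
glance.genome_clustering <- function(x, ...) {
  s2 <- x$silhouette$per_k$silhouette[x$silhouette$per_k$k == 2L]
  tibble(
    genome_id = x$genome_id,
    n_genes = x$n_genes,
    optimal_k = x$optimal_k,
    small_size = x$small_size,
    large_size = x$large_size,
    silhouette_k2 = if (length(s2)) s2 else NA_real_,
    inertia_k2 = x$inertia
  )
}

#' Tidy a per-genome enrichment result
#'
#' @param x An [enrich_genome()] result.
#' @param ... Unused.
#' @return The 26-row per-category tibble (counts, proportions,
#'   indicators).
#' @export
#' @exportS3Method generics::tidy
tidy.cog_enrichment <- function(x, ...) {
  x$table
}

#' One-row summary of a per-genome enrichment result
#'
#' @param x An [enrich_genome()] result.
#' @param ... Unused.
#' @return A one-row tibble: `genome_id`, `statistic`, `dof`, `p_value`,
#'   `n_small`, `n_large`, `n_overrep_small`, `n_overrep_large`.
#' @export
#' @exportS3Method generics::glance
glance.cog_enrichment <- function(x, ...) {
  tibble(
    genome_id = x$genome_id,
    statistic = x$chi2$statistic,
    dof = x$chi2$dof,
    p_value = x$chi2$p_value,
    n_small = x$n_small_total,
    n_large = x$n_large_total,
    n_overrep_small = sum(x$table$ind_small),
    n_overrep_large = sum(x$table$ind_large)
  )
}

#' Tidy a cohort report
#'
#' @param x A [run_cohort()] result.
#' @param ... Unused.
#' @return The long verdict table (genome x category indicators).
#' @export
#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  x$verdicts
}

#' Per-genome summary of a cohort report
#'
#' @param x A [run_cohort()] result.
#' @param ... Unused.
#' @return One row per analyzed genome, combining the clustering and
#'   enrichment glances.
#' @export
#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  purrr::map_dfr(x$reports, function(r) {
    g <- glance(r$clustering)
    if (!is.null(r$enrichment)) {
      e <- glance(r$enrichment)
      g <- bind_cols(g, e[, setdiff(names(e), "genome_id")])
    }
    g
  })
}
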