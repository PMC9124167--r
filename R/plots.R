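#' Scatter plot of a genome's genes in (f(A2), f(T2)) space
#'
#' The classic per-genome view: one point per gene, colored by the
#' SMALL/LARGE designation of the K = 2 partition, with the cluster
#' centroids overplotted. Axes span 0-0.7.
#'
#' @param object A [cluster_genome()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genome_clustering <- function(object, ...) {
  ggplot(object$assignments, aes(x = .data$fA2, y = .data$fT2,
                                 color = .data$cluster)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_point(data = object$centroids, shape = 4, size = 4,
               stroke = 1.5, color = "black") +
    scale_color_manual(values = c(SMALL = "#D55E00", LARGE = "#0072B2")) +
    coord_fixed(xlim = c(0, 0.7), ylim = c(0, 0.7)) +
    labs(title = object$genome_id,
         subtitle = sprintf("optimal K = %d; small/large = %d/%d",
                            object$optimal_k, object$small_size,
                            object$large_size),
         x = "f(A2)", y = "f(T2)", color = "cluster") +
    theme_minimal()
}

#' Silhouette profile across candidate K
#'
#' @param object A [select_optimal_k()] result.
#' @param ... Unused.
#' @return A ggplot object: mean silhouette against K, optimum marked.
#' @export
autoplot.silhouette_profile <- function(object, ...) {
  ggplot(object$per_k, aes(x = .data$k, y = .data$silhouette)) +
    geom_line() +
    geom_point() +
    geom_point(data = object$per_k[object$per_k$k == object$optimal_k, ],
               color = "#D55E00", size = 3) +
    scale_x_continuous(breaks = object$per_k$k) +
    labs(x = "K", y = "mean silhouette coefficient") +
    theme_minimal()
}

#' Paired category proportions of the small and large clusters
#'
#' Side-by-side bars of F(category) in each cluster, in super-category
#' letter order.
#'
#' @param object An [enrich_genome()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cog_enrichment <- function(object, ...) {
  long <- object$table |>
    select("category", "F_small", "F_large") |>
    tidyr::pivot_longer(c("F_small", "F_large"), names_to = "cluster",
                        names_prefix = "F_", values_to = "proportion") |>
    mutate(cluster = toupper(.data$cluster),
           category = factor(.data$category, levels = COG_LETTERS))
  ggplot(long, aes(x = .data$category, y = .data$proportion,
                   fill = .data$cluster)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(SMALL = "#D55E00", LARGE = "#0072B2")) +
    labs(title = object$genome_id,
         subtitle = sprintf("chi-squared p = %.3g (%s threshold %.2f)",
                            object$chi2$p_value, object$threshold_mode,
                            object$threshold),
         x = "COG category", y = "proportion of annotated genes") +
    theme_minimal()
}

#' Heatmap of per-phylum overrepresentation ratios
#'
#' Long-format tile plot of the small-cluster overrepresentation ratio
#' per phylum and category: categories consistently overrepresented in
#' the small cluster appear as a uniformly dark column, large-cluster
#' ones as a uniformly light column.
#'
#' @param ratios Output of [phylum_ratios()].
#' @return A ggplot object.
#' @export
plot_phylum_ratios <- function(ratios) {
  stopifnot(all(c("phylum", "category", "ratio_small") %in% names(ratios)))
  df <- ratios |>
    mutate(category = factor(.data$category, levels = COG_LETTERS))
  ggplot(df, aes(x = .data$category, y = .data$phylum,
                 fill = .data$ratio_small)) +
    geom_tile(color = "grey80") +
    scale_fill_gradient(low = "#0072B2", high = "#D55E00",
                        limits = c(0, 1),
                        name = "small-cluster\nratio") +
    labs(x = "COG category", y = NULL) +
    theme_minimal()
}
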