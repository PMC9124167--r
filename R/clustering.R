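# coerce a points input -- tibble with fA2/fT2 (or x/y) columns, or a
# two-column numeric matrix -- to an n x 2 matrix
points_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2L, is.numeric(points))
    m <- points
    colnames(m) <- c("fA2", "fT2")
    return(m)
  }
  stopifnot(is.data.frame(points))
  cols <- if (all(c("fA2", "fT2") %in% names(points))) c("fA2", "fT2")
          else if (all(c("x", "y") %in% names(points))) c("x", "y")
          else abort("points must have columns fA2/fT2 (or x/y)")
  m <- as.matrix(points[, cols])
  colnames(m) <- c("fA2", "fT2")
  m
}

#' K-means on gene points in (f(A2), f(T2)) space
#'
#' Runs `n_restarts` independent Hartigan-Wong K-means fits (via
#' [stats::kmeans()]) from initial centers sampled among the distinct data
#' points and keeps the fit with the lowest total within-cluster sum of
#' squares. The whole procedure is a pure function of `(points, k, seed,
#' n_restarts)`.
#'
#' @param points Tibble with `fA2`/`fT2` columns (e.g. a
#'   [genome_frequency_table()]) or a two-column numeric matrix.
#' @param k Number of clusters, at least 2 and at most the number of
#'   distinct points.
#' @param seed Integer seed; the default `20170326` is the package-wide
#'   clustering seed.
#' @param n_restarts Number of random restarts (default 50).
#' @return A list with elements `k`, `labels` (integer in 1..k, one per
#'   point), `centroids` (k x 2 matrix), `inertia` (best total
#'   within-cluster SSE), `seed`, `n_restarts`.
#' @examples
#' pts <- rbind(matrix(0.1, 5, 2), matrix(0.6, 5, 2)) +
#'   matrix(stats::rnorm(20, sd = 1e-3), 10, 2)
#' kmeans_points(pts, k = 2)$inertia
#' @export
kmeans_points <- function(points, k, seed = 20170326L, n_restarts = 50L) {
  m <- points_matrix(points)
  k <- as.integer(k)
  if (k < 2L) abort("k must be at least 2")
  um <- unique(m)
  if (nrow(um) < k) {
    abort(paste0("degenerate input: ", nrow(um), " distinct point(s) for k = ", k),
          class = "codonclust_degenerate_input")
  }
  if (nrow(um) == k) {
    # one cluster per distinct point is the exact optimum (inertia 0)
    lab <- match(
      paste(m[, 1L], m[, 2L]),
      paste(um[, 1L], um[, 2L])
    )
    return(list(k = k, labels = lab, centroids = unname(um), inertia = 0,
                seed = seed, n_restarts = as.integer(n_restarts)))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- um[sample.int(nrow(um), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(m, centers = init, iter.max = 100L)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) abort("k-means failed on every restart")
  list(
    k = k,
    labels = unname(best$cluster),
    centroids = unname(best$centers),
    inertia = best$tot.withinss,
    seed = seed,
    n_restarts = as.integer(n_restarts)
  )
}

#' Mean silhouette coefficient of a labeled point set
#'
#' Rousseeuw's silhouette with Euclidean distances: for point i,
#' a(i) is the mean distance to the other members of its own cluster,
#' b(i) the smallest mean distance to any other cluster, and
#' s(i) = (b - a) / max(a, b). Singleton clusters score s(i) = 0, as does
#' the fully degenerate case a = b = 0 (coincident points split across
#' clusters). Returns the mean of s(i) over all points.
#'
#' @inheritParams kmeans_points
#' @param labels Cluster assignment, one per point; at least two clusters
#'   must be present.
#' @param dist_matrix Optional precomputed full distance matrix (as from
#'   `as.matrix(dist(...))`); supplying it lets callers score many
#'   labelings of the same points without recomputing distances.
#' @return The mean silhouette coefficient, a number in \[-1, 1\].
#' @examples
#' pts <- rbind(matrix(0, 2, 2), matrix(1, 2, 2))
#' silhouette_mean(pts, c(1, 1, 2, 2))  # 1: perfectly separated
#' @export
silhouette_mean <- function(points, labels, dist_matrix = NULL) {
  D <- if (is.null(dist_matrix)) as.matrix(stats::dist(points_matrix(points)))
       else dist_matrix
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cls <- unique(labels)
  if (length(cls) < 2L) {
    abort("silhouette undefined for a single cluster",
          class = "codonclust_degenerate_input")
  }
  S <- vapply(cls, function(cl) rowSums(D[, labels == cl, drop = FALSE]),
              numeric(n))
  sizes <- vapply(cls, function(cl) sum(labels == cl), numeric(1L))
  own <- match(labels, cls)
  a <- S[cbind(seq_len(n), own)] / (sizes[own] - 1)   # NaN for singletons
  Bm <- sweep(S, 2L, sizes, "/")
  Bm[cbind(seq_len(n), own)] <- Inf
  b <- do.call(pmin, lapply(seq_along(cls), function(j) Bm[, j]))
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1L] <- 0   # singleton rule
  s[is.nan(s)] <- 0          # a = b = 0 degenerate rule
  mean(s)
}

#' Select the optimal number of clusters by mean silhouette
#'
#' Fits K-means for every K in `k_range` (default 2--9) and scores each
#' partition by [silhouette_mean()]; the K with the highest mean silhouette
#' wins, ties breaking toward the smaller K (parsimony). The distance
#' matrix is computed once and reused across K.
#'
#' @inheritParams kmeans_points
#' @param k_range Candidate cluster counts, default `2:9`. Values exceeding
#'   the number of distinct points are skipped with a warning.
#' @param subsample_cap If finite and smaller than the number of points,
#'   silhouette scores are computed on a fixed random subsample of this
#'   size (the K-means fits still use every point). Off (`Inf`) by default;
#'   an approximation switch for very large gene sets, where the O(n^2)
#'   distance matrix dominates runtime.
#' @return An object of class `silhouette_profile`: a list with `per_k`
#'   (tibble of `k`, `silhouette`) and `optimal_k`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(stats::rnorm(100, 0.3, 0.02), ncol = 2),
#'              matrix(stats::rnorm(20, 0.5, 0.02), ncol = 2))
#' select_optimal_k(pts, n_restarts = 5)$optimal_k
#' @export
select_optimal_k <- function(points, k_range = 2:9, seed = 20170326L,
                             n_restarts = 50L, subsample_cap = Inf) {
  m <- points_matrix(points)
  n <- nrow(m)
  sub <- seq_len(n)
  if (is.finite(subsample_cap) && n > subsample_cap) {
    sub <- withr::with_seed(seed, sort(sample.int(n, subsample_cap)))
  }
  D <- as.matrix(stats::dist(m[sub, , drop = FALSE]))
  n_distinct_pts <- nrow(unique(m))
  ks <- sort(unique(as.integer(k_range)))
  feasible <- ks[ks <= n_distinct_pts & ks >= 2L]
  if (length(feasible) < length(ks)) {
    warn(paste0("skipping infeasible K values: ",
                paste(setdiff(ks, feasible), collapse = ", ")))
  }
  sil <- vapply(feasible, function(k) {
    fit <- kmeans_points(m, k, seed = seed, n_restarts = n_restarts)
    lab <- fit$labels[sub]
    if (length(unique(lab)) < 2L) return(NA_real_)
    silhouette_mean(NULL, lab, dist_matrix = D)
  }, numeric(1L))
  keep <- !is.na(sil)
  per_k <- tibble(k = feasible[keep], silhouette = sil[keep])
  if (nrow(per_k) == 0L) abort("no feasible K produced a silhouette score")
  structure(
    list(per_k = per_k, optimal_k = per_k$k[which.max(per_k$silhouette)]),
    class = "silhouette_profile"
  )
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat("Silhouette profile (optimal K =", x$optimal_k, ")\n")
  print(x$per_k)
  invisible(x)
}

#' Designate the small and large clusters of a K = 2 partition
#'
#' The cluster with fewer genes is SMALL; on an exact size tie the cluster
#' with the higher centroid f(T2) is SMALL — the small cluster is the
#' high-T2 one — and the tie is reported as a message.
#'
#' @param km A `k = 2` result from [kmeans_points()].
#' @return A list with `cluster` (character vector of `"SMALL"`/`"LARGE"`,
#'   one per point), `small_size`, `large_size`, and `centroids` (tibble of
#'   `cluster`, `fA2`, `fT2`, `size`).
#' @export
designate_small_large <- function(km) {
  if (km$k != 2L) abort("small/large designation requires a K = 2 result")
  sizes <- tabulate(km$labels, nbins = 2L)
  if (sizes[1L] == sizes[2L]) {
    small_idx <- which.max(km$centroids[, 2L])
    message("cluster size tie: SMALL assigned to the higher-f(T2) centroid")
  } else {
    small_idx <- which.min(sizes)
  }
  cluster <- ifelse(km$labels == small_idx, "SMALL", "LARGE")
  ord <- c(small_idx, setdiff(1:2, small_idx))
  list(
    cluster = cluster,
    small_size = sizes[small_idx],
    large_size = sizes[setdiff(1:2, small_idx)],
    centroids = tibble(
      cluster = c("SMALL", "LARGE"),
      fA2 = km$centroids[ord, 1L],
      fT2 = km$centroids[ord, 2L],
      size = sizes[ord]
    )
  )
}

#' Cluster a genome's genes in (f(A2), f(T2)) space
#'
#' The per-genome clustering stage: silhouette model selection over
#' `k_range`, plus the K = 2 partition with its SMALL/LARGE designation.
#' The K = 2 partition is always reported (the enrichment stage consumes
#' it) even when the silhouette-optimal K differs; `optimal_k` records the
#' model-selection outcome.
#'
#' @param freq_tbl A [genome_frequency_table()] (any tibble with `gene_id`,
#'   `fA2`, `fT2` columns).
#' @param genome_id Genome identifier carried into reports.
#' @inheritParams select_optimal_k
#' @return An object of class `genome_clustering`: a list with
#'   `genome_id`, `n_genes`, `optimal_k`, `silhouette` (a
#'   `silhouette_profile`), `assignments` (tibble `gene_id`, `fA2`, `fT2`,
#'   `cluster`), `small_size`, `large_size`, `centroids`, `inertia`,
#'   `seed`, `n_restarts`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' g <- simulate_genome("demo", n_genes = 120, seed = 7)
#' ft <- genome_frequency_table(g$genes, min_genes = 50)
#' cl <- cluster_genome(ft, genome_id = "demo", n_restarts = 10)
#' glance(cl)
#' @export
cluster_genome <- function(freq_tbl, genome_id = "genome",
                           k_range = 2:9, seed = 20170326L,
                           n_restarts = 50L, subsample_cap = Inf) {
  stopifnot(all(c("gene_id", "fA2", "fT2") %in% names(freq_tbl)))
  prof <- select_optimal_k(freq_tbl, k_range = k_range, seed = seed,
                           n_restarts = n_restarts,
                           subsample_cap = subsample_cap)
  km2 <- kmeans_points(freq_tbl, 2L, seed = seed, n_restarts = n_restarts)
  dsg <- designate_small_large(km2)
  structure(
    list(
      genome_id = genome_id,
      n_genes = nrow(freq_tbl),
      optimal_k = prof$optimal_k,
      silhouette = prof,
      assignments = tibble(
        gene_id = freq_tbl$gene_id,
        fA2 = freq_tbl$fA2,
        fT2 = freq_tbl$fT2,
        cluster = dsg$cluster
      ),
      small_size = dsg$small_size,
      large_size = dsg$large_size,
      centroids = dsg$centroids,
      inertia = km2$inertia,
      seed = seed,
      n_restarts = as.integer(n_restarts)
    ),
    class = "genome_clustering"
  )
}

#' @export
print.genome_clustering <- function(x, ...) {
  cat("Genome clustering:", x$genome_id, "\n")
  cat("  genes:", x$n_genes,
      " optimal K:", x$optimal_k,
      " small/large:", x$small_size, "/", x$large_size, "\n")
  cat("  K=2 centroids (fA2, fT2): SMALL (",
      sprintf("%.3f, %.3f", x$centroids$fA2[1], x$centroids$fT2[1]),
      ")  LARGE (",
      sprintf("%.3f, %.3f", x$centroids$fA2[2], x$centroids$fT2[2]), ")\n")
  invisible(x)
}
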