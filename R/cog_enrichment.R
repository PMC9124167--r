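#' Read a gene-to-COG-category annotation
#'
#' Two dialects are supported. `tsv` is a headerless two-column file,
#' `gene_id<TAB>letters` (e.g. `g7  P` or `g12  KL`). `ptt` is the NCBI
#' protein-table format: header lines down to the `Location ...` column
#' line, then tab-separated rows whose `COG` column holds either `-` or a
#' COG accession with trailing category letters (`COG0583K`,
#' `COG1234KL`); the locus tag in the `Synonym` column is used as the gene
#' identifier, matching RefSeq `.ffn` headers.
#'
#' Genes with no category (`-`, empty, or a bare accession) are absent
#' from the result. Category letters outside the 26-letter COG alphabet
#' are an error naming the offending line; rows that cannot be parsed at
#' all are skipped with a warning giving their count.
#'
#' @param path Annotation file path.
#' @param dialect `"tsv"` or `"ptt"`; default guesses `ptt` for a `.ptt`
#'   extension, `tsv` otherwise.
#' @return A tibble with columns `gene_id` and `categories` (string of one
#'   or more letters), one row per annotated gene.
#' @examples
#' tsv <- system.file("extdata", "synthetic_example.cog.tsv",
#'                    package = "codonclust")
#' read_cog_annotation(tsv)
#' @export
read_cog_annotation <- function(path, dialect = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(paste0("annotation file not found: ", path),
          class = "codonclust_input_error")
  }
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.ptt$", path, ignore.case = TRUE)) "ptt" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "ptt"))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    parse_cog_tsv(lines, path)
  } else {
    parse_cog_ptt(lines, path)
  }
}

check_cog_letters <- function(letters_str, path, line_no) {
  ch <- strsplit(letters_str, "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, COG_LETTERS)
  if (length(bad) > 0L) {
    abort(paste0("unknown COG category letter(s) '",
                 paste(bad, collapse = ""), "' at ", path, " line ", line_no),
          class = "codonclust_input_error")
  }
  invisible(TRUE)
}

parse_cog_tsv <- function(lines, path) {
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  gene_id <- character(0)
  categories <- character(0)
  n_skipped <- 0L
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || !nzchar(fields[1L])) {
      n_skipped <- n_skipped + 1L
      next
    }
    letters_str <- trimws(fields[2L])
    if (!nzchar(letters_str) || letters_str == "-") next
    check_cog_letters(letters_str, path, i)
    gene_id <- c(gene_id, fields[1L])
    categories <- c(categories, letters_str)
  }
  if (n_skipped > 0L) {
    warn(paste0("skipped ", n_skipped, " unparseable row(s) in ", path))
  }
  collapse_annotation(gene_id, categories)
}

parse_cog_ptt <- function(lines, path) {
  hdr <- grep("^Location\t", lines)[1L]
  if (is.na(hdr)) {
    abort(paste0(path, " does not look like a .ptt protein table ",
                 "(no 'Location' column header line)"),
          class = "codonclust_input_error")
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  syn_i <- match("Synonym", cols)
  cog_i <- match("COG", cols)
  if (is.na(syn_i) || is.na(cog_i)) {
    abort(paste0(path, ": .ptt header lacks Synonym or COG column"),
          class = "codonclust_input_error")
  }
  gene_id <- character(0)
  categories <- character(0)
  n_skipped <- 0L
  body <- seq.int(hdr + 1L, length(lines))
  if (hdr >= length(lines)) body <- integer(0)
  for (i in body) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < max(syn_i, cog_i) || !nzchar(fields[syn_i])) {
      n_skipped <- n_skipped + 1L
      next
    }
    cog <- trimws(fields[cog_i])
    if (!nzchar(cog) || cog == "-") next
    letters_str <- sub("^COG[0-9]+", "", cog)
    if (identical(letters_str, cog)) {   # no COG accession prefix at all
      n_skipped <- n_skipped + 1L
      next
    }
    if (!nzchar(letters_str)) next       # accession without category letters
    check_cog_letters(letters_str, path, i)
    gene_id <- c(gene_id, fields[syn_i])
    categories <- c(categories, letters_str)
  }
  if (n_skipped > 0L) {
    warn(paste0("skipped ", n_skipped, " unparseable row(s) in ", path))
  }
  collapse_annotation(gene_id, categories)
}

# merge duplicate gene ids, unioning their letters in first-seen order
collapse_annotation <- function(gene_id, categories) {
  if (anyDuplicated(gene_id)) {
    merged <- tapply(categories, factor(gene_id, levels = unique(gene_id)),
                     function(x) {
                       paste(unique(unlist(strsplit(x, "", fixed = TRUE))),
                             collapse = "")
                     })
    tibble(gene_id = names(merged), categories = unname(as.character(merged)))
  } else {
    tibble(gene_id = gene_id, categories = categories)
  }
}

#' Count COG categories per cluster
#'
#' Cross-tabulates annotated genes by cluster (SMALL/LARGE) and COG
#' category. Under the default `first_letter` policy each gene increments
#' exactly one category (its first letter), so per-cluster column totals
#' equal the number of annotated genes in the cluster and the 2 x 26 test
#' stays well formed; under `all_letters` a gene increments every letter
#' it carries. Genes without annotation are excluded; annotated genes
#' without a cluster label are reported in a warning.
#'
#' @param labels A tibble with `gene_id` and `cluster` (`"SMALL"`/`"LARGE"`)
#'   columns, or a [cluster_genome()] result.
#' @param annotation A tibble from [read_cog_annotation()] (columns
#'   `gene_id`, `categories`).
#' @param policy `"first_letter"` (default) or `"all_letters"`.
#' @return A tibble with 26 rows: `category` (in super-category order),
#'   `n_small`, `n_large`.
#' @export
count_categories <- function(labels, annotation,
                             policy = c("first_letter", "all_letters")) {
  policy <- match.arg(policy)
  if (inherits(labels, "genome_clustering")) labels <- labels$assignments
  stopifnot(all(c("gene_id", "cluster") %in% names(labels)),
            all(c("gene_id", "categories") %in% names(annotation)))
  unlabeled <- setdiff(annotation$gene_id, labels$gene_id)
  if (length(unlabeled) > 0L) {
    warn(paste0(length(unlabeled),
                " annotated gene(s) have no cluster label and are ignored"))
  }
  joined <- inner_join(labels[, c("gene_id", "cluster")], annotation,
                       by = "gene_id")
  if (nrow(joined) == 0L) {
    abort("no gene is both clustered and annotated",
          class = "codonclust_input_error")
  }
  letters_per_gene <- if (policy == "first_letter") {
    substr(joined$categories, 1L, 1L)
  } else {
    strsplit(joined$categories, "", fixed = TRUE)
  }
  long <- tibble(
    cluster = rep(joined$cluster, lengths(letters_per_gene)),
    category = unlist(letters_per_gene)
  )
  tab <- table(factor(long$category, levels = COG_LETTERS),
               factor(long$cluster, levels = c("SMALL", "LARGE")))
  tibble(
    category = COG_LETTERS,
    n_small = as.integer(tab[, "SMALL"]),
    n_large = as.integer(tab[, "LARGE"])
  )
}

#' Pearson chi-squared test on the 2 x C category table
#'
#' Tests homogeneity of the COG category distribution between the small
#' and large clusters. Categories with a zero total across both clusters
#' are dropped first (they contribute no information and would make
#' expected counts zero); degrees of freedom are `retained columns - 1`.
#' No continuity correction is applied. When any expected count falls
#' below 5 a warning is issued but the statistic is not altered.
#'
#' @param counts A 26-row tibble from [count_categories()] (columns
#'   `category`, `n_small`, `n_large`).
#' @return A list with `statistic`, `dof`, `p_value`, `dropped_categories`
#'   (letters with zero totals), `min_expected`.
#' @examples
#' cc <- tibble::tibble(category = c("J", "P"),
#'                      n_small = c(10L, 0L), n_large = c(0L, 10L))
#' chi_square_2xC(cc)  # statistic 20, dof 1
#' @export
chi_square_2xC <- function(counts) {
  stopifnot(all(c("category", "n_small", "n_large") %in% names(counts)))
  keep <- (counts$n_small + counts$n_large) > 0
  dropped <- as.character(counts$category[!keep])
  if (sum(keep) < 2L) {
    abort("test undefined: fewer than 2 categories with nonzero totals",
          class = "codonclust_test_undefined")
  }
  mat <- rbind(small = counts$n_small[keep], large = counts$n_large[keep])
  if (any(rowSums(mat) == 0)) {
    abort("test undefined: one cluster has no annotated genes",
          class = "codonclust_test_undefined")
  }
  res <- suppressWarnings(stats::chisq.test(mat, correct = FALSE))
  if (min(res$expected) < 5) {
    warn(paste0("chi-squared approximation: minimum expected count ",
                sprintf("%.2f", min(res$expected)), " is below 5"))
  }
  list(
    statistic = unname(res$statistic),
    dof = unname(res$parameter),
    p_value = unname(res$p.value),
    dropped_categories = dropped,
    min_expected = min(res$expected)
  )
}

#' Per-category proportion within a cluster
#'
#' The proportion F of a cluster's annotated genes that belong to a
#' category: `count / total`. Errors when `total` is zero.
#'
#' @param count Number of genes of the category in the cluster.
#' @param total Number of annotated genes in the cluster.
#' @return `count / total`, vectorized over `count`.
#' @export
category_proportions <- function(count, total) {
  if (any(total <= 0)) {
    abort("cluster has no annotated genes: proportion undefined",
          class = "codonclust_input_error")
  }
  count / total
}

#' Overrepresentation indicators for one category
#'
#' Decides which cluster, if either, holds the significantly higher
#' proportion of a category. In `relative` mode (default) the difference
#' must exceed `threshold` times the smaller of the two proportions; in
#' `absolute` mode it must exceed `threshold` itself. The winning cluster
#' scores 1 and the other 0; a sub-threshold difference or an exact tie
#' scores (0, 0).
#'
#' @param f_small,f_large Category proportions in the small and large
#'   clusters (vectors accepted).
#' @param threshold_mode `"relative"` (default) or `"absolute"`.
#' @param threshold Numeric threshold, default 0.05.
#' @return A tibble with integer columns `ind_small`, `ind_large`; per row
#'   one of (1,0), (0,1), (0,0).
#' @examples
#' overrepresentation_indicator(0.20, 0.10)        # (1, 0)
#' overrepresentation_indicator(0.100, 0.104)      # (0, 0): below threshold
#' @export
overrepresentation_indicator <- function(f_small, f_large,
                                         threshold_mode = c("relative", "absolute"),
                                         threshold = 0.05) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(length(f_small) == length(f_large),
            all(f_small >= 0 & f_small <= 1),
            all(f_large >= 0 & f_large <= 1))
  diff <- abs(f_small - f_large)
  cut <- if (threshold_mode == "relative") threshold * pmin(f_small, f_large)
         else threshold
  sig <- diff > cut & f_small != f_large
  tibble(
    ind_small = as.integer(sig & f_small > f_large),
    ind_large = as.integer(sig & f_large > f_small)
  )
}

#' Category enrichment between the small and large clusters of one genome
#'
#' Runs the full per-genome functional stage: category counts under the
#' chosen policy, the 2 x C chi-squared homogeneity test, per-category
#' proportions, and the per-category overrepresentation indicators.
#'
#' @param clustering A [cluster_genome()] result (or a tibble of `gene_id`,
#'   `cluster`).
#' @param annotation A tibble from [read_cog_annotation()].
#' @inheritParams count_categories
#' @inheritParams overrepresentation_indicator
#' @param genome_id Identifier; defaults to the clustering's.
#' @return An object of class `cog_enrichment`: a list with `genome_id`,
#'   `table` (26 rows: `category`, `super_category`, `n_small`, `n_large`,
#'   `F_small`, `F_large`, `ind_small`, `ind_large`), `chi2` (list from
#'   [chi_square_2xC()]), `n_small_total`, `n_large_total`, `policy`,
#'   `threshold_mode`, `threshold`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' g <- simulate_genome("demo", n_genes = 400, seed = 11)
#' ft <- genome_frequency_table(g$genes)
#' cl <- cluster_genome(ft, "demo", k_range = 2:4, n_restarts = 10)
#' enr <- enrich_genome(cl, genome_annotation(g))
#' glance(enr)
#' @export
enrich_genome <- function(clustering, annotation,
                          policy = c("first_letter", "all_letters"),
                          threshold_mode = c("relative", "absolute"),
                          threshold = 0.05, genome_id = NULL) {
  policy <- match.arg(policy)
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(genome_id)) {
    genome_id <- if (inherits(clustering, "genome_clustering"))
      clustering$genome_id else "genome"
  }
  counts <- count_categories(clustering, annotation, policy = policy)
  n_small_total <- sum(counts$n_small)
  n_large_total <- sum(counts$n_large)
  if (n_small_total == 0L || n_large_total == 0L) {
    abort("one cluster has no annotated genes: enrichment undefined",
          class = "codonclust_test_undefined")
  }
  chi2 <- chi_square_2xC(counts)
  F_small <- category_proportions(counts$n_small, n_small_total)
  F_large <- category_proportions(counts$n_large, n_large_total)
  ind <- overrepresentation_indicator(F_small, F_large,
                                      threshold_mode = threshold_mode,
                                      threshold = threshold)
  tab <- counts |>
    left_join(cog_categories(), by = "category") |>
    mutate(F_small = F_small, F_large = F_large,
           ind_small = ind$ind_small, ind_large = ind$ind_large) |>
    select("category", "super_category", "n_small", "n_large",
           "F_small", "F_large", "ind_small", "ind_large")
  structure(
    list(
      genome_id = genome_id,
      table = tab,
      chi2 = chi2,
      n_small_total = n_small_total,
      n_large_total = n_large_total,
      policy = policy,
      threshold_mode = threshold_mode,
      threshold = threshold
    ),
    class = "cog_enrichment"
  )
}

#' @export
print.cog_enrichment <- function(x, ...) {
  cat("COG category enrichment:", x$genome_id, "\n")
  cat("  annotated genes small/large:", x$n_small_total, "/",
      x$n_large_total, "\n")
  cat(sprintf("  chi-squared = %.2f, dof = %d, p = %.3g\n",
              x$chi2$statistic, x$chi2$dof, x$chi2$p_value))
  cat("  overrepresented in SMALL:",
      paste(x$table$category[x$table$ind_small == 1L], collapse = " "), "\n")
  cat("  overrepresented in LARGE:",
      paste(x$table$category[x$table$ind_large == 1L], collapse = " "), "\n")
  invisible(x)
}
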