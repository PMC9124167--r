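#' Assemble per-genome verdict rows for cohort aggregation
#'
#' Joins a list of per-genome enrichment results with cohort metadata into
#' the long verdict table consumed by [significance_summary()],
#' [cumulative_overrepresentation()], [phylum_ratios()] and
#' [consistency_matrix()].
#'
#' @param enrichments A list of [enrich_genome()] results (a
#'   [run_genome()] bundle with an `$enrichment` element also works).
#' @param metadata A tibble with columns `genome_id` and `phylum`. Every
#'   genome must have a row; orphans are an error listing the missing ids.
#' @return A tibble with one row per genome x category: `genome_id`,
#'   `phylum`, `p_value`, `category`, `ind_small`, `ind_large`.
#' @export
cohort_verdicts <- function(enrichments, metadata) {
  stopifnot(is.list(enrichments),
            all(c("genome_id", "phylum") %in% names(metadata)))
  enrichments <- lapply(enrichments, function(e) {
    if (!inherits(e, "cog_enrichment") && !is.null(e$enrichment)) e$enrichment
    else e
  })
  ok <- vapply(enrichments, inherits, logical(1L), "cog_enrichment")
  if (!all(ok)) abort("every element must be a cog_enrichment result")
  rows <- purrr::map_dfr(enrichments, function(e) {
    tibble(
      genome_id = e$genome_id,
      p_value = e$chi2$p_value,
      category = e$table$category,
      ind_small = e$table$ind_small,
      ind_large = e$table$ind_large
    )
  })
  orphans <- setdiff(unique(rows$genome_id), metadata$genome_id)
  if (length(orphans) > 0L) {
    abort(paste0("genome(s) missing from metadata: ",
                 paste(orphans, collapse = ", ")),
          class = "codonclust_input_error")
  }
  rows |>
    left_join(metadata[, c("genome_id", "phylum")], by = "genome_id") |>
    select("genome_id", "phylum", "p_value", "category",
           "ind_small", "ind_large")
}

# accept a verdict table, a tibble with genome_id/p_value, or a bare
# numeric vector of p-values; return one p-value per genome
extract_genome_p <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.data.frame(x), "p_value" %in% names(x))
  if ("genome_id" %in% names(x)) {
    distinct(x, .data$genome_id, .data$p_value)$p_value
  } else {
    x$p_value
  }
}

#' Cohort-wide chi-squared significance summary
#'
#' For each threshold, counts genomes with p below / at-or-above it and
#' reports each count's frequency as a percentage of the cohort, formatted
#' to two decimal places.
#'
#' @param x A verdict table from [cohort_verdicts()], a tibble with
#'   `genome_id` and `p_value`, or a numeric vector of per-genome p-values.
#' @param thresholds Significance thresholds, default `c(0.05, 0.01)`.
#' @return A tibble with columns `threshold`, `band` (`"p < t"` /
#'   `"p >= t"`), `n_genomes`, `frequency_pct` (full precision) and
#'   `label` (e.g. `"99.33%"`).
#' @examples
#' significance_summary(c(rep(0.001, 9), 0.5))
#' @export
significance_summary <- function(x, thresholds = c(0.05, 0.01)) {
  p <- extract_genome_p(x)
  if (length(p) == 0L) abort("empty cohort", class = "codonclust_input_error")
  n <- length(p)
  purrr::map_dfr(thresholds, function(t) {
    n_below <- sum(p < t)
    tibble(
      threshold = t,
      band = c(sprintf("p < %g", t), sprintf("p >= %g", t)),
      n_genomes = c(n_below, n - n_below),
      frequency_pct = 100 * c(n_below, n - n_below) / n
    )
  }) |>
    mutate(label = sprintf("%.2f%%", .data$frequency_pct))
}

#' Cohort-wide cumulative overrepresentation tallies
#'
#' For each of the 26 categories, counts the genomes whose indicator marks
#' the small cluster, the large cluster, or neither (tie / sub-threshold),
#' with frequencies over the cohort size.
#'
#' @param verdicts A verdict table from [cohort_verdicts()].
#' @return A tibble with 26 rows: `category`, `n_small`, `n_large`,
#'   `n_ties`, `freq_small_pct`, `freq_large_pct`, plus two-decimal
#'   `label_small` / `label_large` strings.
#' @export
cumulative_overrepresentation <- function(verdicts) {
  stopifnot(all(c("genome_id", "category", "ind_small", "ind_large")
                %in% names(verdicts)))
  n_genomes <- n_distinct(verdicts$genome_id)
  if (n_genomes == 0L) abort("empty cohort", class = "codonclust_input_error")
  verdicts |>
    group_by(category = factor(.data$category, levels = COG_LETTERS),
             .drop = FALSE) |>
    summarise(n_small = sum(.data$ind_small),
              n_large = sum(.data$ind_large),
              .groups = "drop") |>
    mutate(
      category = as.character(.data$category),
      n_ties = n_genomes - .data$n_small - .data$n_large,
      freq_small_pct = 100 * .data$n_small / n_genomes,
      freq_large_pct = 100 * .data$n_large / n_genomes,
      label_small = sprintf("%.2f%%", .data$freq_small_pct),
      label_large = sprintf("%.2f%%", .data$freq_large_pct)
    ) |>
    arrange(match(.data$category, COG_LETTERS))
}

#' Per-phylum overrepresentation ratios with tie-excluded denominators
#'
#' Phyla with `min_genomes` genomes or fewer are excluded (strictly
#' more-than rule). Within each retained phylum and category, genomes are
#' counted as small-cluster wins, large-cluster wins, or ties (indicator
#' pair (0,0)); the ratios are computed on the tie-excluded denominator
#' `n_small_wins + n_large_wins`, and both ratios are defined as zero when
#' no genome has the category decided.
#'
#' @param verdicts A verdict table from [cohort_verdicts()] (needs a
#'   `phylum` column).
#' @param min_genomes Retain phyla with strictly more than this many
#'   genomes; default 10.
#' @return A tibble with one row per retained phylum x category:
#'   `phylum`, `category`, `n_genomes`, `n_small_wins`, `n_large_wins`,
#'   `n_ties`, `ratio_small`, `ratio_large` (full precision, in \[0, 1\]).
#'   Empty (with a warning) when no phylum survives the filter.
#' @export
phylum_ratios <- function(verdicts, min_genomes = 10L) {
  stopifnot(all(c("genome_id", "phylum", "category",
                  "ind_small", "ind_large") %in% names(verdicts)))
  sizes <- verdicts |>
    distinct(.data$genome_id, .data$phylum) |>
    count(.data$phylum, name = "n_genomes")
  keep <- sizes$phylum[sizes$n_genomes > min_genomes]
  if (length(keep) == 0L) {
    warn(paste0("no phylum has more than ", min_genomes,
                " genomes; returning an empty table"))
    return(tibble(phylum = character(), category = character(),
                  n_genomes = integer(), n_small_wins = integer(),
                  n_large_wins = integer(), n_ties = integer(),
                  ratio_small = numeric(), ratio_large = numeric()))
  }
  verdicts |>
    filter(.data$phylum %in% keep) |>
    group_by(.data$phylum,
             category = factor(.data$category, levels = COG_LETTERS)) |>
    summarise(n_genomes = n_distinct(.data$genome_id),
              n_small_wins = sum(.data$ind_small),
              n_large_wins = sum(.data$ind_large),
              .groups = "drop") |>
    mutate(
      category = as.character(.data$category),
      n_ties = .data$n_genomes - .data$n_small_wins - .data$n_large_wins,
      decided = .data$n_small_wins + .data$n_large_wins,
      ratio_small = ifelse(.data$decided > 0,
                           .data$n_small_wins / .data$decided, 0),
      ratio_large = ifelse(.data$decided > 0,
                           .data$n_large_wins / .data$decided, 0)
    ) |>
    select(-"decided") |>
    arrange(.data$phylum, match(.data$category, COG_LETTERS))
}

#' Cross-phylum consistency classification per category
#'
#' A category is `consistent-large` when the large-cluster ratio exceeds
#' the small-cluster ratio in every retained phylum where the category is
#' decided (nonzero tie-excluded denominator); `consistent-small` is the
#' mirror image; anything else — including a category decided in no phylum
#' — is `mixed`.
#'
#' @param ratios Output of [phylum_ratios()]; at least two phyla required.
#' @return A tibble with 26 rows: `category`, `n_phyla_decided`,
#'   `classification`.
#' @export
consistency_matrix <- function(ratios) {
  stopifnot(all(c("phylum", "category", "ratio_small", "ratio_large")
                %in% names(ratios)))
  if (n_distinct(ratios$phylum) < 2L) {
    abort("consistency classification needs at least 2 phyla",
          class = "codonclust_input_error")
  }
  ratios |>
    mutate(decided = .data$n_small_wins + .data$n_large_wins > 0) |>
    group_by(category = factor(.data$category, levels = COG_LETTERS)) |>
    summarise(
      n_phyla_decided = sum(.data$decided),
      all_large = all(.data$ratio_large[.data$decided] >
                        .data$ratio_small[.data$decided]),
      all_small = all(.data$ratio_small[.data$decided] >
                        .data$ratio_large[.data$decided]),
      .groups = "drop"
    ) |>
    mutate(
      category = as.character(.data$category),
      classification = case_when(
        .data$n_phyla_decided == 0L ~ "mixed",
        .data$all_large ~ "consistent-large",
        .data$all_small ~ "consistent-small",
        TRUE ~ "mixed"
      )
    ) |>
    select("category", "n_phyla_decided", "classification") |>
    arrange(match(.data$category, COG_LETTERS))
}
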