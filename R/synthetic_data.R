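#' Specify one mixture component of a synthetic genome
#'
#' A component is one of the (usually two) gene populations a synthetic
#' genome is drawn from: a mixture weight, a per-codon-position base
#' distribution, a COG category distribution, and an annotation rate.
#'
#' @param weight Mixture weight in (0, 1); weights over a genome's
#'   components must sum to 1.
#' @param base_probs A 3 x 4 numeric matrix: rows are codon positions
#'   1-3, columns the bases A, C, G, T (in that order); every row must
#'   sum to 1 within 1e-9.
#' @param cog_probs Named numeric vector of length 26 over the COG
#'   category letters, summing to 1 within 1e-9. Default: the package's
#'   baseline category distribution ([default_cog_probs()]).
#' @param annotation_rate Probability that an emitted gene carries a COG
#'   annotation, in \[0, 1\]. Default 0.9.
#' @return An object of class `component_spec`.
#' @examples
#' bp <- matrix(0.25, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
#' component_spec(0.5, bp)
#' @export
component_spec <- function(weight, base_probs, cog_probs = default_cog_probs(),
                           annotation_rate = 0.9) {
  stopifnot(is.numeric(weight), length(weight) == 1L,
            weight > 0, weight < 1,
            is.matrix(base_probs), nrow(base_probs) == 3L,
            ncol(base_probs) == 4L,
            is.numeric(annotation_rate), annotation_rate >= 0,
            annotation_rate <= 1)
  if (any(abs(rowSums(base_probs) - 1) > 1e-9) || any(base_probs < 0)) {
    abort("each base_probs row must be a probability vector summing to 1")
  }
  colnames(base_probs) <- BASES
  cog_probs <- cog_probs[COG_LETTERS]
  if (anyNA(cog_probs) || abs(sum(cog_probs) - 1) > 1e-9 || any(cog_probs < 0)) {
    abort("cog_probs must be a named probability vector over the 26 COG letters")
  }
  structure(
    list(weight = weight, base_probs = base_probs, cog_probs = cog_probs,
         annotation_rate = annotation_rate),
    class = "component_spec"
  )
}

#' Baseline COG category distribution for synthetic genomes
#'
#' A fixed, roughly realistic distribution over the 26 COG categories:
#' the broad metabolic and poorly-characterized categories (E, G, R, S)
#' are common, the rare mobilome/cytoskeleton categories (A, B, W, X, Y,
#' Z) are scarce. Used as the base that [paper_like_components()] tilts
#' per component.
#'
#' @return Named numeric vector of length 26 summing to 1, in
#'   super-category letter order.
#' @export
default_cog_probs <- function() {
  v <- c(
    J = 0.050, K = 0.055, L = 0.045, A = 0.004, B = 0.004,
    D = 0.018, Y = 0.004, V = 0.022, T = 0.045, M = 0.055,
    N = 0.020, Z = 0.004, W = 0.006, U = 0.022, O = 0.038,
    X = 0.010, C = 0.055, G = 0.065, E = 0.085, F = 0.028,
    H = 0.042, I = 0.032, P = 0.055, Q = 0.025, R = 0.095,
    S = 0.116
  )
  v <- v[COG_LETTERS]
  v / sum(v)
}

# multiply selected categories' probabilities and renormalize
boost_cog_probs <- function(probs, factors) {
  probs[names(factors)] <- probs[names(factors)] * factors
  probs / sum(probs)
}

#' Two-component mixture echoing the prokaryotic clustering pattern
#'
#' The default study conditions of the generator: a large component
#' (weight `1 - small_weight`) whose second-codon-position base
#' distribution is centered near (f(A2), f(T2)) = (0.32, 0.27), and a
#' small component near (0.22, 0.45) — the high-T2 minority population.
#' Functionally, the small component's category distribution doubles P,
#' boosts U, V, S, G, and strongly depletes the informational categories
#' J, K, L (in real genomes the small high-T2 cluster carries almost no
#' translation, transcription or replication genes); the large component
#' boosts J, K, L, F, H. Both components share generic first/third-position
#' base distributions.
#'
#' @param small_weight Mixture weight of the small (high-T2) component,
#'   default 0.15.
#' @param annotation_rate Annotation rate for both components, default 0.9.
#' @return A named list of two [component_spec()] objects, `small` and
#'   `large`.
#' @export
paper_like_components <- function(small_weight = 0.15, annotation_rate = 0.9) {
  pos1 <- c(A = 0.27, C = 0.21, G = 0.33, T = 0.19)
  pos3 <- c(A = 0.22, C = 0.26, G = 0.27, T = 0.25)
  large_pos2 <- c(A = 0.32, C = 0.21, G = 0.20, T = 0.27)
  small_pos2 <- c(A = 0.22, C = 0.18, G = 0.15, T = 0.45)
  base <- default_cog_probs()
  list(
    small = component_spec(
      weight = small_weight,
      base_probs = rbind(pos1, small_pos2, pos3),
      cog_probs = boost_cog_probs(base, c(P = 2.0, U = 1.6, V = 1.6,
                                          S = 1.3, G = 1.2,
                                          J = 0.15, K = 0.15, L = 0.15)),
      annotation_rate = annotation_rate
    ),
    large = component_spec(
      weight = 1 - small_weight,
      base_probs = rbind(pos1, large_pos2, pos3),
      cog_probs = boost_cog_probs(base, c(J = 1.8, K = 1.6, L = 1.6,
                                          F = 1.3, H = 1.2)),
      annotation_rate = annotation_rate
    )
  )
}

# vectorized emission of full CDS strings for one component.
# Codons are i.i.d. across the gene; an in-frame stop among non-final
# codons has its FIRST base redrawn until the codon is no longer a stop
# (every stop starts with T, so this converges fast and leaves the
# position-2 and position-3 marginals exactly equal to base_probs); the
# final codon is forced to a uniformly chosen stop.
emit_sequences <- function(component, n_codons_vec) {
  bp <- component$base_probs
  total <- sum(n_codons_vec)
  draw <- function(n, p) sample(BASES, n, replace = TRUE, prob = p)
  codons <- paste0(draw(total, bp[1L, ]), draw(total, bp[2L, ]),
                   draw(total, bp[3L, ]))
  last_pos <- cumsum(n_codons_vec)
  is_last <- logical(total)
  is_last[last_pos] <- TRUE
  bad <- which(!is_last & codons %in% STOP_CODONS)
  while (length(bad) > 0L) {
    nb <- length(bad)
    codons[bad] <- paste0(draw(nb, bp[1L, ]), substr(codons[bad], 2L, 3L))
    bad <- bad[codons[bad] %in% STOP_CODONS]
  }
  codons[last_pos] <- sample(STOP_CODONS, length(last_pos), replace = TRUE)
  gene_of <- rep(seq_along(n_codons_vec), n_codons_vec)
  unname(vapply(split(codons, gene_of), paste, character(1L), collapse = ""))
}

# draw category strings (or NA when unannotated) for n genes of one
# component; a second distinct letter is appended with probability 0.1 to
# exercise multi-letter annotation handling
draw_categories <- function(component, n, multi_letter_rate = 0.1) {
  cats <- rep(NA_character_, n)
  ann <- runif(n) < component$annotation_rate
  k <- sum(ann)
  if (k > 0L) {
    first <- sample(COG_LETTERS, k, replace = TRUE, prob = component$cog_probs)
    second <- sample(COG_LETTERS, k, replace = TRUE, prob = component$cog_probs)
    add <- runif(k) < multi_letter_rate & second != first
    cats[ann] <- ifelse(add, paste0(first, second), first)
  }
  cats
}

#' Emit one synthetic coding gene
#'
#' Draws a single CDS from one mixture component: codons i.i.d. with the
#' component's per-position base distributions, no internal in-frame stop
#' codons (rejected and redrawn), and a forced terminal stop. A COG
#' category string is drawn with probability `annotation_rate`.
#'
#' @param component A [component_spec()].
#' @param n_codons Number of codons including the terminal stop; at least 2.
#' @param seed Integer seed making the draw reproducible.
#' @return A list with `sequence` (nucleotide string of `3 * n_codons`
#'   characters) and `categories` (letter string or `NA`).
#' @examples
#' comp <- paper_like_components()$small
#' emit_gene(comp, 100, seed = 1)$categories
#' @export
emit_gene <- function(component, n_codons, seed = 1L) {
  stopifnot(inherits(component, "component_spec"), n_codons >= 2L)
  withr::with_seed(seed, {
    list(
      sequence = emit_sequences(component, as.integer(n_codons)),
      categories = draw_categories(component, 1L)
    )
  })
}

#' Simulate one synthetic genome
#'
#' Draws `n_genes` coding genes from the component mixture: each gene is
#' assigned to a component by the mixture weights, its codon count is
#' log-normal (median `exp(codon_meanlog)` codons, floored at
#' `min_codons`), its sequence is emitted per the component's base
#' distributions (no internal stops, terminal stop forced), and its COG
#' annotation is drawn from the component's category distribution. The
#' ground truth (component and categories per gene) is kept in the
#' returned gene table for recovery scoring.
#'
#' @param genome_id Genome identifier; also prefixes gene ids.
#' @param components List of [component_spec()] objects with weights
#'   summing to 1; default [paper_like_components()].
#' @param n_genes Number of genes, default 2000 (a typical small
#'   prokaryotic genome).
#' @param codon_meanlog,codon_sdlog Parameters of the log-normal codon
#'   count distribution; defaults give a median of ~300 codons.
#' @param min_codons Floor on the codon count, default 50.
#' @param seed Integer seed; the whole genome is a pure function of the
#'   arguments.
#' @return An object of class `synthetic_genome`: a list with `genome_id`,
#'   `genes` (tibble `gene_id`, `sequence`, `component`, `categories`,
#'   `n_codons`), `components`, `seed`.
#' @examples
#' g <- simulate_genome("demo", n_genes = 100, seed = 42)
#' table(g$genes$component)
#' @export
simulate_genome <- function(genome_id = "genome1",
                            components = paper_like_components(),
                            n_genes = 2000L,
                            codon_meanlog = log(300), codon_sdlog = 0.35,
                            min_codons = 50L, seed = 1L) {
  w <- vapply(components, function(cp) cp$weight, numeric(1L))
  if (abs(sum(w) - 1) > 1e-9) abort("component weights must sum to 1")
  if (is.null(names(components))) {
    names(components) <- paste0("component", seq_along(components))
  }
  genes <- withr::with_seed(seed, {
    comp <- sample(seq_along(components), n_genes, replace = TRUE, prob = w)
    n_codons <- pmax(as.integer(min_codons),
                     as.integer(round(rlnorm(n_genes, codon_meanlog,
                                             codon_sdlog))))
    seqs <- character(n_genes)
    cats <- rep(NA_character_, n_genes)
    for (ci in seq_along(components)) {
      idx <- which(comp == ci)
      if (length(idx) == 0L) next
      seqs[idx] <- emit_sequences(components[[ci]], n_codons[idx])
      cats[idx] <- draw_categories(components[[ci]], length(idx))
    }
    tibble(
      gene_id = sprintf("%s_g%05d", genome_id, seq_len(n_genes)),
      sequence = seqs,
      component = names(components)[comp],
      categories = cats,
      n_codons = n_codons
    )
  })
  structure(
    list(genome_id = genome_id, genes = genes, components = components,
         seed = as.integer(seed)),
    class = "synthetic_genome"
  )
}

#' Annotation table of a synthetic genome
#'
#' Extracts the `gene_id` / `categories` annotation of a
#' [simulate_genome()] result in the exact shape [read_cog_annotation()]
#' produces, restricted to annotated genes.
#'
#' @param sim A `synthetic_genome`.
#' @return A tibble with columns `gene_id`, `categories`.
#' @export
genome_annotation <- function(sim) {
  stopifnot(inherits(sim, "synthetic_genome"))
  sim$genes |>
    filter(!is.na(.data$categories)) |>
    select("gene_id", "categories")
}

#' Write a synthetic genome in the dialects the pipeline reads
#'
#' Writes `<genome_id>.ffn` (CDS multi-FASTA), `<genome_id>.cog.tsv`
#' (two-column annotation, annotated genes only) and
#' `<genome_id>.truth.tsv` (the ground-truth ledger: gene_id, component,
#' categories, n_codons) into `dir`.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(sim$genome_id, ".ffn"))
  ann <- file.path(dir, paste0(sim$genome_id, ".cog.tsv"))
  truth <- file.path(dir, paste0(sim$genome_id, ".truth.tsv"))
  writeLines(
    paste0(">", sim$genes$gene_id, " synthetic CDS\n", sim$genes$sequence),
    fasta
  )
  ann_tbl <- genome_annotation(sim)
  readr::write_tsv(ann_tbl, ann, col_names = FALSE)
  readr::write_tsv(
    sim$genes |> select("gene_id", "component", "categories", "n_codons"),
    truth
  )
  invisible(c(fasta = fasta, annotation = ann, truth = truth))
}

#' Simulate a cohort of synthetic genomes grouped by phylum
#'
#' One genome per (phylum, index), each with its own seed derived from
#' the master seed and the genome's global index, so the cohort is
#' reproducible and any genome can be regenerated alone.
#'
#' @param phyla Character vector of phylum names.
#' @param n_genomes_per_phylum Genomes per phylum, default 12.
#' @param components,n_genes,codon_meanlog,codon_sdlog,min_codons Passed
#'   to [simulate_genome()].
#' @param seed Master integer seed.
#' @return An object of class `synthetic_cohort`: a list with `genomes`
#'   (list of `synthetic_genome`), `metadata` (tibble `genome_id`,
#'   `phylum`), `seed`.
#' @examples
#' co <- simulate_cohort(c("A", "B"), n_genomes_per_phylum = 2,
#'                       n_genes = 80, seed = 5)
#' co$metadata
#' @export
simulate_cohort <- function(phyla = c("Proteobacteria", "Firmicutes",
                                      "Actinobacteria"),
                            n_genomes_per_phylum = 12L,
                            components = paper_like_components(),
                            n_genes = 2000L,
                            codon_meanlog = log(300), codon_sdlog = 0.35,
                            min_codons = 50L, seed = 1L) {
  stopifnot(length(phyla) >= 1L, n_genomes_per_phylum >= 1L)
  genomes <- list()
  meta <- list()
  global <- 0L
  for (ph in phyla) {
    for (gi in seq_len(n_genomes_per_phylum)) {
      global <- global + 1L
      gid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", ph), gi)
      gseed <- (as.integer(seed) + 7919L * global) %% 2147483647L
      genomes[[gid]] <- simulate_genome(
        genome_id = gid, components = components, n_genes = n_genes,
        codon_meanlog = codon_meanlog, codon_sdlog = codon_sdlog,
        min_codons = min_codons, seed = gseed
      )
      meta[[gid]] <- tibble(genome_id = gid, phylum = ph)
    }
  }
  structure(
    list(genomes = genomes, metadata = bind_rows(meta),
         seed = as.integer(seed)),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort as a directory tree
#'
#' One subdirectory per genome (via [write_genome()]) plus a
#' `metadata.tsv` (`genome_id`, `phylum`) at the top level — the layout
#' [run_cohort()] reads back.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sim in cohort$genomes) {
    write_genome(sim, file.path(dir, sim$genome_id))
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
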