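#' Read a multi-FASTA of nucleotide coding sequences
#'
#' Reads one CDS per FASTA record. The gene identifier is the first
#' whitespace-delimited token of the header; sequences are uppercased and
#' U is mapped to T so RNA-alphabet input is accepted.
#'
#' @param path Path to a (multi-record) nucleotide FASTA file.
#' @param genome_id Genome identifier attached to every record; defaults to
#'   the file name without extension.
#' @return A tibble with columns `gene_id`, `sequence`, `genome_id`, one row
#'   per record in file order. An empty file yields zero rows with a warning.
#' @examples
#' fa <- system.file("extdata", "synthetic_example.ffn", package = "codonclust")
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path, genome_id = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "codonclust_input_error")
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|ffn|fna|txt)$", "", basename(path),
                     ignore.case = TRUE)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warn(paste0("FASTA file '", path, "' contains no records"))
    return(tibble(gene_id = character(), sequence = character(),
                  genome_id = character()))
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate gene_id in '", path, "': ",
                 paste(dup, collapse = ", ")),
          class = "codonclust_input_error")
  }
  sequence <- chartr("U", "T", toupper(as.character(seqs)))
  tibble(gene_id = unname(ids), sequence = unname(sequence),
         genome_id = genome_id)
}

#' Per-gene base frequencies at each codon position
#'
#' Splits a coding sequence into consecutive non-overlapping triplets from
#' the first base and tallies, for each codon position n in 1..3, the
#' frequency of each base A/C/G/T among the codons whose base at that
#' position is unambiguous. A trailing partial codon (length not a multiple
#' of 3) is discarded; ambiguity codes (N, R, Y, ...) are excluded from the
#' affected position's denominator only, so a gene with a few Ns still
#' contributes everywhere else.
#'
#' @param sequence A single nucleotide string (already uppercased, T not U;
#'   [read_cds_fasta()] guarantees this).
#' @param drop_terminal_stop If `TRUE`, a final complete codon equal to TAA,
#'   TAG or TGA is excluded from counting. Default `FALSE`: every complete
#'   codon is counted.
#' @return A list with elements
#'   \describe{
#'     \item{freq}{4 x 3 matrix, rows A/C/G/T, columns codon positions 1-3;
#'       each column with a nonzero denominator sums to 1.}
#'     \item{counted_codons}{integer(3), the per-position denominators.}
#'     \item{flags}{character vector drawn from `PARTIAL_CODON_TRIMMED`,
#'       `AMBIGUOUS_BASES_SKIPPED`, `TOO_SHORT`.}
#'   }
#'   A sequence with no countable codon returns all-zero `freq` and
#'   `counted_codons` plus the `TOO_SHORT` flag; callers filter such genes.
#' @examples
#' codon_freq_profile("ATGAAATTTTAA", drop_terminal_stop = TRUE)$freq
#' @export
codon_freq_profile <- function(sequence, drop_terminal_stop = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  nc <- n %/% 3L
  flags <- character()
  if (n %% 3L != 0L) flags <- c(flags, "PARTIAL_CODON_TRIMMED")
  if (nc >= 1L && isTRUE(drop_terminal_stop)) {
    last <- paste(chars[(3L * nc - 2L):(3L * nc)], collapse = "")
    if (last %in% STOP_CODONS) nc <- nc - 1L
  }
  freq <- matrix(0, 4L, 3L, dimnames = list(BASES, paste0("pos", 1:3)))
  counted <- integer(3L)
  if (nc >= 1L) {
    idx <- seq_len(nc)
    for (p in 1:3) {
      b <- chars[(idx - 1L) * 3L + p]
      m <- match(b, BASES)
      ok <- !is.na(m)
      if (!all(ok)) flags <- union(flags, "AMBIGUOUS_BASES_SKIPPED")
      counted[p] <- sum(ok)
      if (counted[p] > 0L) {
        freq[, p] <- tabulate(m[ok], nbins = 4L) / counted[p]
      }
    }
  }
  if (sum(counted) == 0L) {
    flags <- union(flags, "TOO_SHORT")
    freq[] <- 0
    counted[] <- 0L
  }
  list(freq = freq, counted_codons = counted, flags = flags)
}

# column names of the flattened 4x3 profile, position-major: fA1 fC1 ... fT3
freq_col_names <- function() {
  paste0("f", rep(BASES, times = 3L), rep(1:3, each = 4L))
}

#' Per-genome table of codon-position base frequencies
#'
#' Computes [codon_freq_profile()] for every gene, drops genes with no
#' countable codon (`TOO_SHORT`), and returns the table that feeds the
#' clustering stage. The two features used downstream, f(A2) and f(T2), are
#' the `fA2` and `fT2` columns.
#'
#' @param genes A tibble with columns `gene_id` and `sequence`, e.g. from
#'   [read_cds_fasta()] or [simulate_genome()].
#' @inheritParams codon_freq_profile
#' @param min_genes Minimum number of usable genes; silhouette model
#'   selection is meaningless on tiny gene sets. Default 50.
#' @return A tibble, one row per usable gene in input order: `gene_id`, the
#'   twelve frequency columns `fA1 ... fT3` (position-major; `fA2` and `fT2`
#'   among them), `counted_codons_1` to `_3`, and `flags` (comma-separated,
#'   empty when clean).
#' @examples
#' g <- tibble::tibble(gene_id = c("a", "b"), sequence = c("ATGAAA", "ATGTTT"))
#' genome_frequency_table(g, min_genes = 2)
#' @export
genome_frequency_table <- function(genes, drop_terminal_stop = FALSE,
                                   min_genes = 50L) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "sequence") %in% names(genes)))
  profiles <- lapply(genes$sequence, codon_freq_profile,
                     drop_terminal_stop = drop_terminal_stop)
  fmat <- t(vapply(profiles, function(p) as.vector(p$freq), numeric(12L)))
  colnames(fmat) <- freq_col_names()
  cmat <- t(vapply(profiles, function(p) p$counted_codons, integer(3L)))
  colnames(cmat) <- paste0("counted_codons_", 1:3)
  flags <- vapply(profiles, function(p) paste(p$flags, collapse = ","),
                  character(1L))
  tbl <- bind_cols(tibble(gene_id = genes$gene_id),
                   as_tibble(fmat), as_tibble(cmat),
                   tibble(flags = flags))
  too_short <- grepl("TOO_SHORT", tbl$flags, fixed = TRUE)
  if (any(too_short)) {
    warn(paste0("dropped ", sum(too_short),
                " gene(s) with no countable codon (TOO_SHORT)"))
    tbl <- tbl[!too_short, , drop = FALSE]
  }
  if (nrow(tbl) < min_genes) {
    abort(paste0("genome too small to cluster: ", nrow(tbl),
                 " usable genes, need at least ", min_genes),
          class = "codonclust_too_few_genes")
  }
  tbl
}

#' Write a frequency table as TSV
#'
#' Frequencies are written in 6-decimal fixed point; a `#`-prefixed comment
#' line records the package version and configuration hash for provenance.
#'
#' @param tbl Output of [genome_frequency_table()].
#' @param path Output file path.
#' @param config_hash Optional provenance string placed in the header comment.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(tbl, path, config_hash = NULL) {
  out <- tbl
  for (cn in freq_col_names()) out[[cn]] <- sprintf("%.6f", tbl[[cn]])
  writeLines(provenance_comment(config_hash), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

provenance_comment <- function(config_hash = NULL) {
  v <- as.character(utils::packageVersion("codonclust"))
  paste0("# codonclust ", v,
         if (!is.null(config_hash)) paste0(" config ", config_hash) else "")
}
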