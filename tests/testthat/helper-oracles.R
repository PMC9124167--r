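# Independent brute-force oracles used across the suite. These are written
# deliberately naively (explicit loops, no shared code with the package) so
# they can serve as ground truth.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# character-walk frequency oracle: loop codon by codon, position by position
naive_profile <- function(seq, drop_terminal_stop = FALSE) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  nc <- length(chars) %/% 3
  if (drop_terminal_stop && nc >= 1) {
    last <- paste0(chars[3 * nc - 2], chars[3 * nc - 1], chars[3 * nc])
    if (last %in% c("TAA", "TAG", "TGA")) nc <- nc - 1
  }
  counts <- matrix(0, 4, 3, dimnames = list(bases, NULL))
  denom <- c(0, 0, 0)
  if (nc >= 1) {
    for (ci in 1:nc) {
      for (p in 1:3) {
        b <- chars[(ci - 1) * 3 + p]
        if (b %in% bases) {
          counts[b, p] <- counts[b, p] + 1
          denom[p] <- denom[p] + 1
        }
      }
    }
  }
  freq <- matrix(0, 4, 3, dimnames = list(bases, paste0("pos", 1:3)))
  for (p in 1:3) if (denom[p] > 0) freq[, p] <- counts[, p] / denom[p]
  list(freq = freq, counted_codons = as.integer(denom))
}

# O(n^2) double-loop silhouette oracle
naive_silhouette <- function(m, labels) {
  n <- nrow(m)
  d <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      other <- which(labels == cl)
      b <- min(b, mean(vapply(other, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive minimum within-cluster SSE over all 2-cluster partitions
exhaustive_k2_inertia <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 0; skip empty
    lab <- c(0, as.integer(intToBits(mask))[1:(n - 1)])
    sse <- 0
    for (cl in 0:1) {
      pts <- m[lab == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# two (or more) gaussian blobs in the unit square
make_blobs <- function(centers, ns, sd = 0.02) {
  m <- do.call(rbind, lapply(seq_along(ns), function(i) {
    cbind(rnorm(ns[i], centers[[i]][1], sd), rnorm(ns[i], centers[[i]][2], sd))
  }))
  m <- pmin(pmax(m, 0), 1)
  colnames(m) <- c("fA2", "fT2")
  m
}
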