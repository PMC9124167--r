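test_that("cog_categories partitions 26 letters into 4 super-categories", {
  cc <- cog_categories()
  expect_equal(nrow(cc), 26)
  expect_equal(anyDuplicated(cc$category), 0)
  expect_equal(as.vector(table(cc$super_category)[unique(cc$super_category)]),
               c(5L, 11L, 8L, 2L))
})

test_that("tsv annotation dialect parses, skips blanks, rejects bad letters", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g7\tP", "g8\tKL", "g9\t-", "", "g10\tJ"), f)
  ann <- read_cog_annotation(f)
  expect_equal(ann$gene_id, c("g7", "g8", "g10"))
  expect_equal(ann$categories, c("P", "KL", "J"))

  writeLines(c("g1\tP", "g2\t9"), f)
  expect_error(read_cog_annotation(f), "line 2")

  writeLines(c("g1\tP", "orphan-no-tab", "g3\tJ"), f)
  expect_warning(ann2 <- read_cog_annotation(f), "1 unparseable")
  expect_equal(nrow(ann2), 2)
})

test_that("ptt dialect extracts trailing letters from the COG column", {
  f <- withr::local_tempfile(fileext = ".ptt")
  writeLines(c(
    "Test chromosome - 1..4000",
    "4 proteins",
    paste("Location", "Strand", "Length", "PID", "Gene", "Synonym", "Code",
          "COG", "Product", sep = "\t"),
    paste("190..255", "+", "21", "101", "thrA", "b0001", "-", "COG0583K",
          "regulator", sep = "\t"),
    paste("300..500", "-", "66", "102", "-", "b0002", "-", "COG1234KL",
          "unknown", sep = "\t"),
    paste("600..700", "+", "33", "103", "-", "b0003", "-", "-",
          "hypothetical", sep = "\t"),
    paste("800..900", "+", "33", "104", "-", "b0004", "-", "COG0007",
          "no letters", sep = "\t")
  ), f)
  ann <- read_cog_annotation(f)          # dialect guessed from extension
  expect_equal(ann$gene_id, c("b0001", "b0002"))
  expect_equal(ann$categories, c("K", "KL"))
})

test_that("bundled ptt and tsv fixtures agree", {
  tsv <- system.file("extdata", "synthetic_example.cog.tsv",
                     package = "codonclust")
  ptt <- system.file("extdata", "synthetic_example.ptt",
                     package = "codonclust")
  a <- read_cog_annotation(tsv)
  b <- read_cog_annotation(ptt)
  expect_equal(a, b)
})

test_that("annotation written by the generator reads back identically", {
  sim <- simulate_genome("ann", n_genes = 80, codon_meanlog = log(40),
                         min_codons = 20, seed = 8)
  d <- withr::local_tempdir()
  paths <- write_genome(sim, d)
  back <- read_cog_annotation(paths[["annotation"]])
  expect_equal(back, genome_annotation(sim))
})

test_that("count_categories applies the multi-letter policy", {
  labels <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                           cluster = c("SMALL", "SMALL", "SMALL", "LARGE"))
  ann <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        categories = c("P", "P", "J", "KL"))
  first <- count_categories(labels, ann, policy = "first_letter")
  expect_equal(first$n_small[first$category == "P"], 2L)
  expect_equal(first$n_small[first$category == "J"], 1L)
  expect_equal(first$n_large[first$category == "K"], 1L)
  expect_equal(first$n_large[first$category == "L"], 0L)
  expect_equal(sum(first$n_small), 3L)   # totals = annotated genes
  all_l <- count_categories(labels, ann, policy = "all_letters")
  expect_equal(all_l$n_large[all_l$category == "L"], 1L)
  expect_equal(sum(all_l$n_large), 2L)   # one gene, two increments
})

test_that("count_categories reports unclustered genes and empty overlap", {
  labels <- tibble::tibble(gene_id = "a", cluster = "SMALL")
  ann <- tibble::tibble(gene_id = c("a", "zz"), categories = c("P", "J"))
  expect_warning(count_categories(labels, ann), "no cluster label")
  ann2 <- tibble::tibble(gene_id = "zz", categories = "J")
  expect_warning(expect_error(count_categories(labels, ann2), "no gene"))
})

test_that("chi_square_2xC matches hand computations", {
  # identical rows: homogeneous, statistic 0, p 1
  cc <- tibble::tibble(category = c("J", "K", "P"),
                       n_small = c(5L, 10L, 15L), n_large = c(5L, 10L, 15L))
  res <- suppressWarnings(chi_square_2xC(cc))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # 2x2 [[10,0],[0,10]]: all expected 5, statistic 20, dof 1
  cc2 <- tibble::tibble(category = c("J", "P"),
                        n_small = c(10L, 0L), n_large = c(0L, 10L))
  res2 <- suppressWarnings(chi_square_2xC(cc2))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$dof, 1L)
})

test_that("zero-total categories are dropped with dof reduced", {
  cc <- tibble::tibble(category = c("J", "K", "P", "Q"),
                       n_small = c(10L, 5L, 0L, 8L),
                       n_large = c(8L, 9L, 0L, 2L))
  res <- suppressWarnings(chi_square_2xC(cc))
  expect_equal(res$dropped_categories, "P")
  expect_equal(res$dof, 2L)
  cc_all0 <- tibble::tibble(category = c("J", "P"),
                            n_small = c(3L, 0L), n_large = c(4L, 0L))
  expect_error(chi_square_2xC(cc_all0), "test undefined")
})

test_that("chi-squared statistic equals brute-force expected counts and is column-permutation invariant", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(3:26, 1)
    cc <- tibble::tibble(
      category = sample(cog_categories()$category, k),
      n_small = rpois(k, 8), n_large = rpois(k, 30)
    )
    cc$n_small[1] <- cc$n_small[1] + 1L  # guard against all-zero rows
    cc$n_large[2] <- cc$n_large[2] + 1L
    res <- suppressWarnings(chi_square_2xC(cc))
    keep <- cc$n_small + cc$n_large > 0
    o <- rbind(cc$n_small[keep], cc$n_large[keep])
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(res$statistic, sum((o - e)^2 / e), tolerance = 1e-9)
    perm <- suppressWarnings(chi_square_2xC(cc[sample(k), ]))
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)
  }
})

test_that("category_proportions is the exact ratio and rejects empty totals", {
  expect_equal(category_proportions(25, 100), 0.25)
  expect_equal(category_proportions(0, 10), 0)
  expect_error(category_proportions(1, 0), "undefined")
})

test_that("proportions under first_letter sum to 1", {
  set.seed(3)
  labels <- tibble::tibble(gene_id = paste0("g", 1:200),
                           cluster = sample(c("SMALL", "LARGE"), 200, TRUE,
                                            prob = c(0.2, 0.8)))
  ann <- tibble::tibble(gene_id = labels$gene_id,
                        categories = sample(cog_categories()$category, 200, TRUE))
  counts <- count_categories(labels, ann)
  expect_equal(sum(category_proportions(counts$n_small, sum(counts$n_small))), 1)
  expect_equal(sum(category_proportions(counts$n_large, sum(counts$n_large))), 1)
})

test_that("overrepresentation indicators follow the threshold rules", {
  # equality -> (0, 0)
  expect_equal(unlist(overrepresentation_indicator(0.10, 0.10)),
               c(ind_small = 0L, ind_large = 0L))
  # relative mode: 0.20 vs 0.10, difference 0.10 > 0.05 * 0.10
  expect_equal(unlist(overrepresentation_indicator(0.20, 0.10)),
               c(ind_small = 1L, ind_large = 0L))
  # sub-threshold: 0.100 vs 0.104, difference 0.004 < 0.005
  expect_equal(unlist(overrepresentation_indicator(0.100, 0.104)),
               c(ind_small = 0L, ind_large = 0L))
  # absolute mode needs the difference itself to beat the threshold
  expect_equal(
    unlist(overrepresentation_indicator(0.16, 0.10, "absolute", 0.05)),
    c(ind_small = 1L, ind_large = 0L)
  )
  expect_equal(
    unlist(overrepresentation_indicator(0.14, 0.10, "absolute", 0.05)),
    c(ind_small = 0L, ind_large = 0L)
  )
})

test_that("indicator pairs are antisymmetric under cluster swap", {
  set.seed(41)
  f1 <- runif(200)
  f2 <- runif(200)
  fwd <- overrepresentation_indicator(f1, f2)
  rev <- overrepresentation_indicator(f2, f1)
  expect_equal(fwd$ind_small, rev$ind_large)
  expect_equal(fwd$ind_large, rev$ind_small)
  # one of (1,0), (0,1), (0,0) always
  expect_true(all(fwd$ind_small + fwd$ind_large <= 1))
})

test_that("enrich_genome recovers the generator's category tilts", {
  sim <- simulate_genome("enr", n_genes = 2000, seed = 77)
  tbl <- genome_frequency_table(sim$genes)
  cl <- cluster_genome(tbl, "enr", k_range = 2:3, n_restarts = 10)
  enr <- enrich_genome(cl, genome_annotation(sim))
  tt <- tidy(enr)
  expect_equal(tt$ind_small[tt$category == "P"], 1L)
  expect_equal(tt$ind_large[tt$category == "J"], 1L)
  expect_lt(glance(enr)$p_value, 0.01)
  expect_equal(glance(enr)$n_small + glance(enr)$n_large,
               sum(!is.na(sim$genes$categories)))
})

test_that("counts equal the generator's ground-truth ledger when clusters are known", {
  sim <- simulate_genome("ledger", n_genes = 400, codon_meanlog = log(60),
                         min_codons = 30, seed = 15)
  # bypass clustering: use the true component as the cluster label
  labels <- tibble::tibble(
    gene_id = sim$genes$gene_id,
    cluster = ifelse(sim$genes$component == "small", "SMALL", "LARGE")
  )
  counts <- count_categories(labels, genome_annotation(sim))
  truth <- sim$genes[!is.na(sim$genes$categories), ]
  first <- substr(truth$categories, 1, 1)
  for (cat in c("P", "J", "S")) {
    expect_equal(counts$n_small[counts$category == cat],
                 sum(first == cat & truth$component == "small"))
    expect_equal(counts$n_large[counts$category == cat],
                 sum(first == cat & truth$component == "large"))
  }
})

test_that("equal-probability categories score (0,0) under the absolute threshold", {
  # clusters drawn from one shared category distribution: no category
  # should be flagged when the difference must exceed 5 percentage points
  probs <- default_cog_probs()
  hits <- withr::with_seed(99, {
    vapply(1:10, function(i) {
      n_small <- 150L; n_large <- 850L
      cats <- sample(names(probs), n_small + n_large, TRUE, prob = probs)
      labels <- tibble::tibble(
        gene_id = paste0("g", seq_len(n_small + n_large)),
        cluster = rep(c("SMALL", "LARGE"), c(n_small, n_large))
      )
      ann <- tibble::tibble(gene_id = labels$gene_id, categories = cats)
      counts <- count_categories(labels, ann)
      ind <- overrepresentation_indicator(
        counts$n_small / sum(counts$n_small),
        counts$n_large / sum(counts$n_large),
        threshold_mode = "absolute"
      )
      all(ind$ind_small == 0L & ind$ind_large == 0L)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})
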