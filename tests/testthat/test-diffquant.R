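# z-scoring, Pearson distance, complete-linkage clustering, ANOVA +
# Tukey HSD, q-values, intersections.

test_that("z-scoring centers and scales rows, dropping degenerate ones", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 20, 40))
  expect_warning(z <- zscore_rows(m), "zero variance")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(attr(z, "dropped"), "b")
  set.seed(2)
  r <- matrix(rnorm(80), 20, 4)
  z2 <- zscore_rows(r)
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(apply(z2, 1, sd) - 1) < 1e-9))
})

test_that("Pearson distance is 1 - r with the expected extremes", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  d <- as.matrix(pearson_distance(m))
  expect_equal(d["a", "b"], 0)     # proportional rows: r = 1
  expect_equal(d["a", "c"], 2)     # reversed row: r = -1
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # matches the covariance definition entry by entry
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4)
  dx <- as.matrix(pearson_distance(x))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      r <- sum((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ]))) /
        ((4 - 1) * sd(x[i, ]) * sd(x[j, ]))
      expect_equal(dx[i, j], 1 - r)
    }
  }
  # a pair sharing < 2 columns is rejected
  y <- rbind(c(1, 2, NA, NA), c(NA, NA, 1, 2), c(1, 2, 3, 4))
  expect_error(pearson_distance(y), class = "acetoprot_validation_error")
})

test_that("complete linkage recovers forced geometry and the identity cut", {
  # two tight pairs far apart
  D <- matrix(1.9, 4, 4)
  D[1, 2] <- D[2, 1] <- 0.1
  D[3, 4] <- D[4, 3] <- 0.1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- letters[1:4]
  dend <- cluster_complete(as.dist(D))
  expect_equal(unname(cut_clusters(dend, 2)), c(1, 1, 2, 2))
  expect_equal(unname(cut_clusters(dend, 4)), 1:4)  # k = n: singletons
  expect_equal(unname(cut_clusters(dend, 1)), rep(1, 4))
  expect_error(cut_clusters(dend, 5), class = "acetoprot_validation_error")
  # merge heights are non-decreasing
  expect_true(all(diff(dend$height) >= 0))
})

test_that("complete linkage agrees with stats::hclust on random instances", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 4), n)
    d <- dist(x)
    mine <- cluster_complete(d)
    ref <- hclust(d, method = "complete")
    expect_equal(mine$height, ref$height)
    for (k in 1:n) {
      expect_equal(unname(cut_clusters(mine, k)), unname(cutree(ref, k)))
    }
  }
})

test_that("heat-map export preserves dendrogram leaf order", {
  set.seed(10)
  m <- matrix(rnorm(24), 8, 3,
              dimnames = list(sprintf("P%03d", 1:8), c("FL", "DL", "UL")))
  dend <- cluster_complete(pearson_distance(zscore_rows(m)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap_matrix(m, dend, path)
  out <- read.delim(path)
  expect_equal(out$accession, dend$labels[dend$order])
})

test_that("ANOVA F is zero for equal group means and t-squared for 2 groups", {
  design <- make_design(phases = c("FL", "DL", "UL"), reps = 3)
  ab <- matrix(rep(c(1, 2, 3), 3), 1, 9,
               dimnames = list("P001", design$sample_id))
  tab <- make_table(ab, design)
  res <- anova_tukey(tab, log_transform = FALSE)
  expect_equal(res$stats$F, 0)
  expect_equal(res$stats$p, 1)

  # two groups: F = t^2, Tukey adjusted p = ANOVA p (the adjusted p is
  # computed through ptukey's quadrature, hence the looser tolerance)
  g1 <- c(10, 11, 12.5)
  g2 <- c(20, 21.5, 22)
  d2 <- make_design(phases = c("FL", "UL"), reps = 3)
  tab2 <- make_table(matrix(c(g1, g2), 1, 6,
                            dimnames = list("P001", d2$sample_id)), d2)
  r2 <- anova_tukey(tab2, log_transform = FALSE)
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(r2$stats$F, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(r2$tukey$p_adj, r2$stats$p, tolerance = 1e-3)
})

test_that("ANOVA and Tukey match the textbook sums-of-squares oracle", {
  set.seed(15)
  design <- make_design(phases = c("FL", "DL", "UL"), reps = 4)
  y <- c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 11))
  tab <- make_table(matrix(y, 1, 12, dimnames = list("P001", design$sample_id)),
                    design)
  res <- anova_tukey(tab, log_transform = FALSE)
  groups <- split(y, rep(c("SY:FL", "SY:DL", "SY:UL"), each = 4))
  groups <- groups[sort(names(groups))]   # factor level order
  oracle <- oracle_anova_tukey(groups)
  expect_equal(res$stats$F, oracle$F, tolerance = 1e-6)
  expect_equal(res$stats$p, oracle$p, tolerance = 1e-6)
  expect_equal(res$stats$df1, oracle$df1)
  expect_equal(res$stats$df2, oracle$df2)
  expect_equal(sort(res$tukey$p_adj), sort(unname(oracle$tukey[, "p_adj"])),
               tolerance = 1e-6)
})

test_that("proteins without two groups of two detected replicates are reported", {
  design <- make_design(phases = c("FL", "DL"), reps = 3)
  ab <- matrix(NA_real_, 2, 6, dimnames = list(NULL, design$sample_id))
  ab[1, ] <- rnorm(6, 10)
  ab[2, c("SY_FL_1", "SY_DL_1")] <- 5  # one replicate per group
  tab <- make_table(ab, design)
  res <- anova_tukey(tab)
  expect_equal(res$stats$accession, "P001")
  expect_equal(res$untestable, "P002")
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1 and stay monotone", {
  expect_equal(unclass(qvalues(0.03)), 0.03, ignore_attr = TRUE)
  # hand-computed BH: min over tails of p * m / rank
  expect_equal(unclass(qvalues(c(0.01, 0.02, 0.03))), c(0.03, 0.03, 0.03),
               ignore_attr = TRUE)
  expect_error(qvalues(c(0.5, 1.2)), class = "acetoprot_validation_error")
  set.seed(6)
  p <- runif(500)
  q <- qvalues(p)
  expect_true(all(q >= p.adjust(p, "BH") * attr(q, "pi0") - 1e-12))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # fixed pi0 reproduces BH exactly
  expect_equal(unclass(qvalues(p, pi0_method = "fixed")),
               unname(p.adjust(p, "BH")), ignore_attr = TRUE)
})

test_that("pi0 is estimated near 1 under the uniform null", {
  set.seed(17)
  pi0s <- replicate(20, attr(qvalues(runif(1000)), "pi0"))
  expect_true(mean(pi0s >= 0.8 & pi0s <= 1) >= 0.9)
})

test_that("intersection counts are exact-combination (UpSet) counts", {
  res <- intersections(list(A = c("x", "y"), B = c("y", "z")))
  expect_setequal(res$combination, c("A", "B", "A&B"))
  expect_equal(res$count[match(c("A", "B", "A&B"), res$combination)],
               c(1L, 1L, 1L))
  expect_equal(sum(res$count), attr(res, "n_union"))

  same <- intersections(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$combination, "A&B")
  expect_equal(same$count, 2L)

  # brute-force per-element pattern tally
  set.seed(19)
  sets <- lapply(1:3, function(i) sample(sprintf("e%02d", 1:40), 20))
  names(sets) <- c("FL", "DL", "UL")
  res3 <- intersections(sets)
  for (e in unique(unlist(sets))) {
    pattern <- paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)],
                     collapse = "&")
    expect_true(pattern %in% res3$combination)
  }
  tally <- table(vapply(sort(unique(unlist(sets))), function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)], collapse = "&")
  }, ""))
  expect_equal(sort(setNames(res3$count, res3$combination)[names(tally)]),
               sort(as.integer(tally)), ignore_attr = TRUE)
})
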