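# 12 samples in 2 conditions unless stated otherwise; all fixtures built here.

mat_fix <- function(vals, n_cond = 2, reps = NULL) {
  m <- do.call(rbind, vals)
  reps <- if (is.null(reps)) ncol(m) / n_cond else reps
  rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  conds <- rep(sprintf("g%d", seq_len(n_cond)), each = reps)
  omics_table(m, conds)
}

test_that("filter_missing implements the per-condition missingness rule", {
  # f01 missing 3/5 in both groups -> removed; f02 fully observed -> kept;
  # f03 missing 3/5 in one group only -> kept under the default reading
  v <- rbind(c(NA, NA, NA, 1, 2,   NA, NA, NA, 1, 2),
             c(1, 2, 3, 4, 5,      1, 2, 3, 4, 5),
             c(NA, NA, NA, 1, 2,   1, 2, 3, 4, 5))
  rownames(v) <- c("f01", "f02", "f03")
  colnames(v) <- sprintf("s%02d", 1:10)
  t <- omics_table(v, rep(c("a", "b"), each = 5))
  out <- filter_missing(t)
  expect_setequal(rownames(out$values), c("f02", "f03"))
  expect_identical(out$removed, "f01")
  # the stricter any-group reading also drops f03
  out2 <- filter_missing(t, mode = "any-group")
  expect_identical(rownames(out2$values), "f02")
})

test_that("half-minimum imputation fills each gap with min/2", {
  t <- mat_fix(list(c(4, NA, 8, 6, 4, 8), c(1, 2, 3, 1, 2, 3)))
  out <- impute_half_min(filter_missing(t))
  expect_identical(unname(out$values["f01", 2]), 2)
  expect_false(anyNA(out$values))
  expect_identical(out$scale, "imputed")
  # identity on complete data; per-feature minimum of imputed rows unchanged
  t2 <- mat_fix(list(c(5, 6, 7, 5, 6, 7)))
  out2 <- impute_half_min(filter_missing(t2))
  expect_identical(out2$values, t2$values)
  expect_identical(min(out$values["f01", ]), 2)  # imputed value IS min/2
  expect_identical(min(out$values["f02", ]), 1)  # observed minimum untouched
})

test_that("range scaling centers by mean and divides by the range", {
  t <- mat_fix(list(c(1, 2, 3, 1, 2, 3), c(5, 5, 5, 5, 5, 5)))
  expect_warning(out <- range_scale(impute_half_min(filter_missing(t))),
                 "constant")
  expect_equal(unname(out$values["f01", 1:3]), c(-0.5, 0, 0.5))
  expect_true(all(out$values["f02", ] == 0))
  # scaled features have unit range and sit inside [-1, 1]
  set.seed(11)
  t3 <- mat_fix(list(rlnorm(8), rlnorm(8), rlnorm(8)), reps = 4)
  s3 <- range_scale(impute_half_min(filter_missing(t3)))
  rng <- apply(s3$values, 1, function(x) diff(range(x)))
  expect_equal(unname(rng), rep(1, 3))
  expect_true(all(abs(s3$values) <= 1))
})

test_that("pipeline stages refuse out-of-order input", {
  t <- mat_fix(list(c(1, 2, 3, 4, 5, 6)))
  expect_error(impute_half_min(t), "filter_missing first")
  expect_error(range_scale(filter_missing(t)), "imputed")
  expect_error(welch_de(impute_half_min(filter_missing(t)), "g1", "g2"),
               "range-scaled")
  expect_error(run_pca(t), "range-scaled")
})

test_that("welch_de reproduces the hand fixture and the t.test oracle", {
  t <- mat_fix(list(c(10, 12, 14, 20, 22, 24)))
  de <- welch_de(scaled_table(t), "g1", "g2")
  expect_equal(abs(de$stat), 10 / sqrt(8 / 3), tolerance = 1e-12)  # 6.1237
  expect_equal(de$df, 4, tolerance = 1e-12)
  expect_equal(de$p, 2 * stats::pt(-6.123724, 4), tolerance = 1e-5) # 3.6e-3
  expect_gt(de$stat, 0)          # B over A: refed-style increase is positive
  expect_equal(de$log2fc, log2(22 / 12))

  # oracle: t.test on several random 3v3 integer fixtures (scale-invariant)
  set.seed(42)
  for (i in 1:10) {
    a <- sample(5:50, 3); b <- sample(5:50, 3)
    if (stats::var(a) == 0 || stats::var(b) == 0) next
    t2 <- mat_fix(list(c(a, b)))
    de2 <- welch_de(scaled_table(t2), "g1", "g2")
    ref <- stats::t.test(t2$values[1, 4:6], t2$values[1, 1:3])
    expect_equal(de2$p, ref$p.value, tolerance = 1e-10)
    expect_equal(de2$stat, unname(ref$statistic), tolerance = 1e-8)
  }
})

test_that("welch_de degenerate conventions", {
  t <- mat_fix(list(c(3, 4, 5, 3, 4, 5)))       # identical groups
  de <- welch_de(scaled_table(t), "g1", "g2")
  expect_identical(de$stat, 0)
  expect_identical(de$p, 1)

  tz <- mat_fix(list(c(5, 5, 5, 5, 5, 5),        # zero variance, equal means
                     c(2, 2, 2, 8, 8, 8)))       # zero variance, unequal
  suppressWarnings(sz <- scaled_table(tz))
  expect_warning(dez <- welch_de(sz, "g1", "g2"), "zero-variance")
  expect_identical(dez$p[1], 1)
  expect_identical(dez$p[2], 0)
})

test_that("anova_de matches hand arithmetic and the aov oracle", {
  t <- mat_fix(list(c(1, 2, 3, 11, 12, 13, 21, 22, 23)), n_cond = 3, reps = 3)
  de <- anova_de(scaled_table(t), c("g1", "g2", "g3"))
  expect_equal(de$stat, 300, tolerance = 1e-9)
  expect_equal(de$p, stats::pf(300, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)   # ~9.8e-7

  # identical groups -> F = 0, p = 1
  t0 <- mat_fix(list(rep(c(1, 2, 3), 3)), n_cond = 3, reps = 3)
  de0 <- anova_de(scaled_table(t0), c("g1", "g2", "g3"))
  expect_equal(de0$stat, 0)
  expect_equal(de0$p, 1)

  # oracle: stats::oneway.test with equal variances on a random fixture
  set.seed(9)
  tr <- mat_fix(list(rlnorm(9, 1, 0.4)), n_cond = 3, reps = 3)
  s <- scaled_table(tr)
  der <- anova_de(s, c("g1", "g2", "g3"))
  ref <- stats::oneway.test(s$values[1, ] ~ s$conditions, var.equal = TRUE)
  expect_equal(der$p, ref$p.value, tolerance = 1e-10)

  expect_error(anova_de(s, c("g1", "g2")), ">= 3 groups")
})

test_that("null p-values stay uniform under label permutation", {
  # one-way ANOVA on pure-noise tables: KS test against U(0,1)
  spec <- simulation_spec(seed = 29, n_features = 2000, n_conditions = 3,
                          replicates = 4, cv = 0.25, dropout_rate = 0,
                          censor_quantile = 0)
  s <- range_scale(impute_half_min(filter_missing(simulate_omics_table(spec)$table)))
  de <- anova_de(s, c("cond01", "cond02", "cond03"))
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("compute_rsd is sd/mean, scale-invariant, and guards zero means", {
  t <- mat_fix(list(c(10, 10, 10, 8, 12, 10)))
  r <- compute_rsd(filter_missing(t))
  expect_identical(unname(r$rsd["f01", "g1"]), 0)
  expect_equal(unname(r$rsd["f01", "g2"]), stats::sd(c(8, 12, 10)) / 10)

  # [8, 12]: sd = 2.828, mean = 10, RSD = 0.2828
  t2 <- mat_fix(list(c(8, 12, 8, 12)), reps = 2)
  r2 <- compute_rsd(filter_missing(t2))
  expect_equal(unname(r2$rsd["f01", "g1"]), 0.2828427, tolerance = 1e-6)

  t3 <- t2; t3$values <- t3$values * 1000
  r3 <- compute_rsd(filter_missing(t3))
  expect_equal(r3$rsd, r2$rsd)
})

test_that("run_pca scores, variance fractions, and ellipses behave", {
  # two perfectly correlated features -> PC1 carries all variance
  v <- rbind(c(1, 2, 3, 4, 5, 6), 2 * c(1, 2, 3, 4, 5, 6))
  rownames(v) <- c("f01", "f02"); colnames(v) <- sprintf("s%02d", 1:6)
  t <- omics_table(v, rep(c("a", "b"), each = 3))
  p <- run_pca(scaled_table(t), n_components = 2)
  expect_equal(p$explained_variance[1], 1)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_true(all(p$explained_variance >= 0 & p$explained_variance <= 1))

  # duplicated samples get identical scores
  v2 <- matrix(rlnorm(40, 10, 0.3), nrow = 5,
               dimnames = list(sprintf("f%02d", 1:5), sprintf("s%02d", 1:8)))
  v2[, 8] <- v2[, 7]
  t2 <- scaled_table(omics_table(v2, rep(c("a", "b"), each = 4)))
  p2 <- run_pca(t2, 2)
  expect_equal(p2$scores[7, ], p2$scores[8, ], ignore_attr = TRUE)

  # ellipses exist per condition with positive axes
  expect_named(p2$ellipses, c("a", "b"))
  expect_true(all(p2$ellipses$a$axes >= 0))

  expect_error(run_pca(t2, 99), "exceeds")
})

test_that("PCA separates the planted two-cluster fixture", {
  sim <- make_two_cluster_table(seed = 17)
  s <- scaled_table(sim$table)
  p <- run_pca(s, 2)
  sil <- silhouette_1d(p$scores[, 1], as.character(s$conditions))
  expect_gt(sil, 0.8)
})

test_that("ward clustering is Ward/Euclidean with deterministic leaves", {
  # two items merge at their Euclidean height
  v <- rbind(f01 = c(0, 0, 1, 1), f02 = c(3, 4, 1, 1)) + 10
  colnames(v) <- sprintf("s%02d", 1:4)
  t <- scaled_table(omics_table(v, rep(c("a", "b"), each = 2)))
  h <- ward_cluster(t, "features")
  expect_identical(length(h$height), 1L)
  expect_equal(h$height, unname(stats::dist(t$values)[1]))

  # three collinear samples (plus a far one): first merge joins the closest
  v3 <- matrix(c(1, 2, 11, 31), nrow = 1,
               dimnames = list("f01", sprintf("s%02d", 1:4)))
  s3 <- scaled_table(omics_table(v3, rep(c("a", "b"), each = 2)))
  h3 <- ward_cluster(s3, "samples")
  first <- sort(h3$labels[-h3$merge[1, ]])
  expect_identical(first, c("s01", "s02"))

  # planted two-cluster fixture: k = 2 cut recovers the condition labels
  sim <- make_two_cluster_table(seed = 17)
  s <- scaled_table(sim$table)
  hs <- ward_cluster(s, "samples")
  cut <- stats::cutree(hs, k = 2)
  labs <- as.character(s$conditions)[match(hs$labels, names(s$conditions))]
  expect_identical(length(unique(paste(cut, labs))), 2L)

  # label order never changes with input column order
  s_rev <- s; s_rev$values <- s_rev$values[, rev(colnames(s_rev$values))]
  s_rev$conditions <- s_rev$conditions[colnames(s_rev$values)]
  expect_identical(ward_cluster(s_rev, "samples")$labels,
                   ward_cluster(s, "samples")$labels)
})

test_that("logfc_distribution summarizes the shift between conditions", {
  t <- mat_fix(list(c(4, 5, 6, 4, 5, 6), c(7, 8, 9, 7, 8, 9)))
  l <- logfc_distribution(impute_half_min(filter_missing(t)), "g1", "g2")
  expect_identical(l$median, 0)

  t2 <- mat_fix(list(c(4, 5, 6, 8, 10, 12), c(1, 2, 3, 2, 4, 6)))
  l2 <- logfc_distribution(impute_half_min(filter_missing(t2)), "g1", "g2")
  expect_identical(l2$median, 1)

  # 30% of features planted at +0.5 log2FC shifts the median right
  spec <- simulation_spec(seed = 7, n_features = 300, n_conditions = 2,
                          replicates = 5, cv = 0.2, dropout_rate = 0,
                          censor_quantile = 0,
                          effects = data.frame(
                            feature = sprintf("feat%04d", 1:90),
                            condition = "cond02", log2fc = 0.5))
  sim <- simulate_omics_table(spec)
  l3 <- logfc_distribution(impute_half_min(filter_missing(sim$table)),
                           "cond01", "cond02")
  expect_gt(l3$median, 0)
  expect_lt(l3$sign_test_p, 0.01)
})
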