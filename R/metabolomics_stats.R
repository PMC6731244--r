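# Metabolomics preprocessing and differential statistics.
#
# The pipeline order is fixed and enforced through the table's scale flag:
#   raw -> filter_missing -> impute_half_min -> (compute_rsd on imputed raw)
#       -> range_scale -> welch_de / anova_de / run_pca / ward_cluster
# Each stage stamps the flag and refuses out-of-order input. Fold changes are
# always computed on the imputed raw values (range-scaled values can be
# negative), which the range-scaled table carries along for that purpose.

#' Construct an omics measurement table
#'
#' Features (compounds) are rows, samples are columns; `NA` cells are the
#' explicit missing mask. Each sample carries exactly one condition label
#' (e.g. `"body.CD.fasted"`). Raw abundances must be positive where present.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids); `NA` = missing.
#' @param conditions character/factor of length `ncol(values)` giving each
#'   sample's condition, in column order (or named by sample id).
#' @return an `omics_table` with scale flag `"raw"`.
#' @export
omics_table <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values))) stop("duplicated sample id(s)")
  if (length(conditions) != ncol(values))
    stop("conditions must have one entry per sample")
  if (!is.null(names(conditions))) {
    miss <- setdiff(colnames(values), names(conditions))
    if (length(miss) > 0)
      stop("sample(s) missing from condition map: ",
           paste(miss, collapse = ", "))
    conditions <- conditions[colnames(values)]
  }
  conditions <- factor(as.character(conditions))
  names(conditions) <- colnames(values)
  if (any(values <= 0, na.rm = TRUE))
    stop("raw abundances must be positive where present")
  structure(list(values = values, conditions = conditions, scale = "raw",
                 imputed = NULL, stages = character(0), removed = character(0)),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table [%s]: %d features x %d samples, %d conditions\n",
              x$scale, nrow(x$values), ncol(x$values),
              nlevels(x$conditions)))
  if (length(x$stages) > 0)
    cat("stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

require_scale <- function(t, allowed, op) {
  if (!inherits(t, "omics_table")) stop(op, ": not an omics_table")
  if (!t$scale %in% allowed)
    stop(op, ": requires a ", paste(allowed, collapse = " or "),
         " table, got '", t$scale, "' (pipeline order is filter -> impute -> ",
         "range-scale -> tests)")
  invisible(t)
}

group_index <- function(t, label) {
  idx <- which(as.character(t$conditions) == label)
  if (length(idx) == 0) stop("condition group not found: ", label)
  idx
}

#' Remove features with too many missing values
#'
#' A feature is removed when its missing fraction exceeds `max_missing_frac`
#' in **every** condition group (the default, which keeps compounds reliably
#' detected in at least one condition). The stricter alternative — drop when
#' *any* group exceeds the threshold — is available via
#' `mode = "any-group"`. Removed feature ids are recorded on the table's
#' removal log.
#'
#' @param t a raw `omics_table`.
#' @param max_missing_frac highest tolerated missing fraction (default 0.5,
#'   i.e. "more than 50% missing" triggers removal).
#' @param mode `"all-groups"` (default) or `"any-group"`.
#' @return the filtered `omics_table` (still raw, stage-stamped).
#' @export
filter_missing <- function(t, max_missing_frac = 0.5,
                           mode = c("all-groups", "any-group")) {
  mode <- match.arg(mode)
  require_scale(t, "raw", "filter_missing")
  groups <- levels(t$conditions)
  sizes <- table(t$conditions)
  if (any(sizes == 0)) stop("condition with 0 samples: ",
                            paste(groups[sizes == 0], collapse = ", "))
  frac <- sapply(groups, function(g) {
    idx <- group_index(t, g)
    rowMeans(is.na(t$values[, idx, drop = FALSE]))
  })
  frac <- matrix(frac, nrow = nrow(t$values))
  exceeded <- frac > max_missing_frac
  drop <- if (mode == "all-groups") apply(exceeded, 1, all)
          else apply(exceeded, 1, any)
  t$removed <- c(t$removed, rownames(t$values)[drop])
  t$values <- t$values[!drop, , drop = FALSE]
  t$stages <- c(t$stages, sprintf("filter_missing(%.2f,%s): removed %d",
                                  max_missing_frac, mode, sum(drop)))
  t
}

#' Half-minimum imputation
#'
#' Each missing cell is replaced by half of the feature's minimum observed
#' value across all samples. Requires [filter_missing()] to have run first;
#' a feature with no observed values at all is an error (it should have been
#' filtered).
#'
#' @param t a filtered raw `omics_table`.
#' @return the table with scale flag `"imputed"` and no missing cells.
#' @export
impute_half_min <- function(t) {
  require_scale(t, "raw", "impute_half_min")
  if (!any(startsWith(t$stages, "filter_missing")))
    stop("impute_half_min: run filter_missing first")
  n_missing <- sum(is.na(t$values))
  if (n_missing > 0) {
    all_na <- rowSums(!is.na(t$values)) == 0
    if (any(all_na))
      stop("feature(s) with zero observed values: ",
           paste(rownames(t$values)[all_na], collapse = ", "))
    mins <- apply(t$values, 1, min, na.rm = TRUE)
    for (i in which(rowSums(is.na(t$values)) > 0)) {
      miss <- is.na(t$values[i, ])
      t$values[i, miss] <- mins[i] / 2
    }
  }
  t$scale <- "imputed"
  t$stages <- c(t$stages, sprintf("impute_half_min: %d cells", n_missing))
  t
}

#' Range scaling
#'
#' Per-feature normalization `x' = (x - mean(x)) / (max(x) - min(x))`; every
#' non-constant feature ends with unit range and values in [-1, 1]. Constant
#' features are set to all zeros with a warning. The pre-scaling (imputed)
#' matrix is retained on the table so downstream fold changes use raw-scale
#' values.
#'
#' @param t an imputed `omics_table`.
#' @return the table with scale flag `"range-scaled"`.
#' @export
range_scale <- function(t) {
  require_scale(t, "imputed", "range_scale")
  v <- t$values
  rng <- apply(v, 1, max) - apply(v, 1, min)
  ctr <- rowMeans(v)
  zero <- rng == 0
  if (any(zero))
    warning("constant feature(s) set to zero after scaling: ",
            paste(rownames(v)[zero], collapse = ", "))
  scaled <- (v - ctr) / ifelse(rng == 0, 1, rng)
  scaled[zero, ] <- 0
  t$imputed <- v
  t$values <- scaled
  t$scale <- "range-scaled"
  t$stages <- c(t$stages, "range_scale")
  t
}

raw_for_fc <- function(t) {
  if (t$scale == "range-scaled") t$imputed
  else if (t$scale == "imputed") t$values
  else stop("fold changes need an imputed table")
}

row_group_stats <- function(m) {
  n <- ncol(m)
  mean <- rowMeans(m)
  var <- rowSums((m - mean)^2) / (n - 1)
  list(mean = mean, var = var, n = n)
}

#' Welch's t-test per feature
#'
#' Two-sided Welch (unequal-variance) t-test of group B against group A for
#' every feature, with Welch-Satterthwaite degrees of freedom and
#' Benjamini-Hochberg q-values across all tested features. The t statistic is
#' computed on the (range-scaled) table values; log2 fold changes
#' (B over A) come from the imputed raw values carried by the table.
#' Degenerate features where both groups have zero variance get p = 1 when
#' the means are equal, p = 0 (with a warning) when they differ.
#'
#' @param t a range-scaled `omics_table`.
#' @param group_a,group_b condition labels present in the table.
#' @param fdr_threshold FDR level defining the `significant` column.
#' @return data.frame: `feature`, `mean_a`, `mean_b` (imputed raw means),
#'   `log2fc`, `stat`, `df`, `p`, `q`, `significant`.
#' @export
welch_de <- function(t, group_a, group_b, fdr_threshold = 0.1) {
  require_scale(t, "range-scaled", "welch_de")
  ia <- group_index(t, group_a); ib <- group_index(t, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 samples")
  a <- row_group_stats(t$values[, ia, drop = FALSE])
  b <- row_group_stats(t$values[, ib, drop = FALSE])
  se2 <- a$var / a$n + b$var / b$n
  stat <- ifelse(se2 > 0, (b$mean - a$mean) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((a$var / a$n)^2 / (a$n - 1) +
                        (b$var / b$n)^2 / (b$n - 1)),
               NA_real_)
  p <- ifelse(is.na(stat), NA_real_, 2 * stats::pt(-abs(stat), df))
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (a$mean == b$mean)
    p[eq] <- 1; stat[eq] <- 0; df[eq] <- a$n + b$n - 2
    ne <- degen & (a$mean != b$mean)
    if (any(ne)) {
      warning(sum(ne), " zero-variance feature(s) with unequal means: p = 0")
      p[ne] <- 0; stat[ne] <- Inf * sign(b$mean - a$mean)[ne]
      df[ne] <- a$n + b$n - 2
    }
  }
  raw <- raw_for_fc(t)
  mean_a <- rowMeans(raw[, ia, drop = FALSE])
  mean_b <- rowMeans(raw[, ib, drop = FALSE])
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(t$values), mean_a = mean_a, mean_b = mean_b,
             log2fc = log2(mean_b / mean_a), stat = stat, df = df,
             p = p, q = q, significant = !is.na(q) & q < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA per feature
#'
#' Classical one-way fixed-effects ANOVA across three or more condition
#' groups, with BH q-values. For two groups use [welch_de()].
#'
#' @param t a range-scaled `omics_table`.
#' @param groups character vector of >= 3 condition labels.
#' @param fdr_threshold FDR level defining the `significant` column.
#' @return data.frame: `feature`, `stat` (F), `df1`, `df2`, `p`, `q`,
#'   `significant`.
#' @export
anova_de <- function(t, groups, fdr_threshold = 0.1) {
  require_scale(t, "range-scaled", "anova_de")
  if (length(groups) < 3) stop("anova_de needs >= 3 groups (use welch_de)")
  idx <- lapply(groups, function(g) group_index(t, g))
  ns <- lengths(idx)
  if (any(ns < 2)) stop("each group needs >= 2 samples")
  g <- length(groups); ntot <- sum(ns)
  v <- t$values[, unlist(idx), drop = FALSE]
  gmeans <- vapply(idx, function(i)
    rowMeans(t$values[, i, drop = FALSE]), numeric(nrow(t$values)))
  gmeans <- matrix(gmeans, nrow = nrow(t$values))
  grand <- as.vector(gmeans %*% ns) / ntot
  ssb <- as.vector(((gmeans - grand)^2) %*% ns)
  ssw <- numeric(nrow(t$values))
  for (j in seq_along(idx))
    ssw <- ssw + rowSums((t$values[, idx[[j]], drop = FALSE] -
                            gmeans[, j])^2)
  df1 <- g - 1; df2 <- ntot - g
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # all groups identical (ssw = ssb = 0): no evidence of difference
  zero <- ssw == 0 & ssb < .Machine$double.eps * ntot
  f[zero] <- 0; p[zero] <- 1
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(t$values), stat = f, df1 = df1, df2 = df2,
             p = p, q = q, significant = !is.na(q) & q < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative standard deviation QC report
#'
#' Per feature and condition group, RSD = sample standard deviation / mean
#' (a dimensionless precision metric), plus the median RSD across features
#' for each group. Cells with zero mean are excluded with a warning.
#'
#' @param t a raw or imputed `omics_table`.
#' @param grouping condition labels to report (default: all groups).
#' @return list with `rsd` (features x groups matrix) and `group_medians`
#'   (named numeric).
#' @export
compute_rsd <- function(t, grouping = NULL) {
  require_scale(t, c("raw", "imputed"), "compute_rsd")
  groups <- if (is.null(grouping)) levels(t$conditions) else grouping
  rsd <- sapply(groups, function(g) {
    idx <- group_index(t, g)
    m <- t$values[, idx, drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1, stats::sd, na.rm = TRUE)
    out <- sd / mu
    bad <- !is.na(mu) & mu == 0
    if (any(bad)) {
      warning("zero group mean; RSD undefined for ", sum(bad),
              " cell(s) in group ", g)
      out[bad] <- NA_real_
    }
    out
  })
  rsd <- matrix(rsd, nrow = nrow(t$values),
                dimnames = list(rownames(t$values), groups))
  list(rsd = rsd,
       group_medians = apply(rsd, 2, stats::median, na.rm = TRUE))
}

#' Principal component analysis with per-condition confidence ellipses
#'
#' PCA of the samples in feature space (components of the sample covariance
#' of the feature-scaled matrix). Returns per-sample scores, per-feature
#' loadings, explained-variance fractions, and for each condition group a 95%
#' confidence ellipse on the first two components, derived from the group's
#' score covariance and the chi-square(2 df) 0.95 quantile.
#'
#' @param t a range-scaled `omics_table` with >= 2 samples.
#' @param n_components number of components to retain.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance` (fractions),
#'   `ellipses` (per condition: center, axes lengths, rotation matrix; `NULL`
#'   for groups of < 3 samples).
#' @export
run_pca <- function(t, n_components = 2) {
  require_scale(t, "range-scaled", "run_pca")
  x <- base::t(t$values)  # samples x features
  if (nrow(x) < 2) stop("need >= 2 samples")
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(samples, features)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, keep, drop = FALSE]
  ellipses <- list()
  for (g in levels(t$conditions)) {
    idx <- which(as.character(t$conditions) == g)
    if (length(idx) < 3 || n_components < 2) {
      ellipses[g] <- list(NULL)
      next
    }
    s <- scores[idx, 1:2, drop = FALSE]
    ctr <- colMeans(s)
    cv <- stats::cov(s)
    ev <- eigen(cv, symmetric = TRUE)
    r2 <- stats::qchisq(0.95, df = 2)
    ellipses[[g]] <- list(center = ctr,
                          axes = sqrt(pmax(ev$values, 0) * r2),
                          rotation = ev$vectors)
  }
  structure(list(scores = scores,
                 loadings = pc$rotation[, keep, drop = FALSE],
                 explained_variance = evf[keep],
                 ellipses = ellipses),
            class = "pca_result")
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`, which operates on
#' unsquared distances). Items are sorted by id before clustering so the
#' merge order and leaf order are deterministic regardless of input order.
#'
#' @param t a range-scaled `omics_table`.
#' @param axis cluster `"features"` (rows) or `"samples"` (columns).
#' @return the `hclust` object (merge list, heights, leaf order, labels).
#' @export
ward_cluster <- function(t, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  require_scale(t, "range-scaled", "ward_cluster")
  m <- if (axis == "features") t$values else base::t(t$values)
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Per-feature fold-change distribution between two conditions
#'
#' Log2 fold changes of group B over group A on the imputed raw scale, with
#' the median shift and a two-sided sign-test p-value (exact binomial on the
#' nonzero signs) — the summary used to ask whether a whole metabolome is
#' shifted or centered at zero between two states.
#'
#' @param t an imputed or range-scaled `omics_table`.
#' @param group_a,group_b condition labels.
#' @return list: `log2fc` (named numeric), `median`, `sign_test_p`.
#' @export
logfc_distribution <- function(t, group_a, group_b) {
  require_scale(t, c("imputed", "range-scaled"), "logfc_distribution")
  raw <- raw_for_fc(t)
  ia <- group_index(t, group_a); ib <- group_index(t, group_b)
  lfc <- log2(rowMeans(raw[, ib, drop = FALSE]) /
              rowMeans(raw[, ia, drop = FALSE]))
  nz <- lfc[lfc != 0]
  p <- if (length(nz) == 0) 1
       else stats::binom.test(sum(nz > 0), length(nz))$p.value
  list(log2fc = lfc, median = stats::median(lfc), sign_test_p = p)
}
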