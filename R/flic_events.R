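# Feeding-bout detection from 5 Hz fly-to-liquid-food interaction signals and
# the bootstrap / randomization statistics used to compare groups of flies.
#
# Conventions (all parameterized): an interaction is a sample strictly above
# the signal threshold (default 40); a feeding event is a maximal run of at
# least 5 consecutive interactions; a run still above threshold at the final
# sample is censored (the event did not conclude before the recording ended);
# events separated by even a single below-threshold sample are distinct.
# Durations are reported in seconds, intervals and latency in minutes.

#' Construct a FLIC trace
#'
#' @param signal numeric vector of finite signal samples (arbitrary units).
#' @param fly_id identifier of the fly/well.
#' @param device identifier of the recording device (the bootstrap stratum).
#' @param sample_rate samples per second (5 Hz for this assay).
#' @return a `flic_trace`.
#' @export
flic_trace <- function(signal, fly_id = "fly", device = "device1",
                       sample_rate = 5) {
  signal <- as.numeric(signal)
  if (length(signal) == 0) stop("signal must be non-empty")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(signal = signal, fly_id = as.character(fly_id),
                 device = as.character(device), sample_rate = sample_rate),
            class = "flic_trace")
}

#' @export
print.flic_trace <- function(x, ...) {
  cat(sprintf("flic_trace %s (device %s): %d samples @ %g Hz = %.1f s\n",
              x$fly_id, x$device, length(x$signal), x$sample_rate,
              length(x$signal) / x$sample_rate))
  invisible(x)
}

#' Read FLIC traces from a long CSV
#'
#' Expects columns `device`, `fly`, `sample`, `signal`; one row per sample.
#' Samples are ordered by the `sample` index within each fly.
#'
#' @param path CSV file.
#' @param sample_rate samples per second.
#' @return named list of `flic_trace` objects (one per fly).
#' @export
read_flic_csv <- function(path, sample_rate = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device", "fly", "sample", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("FLIC CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (f in unique(df$fly)) {
    sub <- df[df$fly == f, , drop = FALSE]
    sub <- sub[order(sub$sample), , drop = FALSE]
    out[[as.character(f)]] <- flic_trace(sub$signal, fly_id = f,
                                         device = sub$device[1],
                                         sample_rate = sample_rate)
  }
  out
}

#' Detect feeding interactions
#'
#' An interaction is a sample strictly greater than the threshold.
#'
#' @param tr a `flic_trace`.
#' @param threshold signal threshold (default 40).
#' @return list: `mask` (logical per sample), `count`.
#' @export
detect_interactions <- function(tr, threshold = 40) {
  stopifnot(inherits(tr, "flic_trace"))
  mask <- tr$signal > threshold
  list(mask = mask, count = sum(mask))
}

#' Detect feeding events from an interaction mask
#'
#' Maximal runs of `TRUE` of length at least `min_run` become events. When
#' `censor_end` is set (the default), a run still active at the final sample
#' is discarded: the event was not concluded before the recording ended.
#'
#' @param mask logical vector from [detect_interactions()].
#' @param min_run minimum run length in samples (default 5).
#' @param censor_end drop an event that touches the last sample.
#' @param sample_rate samples per second, for durations.
#' @return data.frame: `start`, `end` (1-based inclusive sample indices),
#'   `length` (samples), `duration` (seconds); zero rows when no events.
#' @export
detect_events <- function(mask, min_run = 5, censor_end = TRUE,
                          sample_rate = 5) {
  stopifnot(is.logical(mask))
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), duration = numeric(0))
  if (length(mask) == 0 || !any(mask)) return(empty)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (censor_end && any(ok))
    ok <- ok & ends != length(mask)
  if (!any(ok)) return(empty)
  ev <- data.frame(start = starts[ok], end = ends[ok],
                   length = r$lengths[ok])
  ev$duration <- ev$length / sample_rate
  rownames(ev) <- NULL
  ev
}

#' Summarize one fly's feeding behavior
#'
#' Computes the per-fly statistics: interaction count, event count, mean
#' event duration (seconds), mean inter-event interval (minutes; only the
#' gaps between consecutive events — not the time before the first or after
#' the last event — and defined only for flies with at least two events), and
#' latency to the first interaction (minutes; `NA` if the fly never
#' interacted, in which case it is flagged a non-eater).
#'
#' @param tr a `flic_trace`.
#' @param threshold interaction threshold.
#' @param min_run minimum event run length.
#' @param censor_end censor events touching the final sample.
#' @return list of class `feeding_summary`: `fly_id`, `device`,
#'   `n_interactions`, `n_events`, `mean_event_duration` (s),
#'   `mean_inter_event_interval` (min), `latency` (min), `eater` (logical).
#' @export
summarize_fly <- function(tr, threshold = 40, min_run = 5, censor_end = TRUE) {
  stopifnot(inherits(tr, "flic_trace"))
  det <- detect_interactions(tr, threshold)
  ev <- detect_events(det$mask, min_run = min_run, censor_end = censor_end,
                      sample_rate = tr$sample_rate)
  n_ev <- nrow(ev)
  mean_dur <- if (n_ev > 0) mean(ev$duration) else NA_real_
  iei <- NA_real_
  if (n_ev >= 2) {
    gaps <- ev$start[-1] - ev$end[-n_ev] - 1L   # samples strictly between
    iei <- mean(gaps) / tr$sample_rate / 60
  }
  latency <- if (det$count > 0)
    (which(det$mask)[1] - 1L) / tr$sample_rate / 60 else NA_real_
  structure(list(fly_id = tr$fly_id, device = tr$device,
                 n_interactions = det$count, n_events = n_ev,
                 mean_event_duration = mean_dur,
                 mean_inter_event_interval = iei,
                 latency = latency, eater = det$count > 0),
            class = "feeding_summary")
}

#' @export
print.feeding_summary <- function(x, ...) {
  cat(sprintf(paste0("feeding_summary %s: %d interactions, %d events, ",
                     "mean duration %.2f s, mean interval %.3f min, ",
                     "latency %.3f min\n"),
              x$fly_id, x$n_interactions, x$n_events,
              x$mean_event_duration, x$mean_inter_event_interval, x$latency))
  invisible(x)
}

#' Summarize a set of flies into one table
#'
#' @param traces list of `flic_trace` objects.
#' @inheritParams summarize_fly
#' @return data.frame with one row per fly.
#' @export
summarize_flies <- function(traces, threshold = 40, min_run = 5,
                            censor_end = TRUE) {
  rows <- lapply(traces, function(tr) {
    s <- summarize_fly(tr, threshold, min_run, censor_end)
    data.frame(fly_id = s$fly_id, device = s$device,
               n_interactions = s$n_interactions, n_events = s$n_events,
               mean_event_duration = s$mean_event_duration,
               mean_inter_event_interval = s$mean_inter_event_interval,
               latency = s$latency, eater = s$eater,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stratified_resample <- function(values, strata) {
  idx <- integer(0)
  for (s in unique(strata)) {
    pos <- which(strata == s)
    idx <- c(idx, pos[sample.int(length(pos), length(pos), replace = TRUE)])
  }
  values[idx]
}

#' Stratified BCa bootstrap confidence interval for the median
#'
#' Resamples flies with replacement within each stratum (recording device) to
#' control for batch effects, and builds a bias-corrected accelerated (BCa)
#' 95% interval around the median: the bias correction comes from the
#' bootstrap distribution's position relative to the observed median, the
#' acceleration from the jackknife skewness. Fully reproducible given `seed`.
#'
#' @param values numeric per-fly statistic.
#' @param strata device id per fly (same length as `values`); a stratum of
#'   size 1 contributes its single value, with a warning.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (required; every stochastic routine in this
#'   package takes one).
#' @param conf confidence level.
#' @return list of class `bootstrap_result`: `estimate` (observed median),
#'   `ci_low`, `ci_high`, `n_boot`, `method = "BCa"`.
#' @export
stratified_bca_bootstrap <- function(values, strata = NULL, n_boot = 1000,
                                     seed, conf = 0.95) {
  if (missing(seed)) stop("seed is required")
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need >= 2 values")
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.character(strata)
  if (length(strata) != n) stop("strata must match values in length")
  singletons <- names(which(table(strata) == 1))
  if (length(singletons) > 0)
    warning("stratum/strata of size 1 (contribute a constant value): ",
            paste(singletons, collapse = ", "))

  obs <- stats::median(values)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(stratified_resample(values, strata)), numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  alpha <- (1 - conf) / 2
  if (diff(range(boots)) == 0) {
    ci <- c(boots[1], boots[1])
  } else {
    # bias correction
    prop <- mean(boots < obs) + 0.5 * mean(boots == obs)
    prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
    z0 <- stats::qnorm(prop)
    # jackknife acceleration
    jack <- vapply(seq_len(n), function(i)
      stats::median(values[-i]), numeric(1))
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    a <- if (den == 0) 0 else num / den
    zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
    p_lo <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
    p_hi <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
    ci <- stats::quantile(boots, c(p_lo, p_hi), names = FALSE, type = 7)
  }
  structure(list(estimate = obs, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, method = "BCa"),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("median %.4g, 95%% %s CI [%.4g, %.4g] (%d replicates)\n",
              x$estimate, x$method, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Stratified randomization test on the difference in medians
#'
#' Builds the null distribution by permuting group labels within strata and
#' recomputing the median difference; the two-sided p-value is
#' `(1 + #{|null| >= |observed|}) / (1 + n_perm)`. Degenerate data with zero
#' observed and null differences give p = 1.
#'
#' @param group_a,group_b numeric per-fly statistics.
#' @param strata_a,strata_b device ids aligned with the two groups; default
#'   places everything in one stratum.
#' @param n_perm number of label permutations.
#' @param seed integer seed (required).
#' @return list: `p`, `observed` (median(B) - median(A)), `n_perm`.
#' @export
randomization_test_medians <- function(group_a, group_b,
                                       strata_a = NULL, strata_b = NULL,
                                       n_perm = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (is.null(strata_a)) strata_a <- rep("all", length(a))
  if (is.null(strata_b)) strata_b <- rep("all", length(b))
  values <- c(a, b)
  strata <- as.character(c(strata_a, strata_b))
  labels <- rep(c("a", "b"), c(length(a), length(b)))
  obs <- stats::median(b) - stats::median(a)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed(seed)
  stratum_pos <- split(seq_along(values), strata)
  null_diffs <- vapply(seq_len(n_perm), function(i) {
    perm <- labels
    for (pos in stratum_pos)
      perm[pos] <- labels[pos][sample.int(length(pos))]
    stats::median(values[perm == "b"]) - stats::median(values[perm == "a"])
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  p <- (1 + sum(abs(null_diffs) >= abs(obs))) / (1 + n_perm)
  list(p = p, observed = obs, n_perm = n_perm)
}
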