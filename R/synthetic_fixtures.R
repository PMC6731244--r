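# Deterministic generators: a toy pathway database, omics tables with planted
# structure, and two-state feeding traces. Every generator is a pure function
# of its spec (seed included); repeated calls are byte-identical.

lc <- function(...) list(c(...))

#' Build the packaged toy metabolic database
#'
#' Two variants. `"tca"`: 9 compounds and 8 reactions forming a closed
#' citric-acid cycle (acetyl-CoA + oxaloacetate through citrate, aconitate,
#' isocitrate, alpha-ketoglutarate, succinate, fumarate, malate and back).
#' `"tca+glycolysis+bcaa"` adds a 5-reaction glycolysis chain feeding
#' acetyl-CoA and a branched-chain amino-acid transamination reaction whose
#' enzyme is encoded by a gene modeled on the fly transaminase *CG1673*, for
#' 18 compounds, 14 reactions, 9 enzymes, 11 genes (one deliberately
#' isolated), and 3 pathways. All construction is literal; no randomness.
#'
#' @param variant `"tca"` or `"tca+glycolysis+bcaa"`.
#' @return a `metabolic_db`.
#' @export
make_toy_database <- function(variant = c("tca+glycolysis+bcaa", "tca")) {
  variant <- match.arg(variant)

  tca_compounds <- data.frame(
    id = c("C-ACCOA", "C-CIT", "C-ACON", "C-ICIT", "C-AKG",
           "C-SUCC", "C-FUM", "C-MAL", "C-OAA"),
    name = c("acetyl-CoA", "citrate", "aconitate", "isocitrate",
             "alpha-ketoglutarate", "succinate", "fumarate", "malate",
             "oxaloacetate"),
    class_label = rep("energy", 9),
    stringsAsFactors = FALSE)
  tca_compounds$synonyms <- list(
    c("acetyl coenzyme A"), c("citric acid"), c("cis-aconitate"),
    c("isocitric acid"), c("2-oxoglutarate", "alpha-KG"),
    c("succinic acid"), c("fumaric acid"), c("malic acid", "L-malate"),
    c("oxalacetate"))
  tca_compounds$xrefs <- list(
    c(KEGG = "C00024"), c(KEGG = "C00158"), c(KEGG = "C00417"),
    c(KEGG = "C00311"), c(KEGG = "C00026"), c(KEGG = "C00042"),
    c(KEGG = "C00122"), c(KEGG = "C00149"), c(KEGG = "C00036"))

  tca_reactions <- data.frame(
    id = paste0("R-TCA-", 1:8),
    reversible = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  tca_reactions$substrate_ids <- list(
    c("C-ACCOA", "C-OAA"), "C-CIT", "C-ACON", "C-ICIT", "C-AKG",
    "C-SUCC", "C-FUM", "C-MAL")
  tca_reactions$product_ids <- list(
    "C-CIT", "C-ACON", "C-ICIT", "C-AKG", "C-SUCC",
    "C-FUM", "C-MAL", "C-OAA")
  tca_reactions$enzyme_ids <- list(
    "E-CS", "E-ACO", "E-ACO", "E-IDH", character(0),
    "E-SDH", "E-FUM", "E-MDH")
  tca_reactions$pathway_ids <- rep(list("PWY-TCA"), 8)

  tca_enzymes <- data.frame(
    id = c("E-CS", "E-ACO", "E-IDH", "E-SDH", "E-FUM", "E-MDH"),
    name = c("citrate synthase", "aconitase", "isocitrate dehydrogenase",
             "succinate dehydrogenase", "fumarase", "malate dehydrogenase"),
    stringsAsFactors = FALSE)
  tca_enzymes$gene_ids <- list(
    "FBgn0000001", "FBgn0000002", "FBgn0000003",
    c("FBgn0000004", "FBgn0000005"), "FBgn0000006", "FBgn0000007")
  tca_enzymes$reaction_ids <- list(
    "R-TCA-1", c("R-TCA-2", "R-TCA-3"), "R-TCA-4",
    "R-TCA-6", "R-TCA-7", "R-TCA-8")

  tca_genes <- data.frame(
    id = paste0("FBgn000000", 1:7),
    symbol = c("kdn", "Acon", "Idh", "SdhA", "SdhB", "Fum1", "Mdh1"),
    stringsAsFactors = FALSE)
  tca_genes$enzyme_ids <- list(
    "E-CS", "E-ACO", "E-IDH", "E-SDH", "E-SDH", "E-FUM", "E-MDH")

  tca_pathways <- data.frame(id = "PWY-TCA", name = "TCA cycle",
                             stringsAsFactors = FALSE)
  tca_pathways$compound_ids <- list(tca_compounds$id)
  tca_pathways$reaction_ids <- list(tca_reactions$id)

  if (variant == "tca")
    return(metabolic_db(tca_compounds, tca_reactions, tca_enzymes, tca_genes,
                        tca_pathways, provenance = "toy:tca"))

  more_compounds <- data.frame(
    id = c("C-GLC", "C-G6P", "C-PEP", "C-PYR", "C-LAC",
           "C-LEU", "C-VAL", "C-ILE", "C-KMVA"),
    name = c("glucose", "glucose-6-phosphate", "phosphoenolpyruvate",
             "pyruvate", "lactate", "leucine", "valine", "isoleucine",
             "4-methyl-2-oxopentanoate"),
    class_label = c(rep("carbohydrate", 5), rep("amino acid", 3),
                    "amino acid"),
    stringsAsFactors = FALSE)
  more_compounds$synonyms <- list(
    c("D-glucose", "dextrose"), c("G6P"), c("PEP"), c("pyruvic acid"),
    c("lactic acid", "L-lactate"), c("L-leucine"), c("L-valine"),
    c("L-isoleucine"), c("ketoleucine", "BCKA"))
  more_compounds$xrefs <- list(
    c(KEGG = "C00031"), c(KEGG = "C00092"), c(KEGG = "C00074"),
    c(KEGG = "C00022"), c(KEGG = "C00186"), c(KEGG = "C00123"),
    c(KEGG = "C00183"), c(KEGG = "C00407"), c(KEGG = "C00233"))

  more_reactions <- data.frame(
    id = c(paste0("R-GLY-", 1:5), "R-BCAA-1"),
    reversible = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  more_reactions$substrate_ids <- list(
    "C-GLC", "C-G6P", "C-PEP", "C-PYR", "C-PYR",
    c("C-LEU", "C-VAL", "C-ILE", "C-AKG"))
  more_reactions$product_ids <- list(
    "C-G6P", "C-PEP", "C-PYR", "C-LAC", "C-ACCOA", "C-KMVA")
  more_reactions$enzyme_ids <- list(
    "E-HEX", character(0), "E-PYK", character(0), character(0), "E-BCAT")
  more_reactions$pathway_ids <- c(rep(list("PWY-GLYCOLYSIS"), 5),
                                  list("PWY-BCAA"))

  more_enzymes <- data.frame(
    id = c("E-HEX", "E-PYK", "E-BCAT"),
    name = c("hexokinase", "pyruvate kinase",
             "branched-chain amino acid transaminase"),
    stringsAsFactors = FALSE)
  more_enzymes$gene_ids <- list("FBgn0000008", "FBgn0000009", "FBgn0000010")
  more_enzymes$reaction_ids <- list("R-GLY-1", "R-GLY-3", "R-BCAA-1")

  more_genes <- data.frame(
    id = c("FBgn0000008", "FBgn0000009", "FBgn0000010", "FBgn0000011"),
    symbol = c("Hex-A", "PyK", "CG1673", "bmm"),
    stringsAsFactors = FALSE)
  # bmm is deliberately isolated: a gene with no enzyme link is legal
  more_genes$enzyme_ids <- list("E-HEX", "E-PYK", "E-BCAT", character(0))

  more_pathways <- data.frame(
    id = c("PWY-GLYCOLYSIS", "PWY-BCAA"),
    name = c("glycolysis", "branched-chain amino acid metabolism"),
    stringsAsFactors = FALSE)
  more_pathways$compound_ids <- list(
    c("C-GLC", "C-G6P", "C-PEP", "C-PYR", "C-LAC", "C-ACCOA"),
    c("C-LEU", "C-VAL", "C-ILE", "C-AKG", "C-KMVA"))
  more_pathways$reaction_ids <- list(paste0("R-GLY-", 1:5), "R-BCAA-1")

  metabolic_db(rbind(tca_compounds, more_compounds),
               rbind(tca_reactions, more_reactions),
               rbind(tca_enzymes, more_enzymes),
               rbind(tca_genes, more_genes),
               rbind(tca_pathways, more_pathways),
               provenance = "toy:tca+glycolysis+bcaa")
}

#' Simulation specification for synthetic data
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults emulate the study design the package targets: ~391 compounds
#' measured across 12 condition groups with ~5 replicates each, log-normal
#' mass-spectrometry-like abundances with a within-group coefficient of
#' variation of 30% (the reported median per-condition RSD), low missingness
#' produced by per-condition left-censoring plus random dropout, and 1-hour
#' 5 Hz feeding traces with roughly one bout every two minutes of ~2 s
#' duration.
#'
#' @param seed mandatory integer seed.
#' @param n_features number of compounds.
#' @param n_conditions number of condition groups.
#' @param replicates samples per condition.
#' @param baseline_log_mean mean of log abundance (natural log).
#' @param cv within-group coefficient of variation of abundances.
#' @param effects `NULL` or data.frame (`feature`, `condition`, `log2fc`)
#'   of planted multiplicative contrasts relative to baseline.
#' @param dropout_rate random missingness rate in [0, 1].
#' @param censor_quantile per-condition left-censoring quantile in [0, 1):
#'   values below this quantile of the condition's detection scale go
#'   missing, emulating condition-dependent detection limits.
#' @param condition_excess_dropout named numeric: extra dropout per condition.
#' @param trace_minutes,bout_rate_per_min,mean_bout_samples,eat_level,base_level
#'   feeding-trace model: recording length, bout initiation rate, mean bout
#'   length in samples (minimum 5), and the signal levels of the eating and
#'   baseline states.
#' @return a validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, n_features = 391, n_conditions = 12,
                            replicates = 5, baseline_log_mean = log(1e6),
                            cv = 0.3, effects = NULL, dropout_rate = 0.02,
                            censor_quantile = 0.02,
                            condition_excess_dropout = NULL,
                            trace_minutes = 60, bout_rate_per_min = 0.5,
                            mean_bout_samples = 10, eat_level = 100,
                            base_level = 10) {
  if (missing(seed)) stop("simulation_spec: seed is mandatory")
  chk01 <- function(x, nm) if (any(x < 0 | x > 1))
    stop("simulation_spec: ", nm, " must be in [0, 1]")
  chk01(dropout_rate, "dropout_rate")
  chk01(censor_quantile, "censor_quantile")
  if (!is.null(condition_excess_dropout))
    chk01(condition_excess_dropout, "condition_excess_dropout")
  if (n_features < 1) stop("simulation_spec: n_features must be >= 1")
  if (replicates < 2) stop("simulation_spec: replicates must be >= 2")
  if (cv <= 0) stop("simulation_spec: cv must be positive")
  if (!is.null(effects)) {
    need <- c("feature", "condition", "log2fc")
    miss <- setdiff(need, names(effects))
    if (length(miss) > 0)
      stop("simulation_spec: effects missing column(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_features = n_features,
                 n_conditions = n_conditions, replicates = replicates,
                 baseline_log_mean = baseline_log_mean, cv = cv,
                 effects = effects, dropout_rate = dropout_rate,
                 censor_quantile = censor_quantile,
                 condition_excess_dropout = condition_excess_dropout,
                 trace_minutes = trace_minutes,
                 bout_rate_per_min = bout_rate_per_min,
                 mean_bout_samples = mean_bout_samples,
                 eat_level = eat_level, base_level = base_level),
            class = "simulation_spec")
}

#' Simulate an omics table with planted structure
#'
#' Log-normal abundances: feature `f` in condition `c` has log-mean
#' `baseline_log_mean + log-offset(f) + log(2) * log2fc(f, c)` with log-sd
#' derived from the CV; per-feature baseline offsets spread the features over
#' roughly two orders of magnitude. Missingness is left-censoring below the
#' condition's detection quantile plus independent random dropout (optionally
#' higher in named conditions). The planted effect table is returned as
#' ground truth for recovery tests.
#'
#' @param spec a [simulation_spec()].
#' @return list: `table` (a raw `omics_table`), `truth` (the effects
#'   data.frame, possibly empty).
#' @export
simulate_omics_table <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  feats <- sprintf("feat%04d", seq_len(spec$n_features))
  conds <- sprintf("cond%02d", seq_len(spec$n_conditions))
  samples <- as.vector(outer(seq_len(spec$replicates), conds,
                             function(r, c) paste0(c, "_rep", r)))
  cond_of <- rep(conds, each = spec$replicates)
  sdlog <- sqrt(log(1 + spec$cv^2))

  base_off <- stats::rnorm(spec$n_features, 0, 1)  # ~2 orders of magnitude
  lmu <- matrix(spec$baseline_log_mean + base_off,
                nrow = spec$n_features, ncol = length(samples))
  truth <- spec$effects
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      fi <- match(truth$feature[i], feats)
      if (is.na(fi)) stop("effects: unknown feature ", truth$feature[i])
      ci <- cond_of == truth$condition[i]
      if (!any(ci)) stop("effects: unknown condition ", truth$condition[i])
      lmu[fi, ci] <- lmu[fi, ci] + log(2) * truth$log2fc[i]
    }
  } else {
    truth <- data.frame(feature = character(0), condition = character(0),
                        log2fc = numeric(0), stringsAsFactors = FALSE)
  }
  v <- matrix(stats::rlnorm(length(lmu), meanlog = as.vector(lmu),
                            sdlog = sdlog),
              nrow = spec$n_features,
              dimnames = list(feats, samples))

  # left-censoring below the per-condition detection quantile
  if (spec$censor_quantile > 0) {
    for (c in conds) {
      idx <- which(cond_of == c)
      lim <- stats::quantile(v[, idx], spec$censor_quantile, names = FALSE)
      v[, idx][v[, idx] < lim] <- NA
    }
  }
  # random dropout, optionally boosted per condition
  drop_p <- matrix(spec$dropout_rate, nrow = nrow(v), ncol = ncol(v))
  if (!is.null(spec$condition_excess_dropout)) {
    for (c in names(spec$condition_excess_dropout)) {
      idx <- which(cond_of == c)
      drop_p[, idx] <- drop_p[, idx] + spec$condition_excess_dropout[[c]]
    }
  }
  if (any(drop_p > 0))
    v[matrix(stats::runif(length(v)), nrow = nrow(v)) < drop_p] <- NA

  tab <- omics_table(v, stats::setNames(cond_of, samples))
  list(table = tab, truth = truth)
}

#' Simulate 5 Hz feeding traces with known bout ground truth
#'
#' A two-state renewal process: from the baseline state, a bout starts at
#' each sample with probability `bout_rate_per_min / (60 * 5)`; bout length
#' is `5 + Geometric` with the requested mean (so every generated bout is a
#' detectable event); signal is Gaussian around `eat_level` during bouts and
#' `base_level` otherwise, truncated at zero. True bout intervals are
#' returned for oracle-equality tests.
#'
#' @param spec a [simulation_spec()].
#' @param n_flies number of traces.
#' @return list: `traces` (list of `flic_trace`), `truth` (list of
#'   data.frames with `start`, `end` per fly, 1-based inclusive).
#' @export
simulate_flic_trace <- function(spec, n_flies = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- round(spec$trace_minutes * 60 * 5)
  p_start <- spec$bout_rate_per_min / (60 * 5)
  extra <- max(spec$mean_bout_samples - 5, 0.001)
  traces <- list(); truth <- list()
  for (f in seq_len(n_flies)) {
    eating <- logical(n)
    bouts <- list()
    i <- 1L
    while (i <= n) {
      if (p_start > 0 && stats::runif(1) < p_start) {
        len <- 5L + stats::rgeom(1, prob = 1 / (1 + extra))
        end <- min(i + len - 1L, n)
        eating[i:end] <- TRUE
        bouts[[length(bouts) + 1L]] <- c(start = i, end = end)
        i <- end + 2L  # at least one below-threshold sample between bouts
      } else {
        i <- i + 1L
      }
    }
    sig <- ifelse(eating,
                  stats::rnorm(n, spec$eat_level, 10),
                  stats::rnorm(n, spec$base_level, 5))
    sig <- pmax(sig, 0)
    id <- sprintf("fly%02d", f)
    traces[[id]] <- flic_trace(sig, fly_id = id,
                               device = sprintf("device%d", (f - 1L) %% 4L + 1L))
    truth[[id]] <- if (length(bouts))
      as.data.frame(do.call(rbind, bouts))
    else data.frame(start = integer(0), end = integer(0))
  }
  list(traces = traces, truth = truth)
}
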