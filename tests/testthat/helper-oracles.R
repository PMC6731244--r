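# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, explicit loops, direct formulas) and never call the code paths
# they check.

# single reaction A + B -> C, enzyme E1, genes G1 and G2
mini_db <- function() {
  compounds <- data.frame(id = c("A", "B", "C"),
                          name = c("cpd A", "cpd B", "cpd C"),
                          class_label = "misc", stringsAsFactors = FALSE)
  compounds$synonyms <- list(character(0), character(0), character(0))
  compounds$xrefs <- list(c(KEGG = "C90001"), character(0), character(0))
  reactions <- data.frame(id = "R1", reversible = FALSE,
                          stringsAsFactors = FALSE)
  reactions$substrate_ids <- list(c("A", "B"))
  reactions$product_ids <- list("C")
  reactions$enzyme_ids <- list("E1")
  reactions$pathway_ids <- list("P1")
  enzymes <- data.frame(id = "E1", name = "enzyme one",
                        stringsAsFactors = FALSE)
  enzymes$gene_ids <- list(c("G1", "G2"))
  enzymes$reaction_ids <- list("R1")
  genes <- data.frame(id = c("G1", "G2"), symbol = c("gene1", "gene2"),
                      stringsAsFactors = FALSE)
  genes$enzyme_ids <- list("E1", "E1")
  pathways <- data.frame(id = "P1", name = "mini pathway",
                         stringsAsFactors = FALSE)
  pathways$compound_ids <- list(c("A", "B", "C"))
  pathways$reaction_ids <- list("R1")
  metabolic_db(compounds, reactions, enzymes, genes, pathways,
               provenance = "test:mini")
}

empty_db <- function() {
  compounds <- data.frame(id = character(0), name = character(0),
                          class_label = character(0), stringsAsFactors = FALSE)
  compounds$synonyms <- list(); compounds$xrefs <- list()
  reactions <- data.frame(id = character(0), reversible = logical(0),
                          stringsAsFactors = FALSE)
  reactions$substrate_ids <- list(); reactions$product_ids <- list()
  reactions$enzyme_ids <- list(); reactions$pathway_ids <- list()
  enzymes <- data.frame(id = character(0), name = character(0),
                        stringsAsFactors = FALSE)
  enzymes$gene_ids <- list(); enzymes$reaction_ids <- list()
  genes <- data.frame(id = character(0), symbol = character(0),
                      stringsAsFactors = FALSE)
  genes$enzyme_ids <- list()
  pathways <- data.frame(id = character(0), name = character(0),
                         stringsAsFactors = FALSE)
  pathways$compound_ids <- list(); pathways$reaction_ids <- list()
  metabolic_db(compounds, reactions, enzymes, genes, pathways,
               provenance = "test:empty")
}

# brute-force upper-tail hypergeometric by enumerating all C(N, n) draws
brute_hyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the successes
  mean(hits >= k)
}

# brute-force run detection: explicit sample-by-sample scan
brute_events <- function(mask, min_run = 5, censor_end = TRUE) {
  events <- list()
  i <- 1L; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if ((j - i + 1L) >= min_run && !(censor_end && j == n))
        events[[length(events) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(events) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, events))
}

# build a raw omics_table directly from a matrix of positive values
raw_table <- function(values, conditions) {
  omics_table(values, conditions)
}

# push a raw table through the fixed pipeline
scaled_table <- function(t) {
  range_scale(impute_half_min(filter_missing(t)))
}

# mean silhouette width for a 1-d score split into two known groups
silhouette_1d <- function(x, labels) {
  stopifnot(length(unique(labels)) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# planted two-cluster table: two conditions, strong shared shift on a block
# of features, fixed generator
make_two_cluster_table <- function(seed = 17) {
  spec <- simulation_spec(seed = seed, n_features = 100, n_conditions = 2,
                          replicates = 6, cv = 0.2, dropout_rate = 0,
                          censor_quantile = 0,
                          effects = data.frame(
                            feature = sprintf("feat%04d", 1:30),
                            condition = "cond02", log2fc = 2))
  simulate_omics_table(spec)
}

graph_signature <- function(g) {
  paste(c(g$graph_type, g$nodes$id, g$nodes$kind,
          g$edges$from, g$edges$to, g$edges$role, g$edges$directed,
          g$edges$reaction_id), collapse = "\n")
}
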