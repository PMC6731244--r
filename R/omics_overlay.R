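# Overlay of differential results onto a network graph, and the categorical
# visual-attribute encoding used for display:
#   shape:   compound = hexagon, gene = circle, enzyme = square,
#            reaction = diamond
#   fill:    measured compounds red / unmeasured salmon; measured genes blue /
#            unmeasured light blue; enzymes green; reactions gray
#   size:    base * (1 + size_gain * |log2FC|), clipped to [base, 4*base]
#   outline: green iff measured and q below the kind's significance threshold
# The mapping is a pure function of (measurement record, node kind,
# parameters); the direction of change is carried as its own attribute so the
# linear size encoding stays invertible from exports.

#' Differential-result table constructor
#'
#' Normalizes a per-feature differential table to the three columns the
#' overlay needs. Input may use any superset of columns; `feature`, `log2fc`,
#' and `q` are required (a `welch_de()` result already qualifies via its
#' `feature`, `log2fc`, `q` columns).
#'
#' @param x data.frame with columns `feature`, `log2fc`, `q`.
#' @return data.frame with exactly those columns.
#' @export
differential_table <- function(x) {
  need <- c("feature", "log2fc", "q")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("differential table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$feature))
    stop("duplicate feature rows (pre-aggregate before attaching): ",
         paste(unique(x$feature[duplicated(x$feature)]), collapse = ", "))
  data.frame(feature = as.character(x$feature),
             log2fc = as.numeric(x$log2fc), q = as.numeric(x$q),
             stringsAsFactors = FALSE)
}

empty_differential <- function() {
  data.frame(feature = character(0), log2fc = numeric(0), q = numeric(0),
             stringsAsFactors = FALSE)
}

#' Attach differential omics results to a network graph
#'
#' Matches compound rows against compound nodes and gene rows against gene
#' nodes, using [resolve_ids()] so feature ids may be database ids, names,
#' synonyms, or xref values. Matched nodes become `measured` with their
#' statistics; everything else (including all enzyme and reaction nodes) is
#' unmeasured. A match report (matched/unmatched counts per kind) is stored
#' on the result.
#'
#' @param g a `network_graph`.
#' @param compound_results,gene_results differential tables (see
#'   [differential_table()]); either may be `NULL` or empty.
#' @param db the `metabolic_db` used for identifier resolution.
#' @return an `annotated_graph`: the input graph plus a `measurements`
#'   data.frame (node_id, measured, log2fc, q, direction) and a
#'   `match_report` list.
#' @export
attach_omics <- function(g, compound_results = NULL, gene_results = NULL, db) {
  stopifnot(inherits(g, "network_graph"), inherits(db, "metabolic_db"))
  compound_results <- if (is.null(compound_results)) empty_differential()
                      else differential_table(compound_results)
  gene_results <- if (is.null(gene_results)) empty_differential()
                  else differential_table(gene_results)

  meas <- data.frame(node_id = g$nodes$id, measured = FALSE,
                     log2fc = NA_real_, q = NA_real_,
                     direction = NA_character_, stringsAsFactors = FALSE)
  report <- list(compound = c(matched = 0L, unmatched = 0L),
                 gene = c(matched = 0L, unmatched = 0L))

  attach_kind <- function(results, kind) {
    if (nrow(results) == 0) return(invisible())
    res <- resolve_ids(db, results$feature)
    hits <- res$matches[res$matches$entity_kind == kind, , drop = FALSE]
    n_match <- 0L
    for (i in seq_len(nrow(hits))) {
      node <- hits$entity_id[i]
      j <- match(node, meas$node_id)
      if (is.na(j) || g$nodes$kind[match(node, g$nodes$id)] != kind) next
      if (meas$measured[j])
        stop("node ", node, " matched by more than one feature row; ",
             "pre-aggregate the results table")
      row <- results[results$feature == hits$query[i], ]
      meas$measured[j] <<- TRUE
      meas$log2fc[j] <<- row$log2fc
      meas$q[j] <<- row$q
      meas$direction[j] <<- if (is.na(row$log2fc) || row$log2fc == 0) "none"
                            else if (row$log2fc > 0) "up" else "down"
      n_match <- n_match + 1L
    }
    report[[kind]] <<- c(matched = n_match,
                         unmatched = nrow(results) - n_match)
  }
  attach_kind(compound_results, "compound")
  attach_kind(gene_results, "gene")

  structure(c(unclass(g),
              list(measurements = meas, match_report = report,
                   styles = NULL)),
            class = c("annotated_graph", "network_graph"))
}

#' @export
print.annotated_graph <- function(x, ...) {
  cat(sprintf("annotated_graph [%s]: %d nodes (%d measured), %d edges\n",
              x$graph_type, nrow(x$nodes), sum(x$measurements$measured),
              nrow(x$edges)))
  invisible(x)
}

node_fill <- function(kind, measured) {
  switch(kind,
    compound = if (measured) "measured-red" else "unmeasured-salmon",
    gene     = if (measured) "measured-blue" else "unmeasured-lightblue",
    enzyme   = "enzyme-green",
    reaction = "reaction-gray")
}

node_shape <- function(kind) {
  switch(kind, compound = "hexagon", gene = "circle", enzyme = "square",
         reaction = "diamond")
}

#' Compute display styles for an annotated graph
#'
#' Derives per-node shape, fill, size, and significance outline. Size is
#' `base_size * (1 + size_gain * |log2FC|)` clipped to `[base_size,
#' 4 * base_size]`; unmeasured nodes sit at base size. The outline is
#' `significant-green` iff the node is measured and its q-value is below the
#' threshold for its kind (metabolite convention FDR < 0.1; gene convention
#' FDR < 0.05). A non-finite fold change demotes the node to unmeasured with
#' a warning.
#'
#' @param ag an `annotated_graph` from [attach_omics()].
#' @param size_gain positive scale factor on `|log2FC|`.
#' @param q_threshold significance threshold for compound nodes.
#' @param q_threshold_gene significance threshold for gene nodes.
#' @param base_size minimum node size in display units.
#' @return the graph with a `styles` data.frame (node_id, shape, fill, size,
#'   outline) filled in.
#' @export
style_nodes <- function(ag, size_gain = 0.5, q_threshold = 0.1,
                        q_threshold_gene = 0.05, base_size = 30) {
  stopifnot(inherits(ag, "annotated_graph"))
  if (size_gain <= 0) stop("size_gain must be positive")
  m <- ag$measurements
  bad <- m$measured & !is.finite(m$log2fc)
  if (any(bad)) {
    warning("non-finite fold change for node(s) ",
            paste(m$node_id[bad], collapse = ", "), "; treated as unmeasured")
    m$measured[bad] <- FALSE
    m$log2fc[bad] <- NA_real_
    m$q[bad] <- NA_real_
  }
  kinds <- ag$nodes$kind[match(m$node_id, ag$nodes$id)]
  size <- ifelse(m$measured,
                 pmin(base_size * (1 + size_gain * abs(m$log2fc)),
                      4 * base_size),
                 base_size)
  size <- pmax(size, base_size)
  thr <- ifelse(kinds == "gene", q_threshold_gene, q_threshold)
  outline <- ifelse(m$measured & !is.na(m$q) & m$q < thr,
                    "significant-green", "none")
  ag$styles <- data.frame(
    node_id = m$node_id,
    shape = vapply(kinds, node_shape, character(1)),
    fill = mapply(node_fill, kinds, m$measured),
    size = size, outline = outline, stringsAsFactors = FALSE)
  rownames(ag$styles) <- NULL
  ag$measurements <- m
  ag
}
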