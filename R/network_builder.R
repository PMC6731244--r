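# Typed-node, mixed-directedness network graphs derived from a metabolic_db.
#
# Four graph types:
#   CREG  compound-reaction-enzyme-gene; compound<->reaction edges directed by
#         substrate/product role, reaction--enzyme and enzyme--gene undirected
#   CR    CREG minus enzyme and gene nodes
#   CG    compound--gene projection of CREG (reaction/enzyme contracted out)
#   C     compounds only; one substrate->product edge per reaction pair,
#         annotated with the generating reaction id; reversible reactions
#         yield a single undirected edge (not two directed ones)
# Same-kind edges never occur in CR/CG/CREG. Nodes and edges are kept in
# lexicographic order so serialized output is reproducible.

empty_nodes <- function() data.frame(id = character(0), kind = character(0),
                                     label = character(0),
                                     stringsAsFactors = FALSE)
empty_edges <- function() data.frame(from = character(0), to = character(0),
                                     directed = logical(0), role = character(0),
                                     reaction_id = character(0),
                                     stringsAsFactors = FALSE)

new_network_graph <- function(nodes, edges, graph_type, provenance) {
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  key <- paste(edges$from, edges$to, edges$role, edges$reaction_id)
  edges <- edges[order(key), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$from, edges$to, edges$role,
                                   edges$reaction_id)), , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, graph_type = graph_type,
                 provenance = provenance),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph [%s]: %d nodes, %d edges\n", x$graph_type,
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes) > 0) {
    tab <- table(x$nodes$kind)
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

db_row <- function(df, id) {
  i <- match(id, df$id)
  if (is.na(i)) NULL else df[i, , drop = FALSE]
}

#' Expand seed compounds and genes to their incident reactions
#'
#' One-step query expansion: a seed compound pulls in every reaction having
#' it among its substrates or products; a seed gene pulls in every reaction
#' catalyzed by an enzyme that gene encodes. No iterative growth beyond this
#' single step.
#'
#' @param db a `metabolic_db`.
#' @param compound_ids,gene_ids character vectors of entity ids (may be
#'   empty). Ids must resolve in `db`; run [resolve_ids()] on free text first.
#' @return sorted character vector of reaction ids.
#' @export
expand_seeds <- function(db, compound_ids = character(0),
                         gene_ids = character(0)) {
  stopifnot(inherits(db, "metabolic_db"))
  bad <- c(setdiff(compound_ids, db$compounds$id),
           setdiff(gene_ids, db$genes$id))
  if (length(bad) > 0)
    stop("unresolvable seed id(s): ", paste(bad, collapse = ", "))
  rxns <- character(0)
  for (c in compound_ids)
    rxns <- c(rxns, db$indices$compound_to_reactions[[c]])
  for (g in gene_ids)
    for (e in db$indices$gene_to_enzymes[[g]])
      rxns <- c(rxns, db$indices$enzyme_to_reactions[[e]])
  sort(unique(rxns))
}

#' Look up the reactions of a canonical pathway
#'
#' @param db a `metabolic_db`.
#' @param pathway_id pathway id present in `db`.
#' @return sorted character vector of the pathway's reaction ids.
#' @export
query_pathway <- function(db, pathway_id) {
  stopifnot(inherits(db, "metabolic_db"))
  i <- match(pathway_id, db$pathways$id)
  if (is.na(i)) stop("unknown pathway id: ", pathway_id)
  sort(unique(db$pathways$reaction_ids[[i]]))
}

# enzymes catalyzing a reaction = union of the reaction's enzyme list and
# the reverse index (enzymes declaring the reaction)
reaction_enzymes <- function(db, rid) {
  r <- db_row(db$reactions, rid)
  direct <- r$enzyme_ids[[1]]
  rev <- db$enzymes$id[vapply(db$enzymes$reaction_ids,
                              function(x) rid %in% x, logical(1))]
  sort(unique(c(direct, rev)))
}

enzyme_genes <- function(db, eid) {
  e <- db_row(db$enzymes, eid)
  direct <- if (is.null(e)) character(0) else e$gene_ids[[1]]
  rev <- db$genes$id[vapply(db$genes$enzyme_ids,
                            function(x) eid %in% x, logical(1))]
  sort(unique(c(direct, rev)))
}

node_label <- function(db, id, kind) {
  switch(kind,
    compound = { r <- db_row(db$compounds, id); if (is.null(r)) id else r$name },
    reaction = id,
    enzyme   = { r <- db_row(db$enzymes, id); if (is.null(r)) id else r$name },
    gene     = { r <- db_row(db$genes, id); if (is.null(r)) id else r$symbol })
}

#' Build a network graph from a set of reactions
#'
#' Constructs one of the four graph types over the full closure of
#' `reaction_ids`: all participating compounds, all catalyzing enzymes, and
#' all genes encoding those enzymes. Nodes of the same kind are never
#' connected in CR/CG/CREG; substrate/product edges are directed, catalysis
#' and encoding edges undirected. In C graphs every (substrate, product,
#' reaction) triple becomes one edge carrying the reaction id; edges of
#' reversible reactions are marked undirected.
#'
#' @param db a `metabolic_db`.
#' @param reaction_ids character vector of reaction ids (subset of the
#'   database; empty gives an empty graph of the requested type).
#' @param graph_type one of `"C"`, `"CR"`, `"CG"`, `"CREG"`.
#' @param provenance free-text query description stored on the graph.
#' @return a `network_graph`.
#' @examples
#' db <- make_toy_database("tca")
#' g <- build_network(db, query_pathway(db, "PWY-TCA"), "CREG")
#' g
#' @export
build_network <- function(db, reaction_ids,
                          graph_type = c("CREG", "CR", "CG", "C"),
                          provenance = NULL) {
  stopifnot(inherits(db, "metabolic_db"))
  graph_type <- match.arg(graph_type)
  reaction_ids <- unique(as.character(reaction_ids))
  bad <- setdiff(reaction_ids, db$reactions$id)
  if (length(bad) > 0)
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  if (is.null(provenance))
    provenance <- sprintf("build_network(%s; %d reactions)", graph_type,
                          length(reaction_ids))

  if (graph_type == "CG") {
    creg <- build_network(db, reaction_ids, "CREG", provenance = provenance)
    g <- creg_to_cg(creg)
    g$provenance <- provenance
    return(g)
  }

  nodes <- list(); edges <- list()
  add_node <- function(id, kind)
    nodes[[paste(kind, id)]] <<- data.frame(
      id = id, kind = kind, label = node_label(db, id, kind),
      stringsAsFactors = FALSE)
  add_edge <- function(from, to, directed, role, rid = "")
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, directed = directed, role = role,
      reaction_id = rid, stringsAsFactors = FALSE)

  if (graph_type == "C") {
    for (rid in reaction_ids) {
      r <- db_row(db$reactions, rid)
      for (s in r$substrate_ids[[1]]) add_node(s, "compound")
      for (p in r$product_ids[[1]]) add_node(p, "compound")
      for (s in r$substrate_ids[[1]])
        for (p in r$product_ids[[1]])
          add_edge(s, p, directed = !r$reversible, role = "compound-compound",
                   rid = rid)
    }
  } else { # CR or CREG
    for (rid in reaction_ids) {
      r <- db_row(db$reactions, rid)
      add_node(rid, "reaction")
      for (s in r$substrate_ids[[1]]) {
        add_node(s, "compound")
        add_edge(s, rid, directed = TRUE, role = "substrate", rid = rid)
      }
      for (p in r$product_ids[[1]]) {
        add_node(p, "compound")
        add_edge(rid, p, directed = TRUE, role = "product", rid = rid)
      }
      if (graph_type == "CREG") {
        for (e in reaction_enzymes(db, rid)) {
          add_node(e, "enzyme")
          add_edge(rid, e, directed = FALSE, role = "catalysis", rid = rid)
          for (g in enzyme_genes(db, e)) {
            add_node(g, "gene")
            add_edge(e, g, directed = FALSE, role = "encoding")
          }
        }
      }
    }
  }

  nodes <- if (length(nodes)) do.call(rbind, unname(nodes)) else empty_nodes()
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  new_network_graph(nodes, edges, graph_type, provenance)
}

#' Contract a CREG graph to its compound-gene projection
#'
#' Reaction and enzyme nodes are removed; an undirected compound--gene edge is
#' created whenever a compound--reaction--enzyme--gene path exists in the
#' input. Duplicate paths collapse to a single edge. The result is
#' byte-identical to building a CG graph directly from the same reaction set.
#'
#' @param g a `network_graph` of type CREG.
#' @return a `network_graph` of type CG.
#' @export
creg_to_cg <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  if (g$graph_type != "CREG")
    stop("creg_to_cg requires a CREG graph, got ", g$graph_type)
  nodes <- g$nodes[g$nodes$kind %in% c("compound", "gene"), , drop = FALSE]
  e <- g$edges
  # compound--reaction incidences (either direction)
  cr <- e[e$role %in% c("substrate", "product"), , drop = FALSE]
  comp_of <- data.frame(
    compound = ifelse(cr$role == "substrate", cr$from, cr$to),
    reaction = ifelse(cr$role == "substrate", cr$to, cr$from),
    stringsAsFactors = FALSE)
  re <- e[e$role == "catalysis", , drop = FALSE]   # reaction--enzyme
  eg <- e[e$role == "encoding", , drop = FALSE]    # enzyme--gene
  edges <- empty_edges()
  if (nrow(comp_of) > 0 && nrow(re) > 0 && nrow(eg) > 0) {
    m1 <- merge(comp_of, data.frame(reaction = re$from, enzyme = re$to,
                                    stringsAsFactors = FALSE), by = "reaction")
    m2 <- merge(m1, data.frame(enzyme = eg$from, gene = eg$to,
                               stringsAsFactors = FALSE), by = "enzyme")
    if (nrow(m2) > 0) {
      pairs <- unique(m2[, c("compound", "gene")])
      edges <- data.frame(from = pairs$compound, to = pairs$gene,
                          directed = FALSE, role = "compound-gene",
                          reaction_id = "", stringsAsFactors = FALSE)
    }
  }
  new_network_graph(nodes, edges, "CG",
                    paste0(g$provenance, " | contracted to CG"))
}

#' Extract a subnetwork by pathway or node set
#'
#' In node-set mode, returns the induced subgraph on the kept node ids. In
#' pathway mode (`keep` is a single pathway id present in `db`), the kept set
#' is every node generated by that pathway's reactions for the graph's own
#' type. The graph type is preserved and the provenance records the
#' refinement. An empty result is returned with a warning, not an error.
#'
#' @param g a `network_graph`.
#' @param keep a pathway id or a character vector of node ids.
#' @param db the `metabolic_db` the graph was built from (needed for pathway
#'   mode).
#' @return a `network_graph` of the same type.
#' @export
extract_subnetwork <- function(g, keep, db = NULL) {
  stopifnot(inherits(g, "network_graph"))
  if (length(keep) == 0) stop("keep must be non-empty")
  if (length(keep) == 1 && !is.null(db) && keep %in% db$pathways$id) {
    ref <- build_network(db, query_pathway(db, keep), g$graph_type)
    keep_ids <- ref$nodes$id
    mode <- paste0("pathway:", keep)
  } else {
    keep_ids <- as.character(keep)
    mode <- sprintf("nodes:%d", length(keep_ids))
  }
  nodes <- g$nodes[g$nodes$id %in% keep_ids, , drop = FALSE]
  edges <- g$edges[g$edges$from %in% nodes$id & g$edges$to %in% nodes$id, ,
                   drop = FALSE]
  if (nrow(nodes) == 0) warning("subnetwork is empty: no surviving nodes")
  new_network_graph(nodes, edges, g$graph_type,
                    paste0(g$provenance, " | subnetwork(", mode, ")"))
}
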