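test_that("expand_seeds pulls exactly the incident reactions", {
  db <- make_toy_database()
  expect_identical(expand_seeds(db, "C-MAL"), c("R-TCA-7", "R-TCA-8"))
  expect_identical(expand_seeds(db), character(0))
  # kdn encodes citrate synthase, which catalyzes only R-TCA-1
  expect_identical(expand_seeds(db, gene_ids = "FBgn0000001"), "R-TCA-1")
  expect_error(expand_seeds(db, "nope"), "nope")
})

test_that("query_pathway returns the pathway's reaction set", {
  db <- make_toy_database()
  expect_identical(query_pathway(db, "PWY-TCA"), sort(paste0("R-TCA-", 1:8)))
  expect_error(query_pathway(db, "PWY-NOPE"), "PWY-NOPE")

  # a pathway with no reactions is legal and yields the empty set
  db$pathways <- rbind(db$pathways,
                       data.frame(id = "PWY-EMPTY", name = "empty",
                                  compound_ids = I(list(character(0))),
                                  reaction_ids = I(list(character(0)))))
  db2 <- do.call(metabolic_db, db[c("compounds", "reactions", "enzymes",
                                    "genes", "pathways")])
  expect_identical(query_pathway(db2, "PWY-EMPTY"), character(0))
})

test_that("single-reaction CREG and C graphs match hand enumeration", {
  db <- mini_db()
  g <- build_network(db, "R1", "CREG")
  expect_identical(nrow(g$nodes), 7L)   # A B C R1 E1 G1 G2
  expect_identical(nrow(g$edges), 6L)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("A R1", "B R1", "R1 C", "R1 E1", "E1 G1", "E1 G2"))
  expect_true(all(g$edges$directed[g$edges$role %in% c("substrate", "product")]))
  expect_false(any(g$edges$directed[g$edges$role %in% c("catalysis", "encoding")]))

  c_graph <- build_network(db, "R1", "C")
  expect_identical(nrow(c_graph$nodes), 3L)
  expect_identical(nrow(c_graph$edges), 2L)
  expect_setequal(paste(c_graph$edges$from, c_graph$edges$to),
                  c("A C", "B C"))
  expect_true(all(c_graph$edges$directed))
  expect_true(all(c_graph$edges$reaction_id == "R1"))

  empty <- build_network(db, character(0), "CREG")
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("reversible reactions give undirected C-graph edges", {
  db <- make_toy_database("tca")
  g <- build_network(db, "R-TCA-7", "C")  # fumarate <-> malate
  expect_identical(nrow(g$edges), 1L)
  expect_false(g$edges$directed)
})

test_that("creg_to_cg contracts paths to compound-gene edges", {
  db <- mini_db()
  cg <- creg_to_cg(build_network(db, "R1", "CREG"))
  expect_identical(sort(cg$nodes$id), c("A", "B", "C", "G1", "G2"))
  expect_identical(nrow(cg$edges), 6L)  # each compound to each gene
  expect_true(all(cg$edges$role == "compound-gene"))
  expect_false(any(cg$edges$directed))

  # CREG with no genes contracts to compounds only
  db2 <- mini_db()
  db2$genes <- db2$genes[0, , drop = FALSE]
  db2$enzymes$gene_ids <- list(character(0))
  db2 <- do.call(metabolic_db, db2[c("compounds", "reactions", "enzymes",
                                     "genes", "pathways")])
  cg2 <- creg_to_cg(build_network(db2, "R1", "CREG"))
  expect_identical(sort(cg2$nodes$kind), rep("compound", 3))
  expect_identical(nrow(cg2$edges), 0L)

  expect_error(creg_to_cg(build_network(db, "R1", "C")), "CREG")
})

test_that("extract_subnetwork refines by pathway and by node set", {
  db <- make_toy_database()
  full <- build_network(db, db$reactions$id, "CREG")
  sub <- extract_subnetwork(full, "PWY-TCA", db)
  ref <- build_network(db, query_pathway(db, "PWY-TCA"), "CREG")
  expect_identical(sub$nodes, ref$nodes)
  expect_identical(sub$edges, ref$edges)

  all_kept <- extract_subnetwork(full, full$nodes$id, db)
  expect_identical(all_kept$nodes, full$nodes)
  expect_identical(all_kept$edges, full$edges)

  one <- extract_subnetwork(full, "C-LAC", db)
  expect_identical(nrow(one$nodes), 1L)
  expect_identical(nrow(one$edges), 0L)

  expect_warning(extract_subnetwork(full, "not-a-node", db), "no surviving")
})

test_that("graph-type connectivity contracts hold on every built graph", {
  db <- make_toy_database()
  rxns <- db$reactions$id
  for (type in c("CR", "CG", "CREG")) {
    g <- build_network(db, rxns, type)
    kind_of <- stats::setNames(g$nodes$kind, g$nodes$id)
    expect_false(any(kind_of[g$edges$from] == kind_of[g$edges$to]),
                 label = paste("same-kind edge in", type))
  }
  g <- build_network(db, rxns, "C")
  expect_true(all(g$nodes$kind == "compound"))
  expect_true(all(nzchar(g$edges$reaction_id)))

  # degree contract in CREG
  creg <- build_network(db, rxns, "CREG")
  for (rid in creg$nodes$id[creg$nodes$kind == "reaction"]) {
    inc <- creg$edges[creg$edges$role %in% c("substrate", "product") &
                        (creg$edges$from == rid | creg$edges$to == rid), ]
    expect_gte(nrow(inc), 1)
  }
  for (eid in creg$nodes$id[creg$nodes$kind == "enzyme"]) {
    inc <- creg$edges[creg$edges$role == "catalysis" & creg$edges$to == eid, ]
    expect_gte(nrow(inc), 1)
  }

  # shared compounds appear once even when reactions span pathways:
  # acetyl-CoA is in both glycolysis (R-GLY-5) and the TCA cycle (R-TCA-1)
  g2 <- build_network(db, c("R-GLY-5", "R-TCA-1"), "CR")
  expect_identical(sum(g2$nodes$id == "C-ACCOA"), 1L)

  # determinism: identical serialized output on repeated builds
  expect_identical(graph_signature(build_network(db, rev(rxns), "CREG")),
                   graph_signature(build_network(db, rxns, "CREG")))
})
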