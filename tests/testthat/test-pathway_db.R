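test_that("toy fixture loads with the documented entity counts", {
  db <- make_toy_database("tca+glycolysis+bcaa")
  expect_identical(nrow(db$compounds), 18L)
  expect_identical(nrow(db$reactions), 14L)
  expect_identical(nrow(db$enzymes), 9L)
  expect_identical(nrow(db$genes), 11L)
  expect_identical(nrow(db$pathways), 3L)
})

test_that("empty but well-formed tables give an all-zero database", {
  db <- empty_db()
  expect_identical(nrow(db$compounds), 0L)
  expect_identical(nrow(db$reactions), 0L)
  expect_identical(nrow(validate_db(db)), 0L)
})

test_that("native TSV round-trip restores the database entity-by-entity", {
  db <- make_toy_database()
  dir <- withr::local_tempdir()
  write_metabolic_db(db, dir)
  db2 <- read_metabolic_db(dir)
  for (tab in c("compounds", "reactions", "enzymes", "genes", "pathways"))
    expect_equal(db2[[tab]], db[[tab]], ignore_attr = TRUE)
  expect_equal(db2$indices, db$indices)
  # and the second write is byte-identical to the first
  dir2 <- withr::local_tempdir()
  write_metabolic_db(db2, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)))
})

test_that("reader errors name the offending table / row", {
  db <- make_toy_database()
  dir <- withr::local_tempdir()
  write_metabolic_db(db, dir)
  file.remove(file.path(dir, "genes.tsv"))
  expect_error(read_metabolic_db(dir), "genes.tsv")

  dir3 <- withr::local_tempdir()
  write_metabolic_db(db, dir3)
  rx <- readLines(file.path(dir3, "reactions.tsv"))
  rx[2] <- sub("\ttrue\t|\tfalse\t", "\tmaybe\t", rx[2])
  writeLines(rx, file.path(dir3, "reactions.tsv"))
  expect_error(read_metabolic_db(dir3), "row 2")
})

test_that("same compound on both reaction sides is rejected at load", {
  db <- mini_db()
  db$reactions$product_ids[[1]] <- c("C", "A")
  expect_error(do.call(metabolic_db, db[c("compounds", "reactions", "enzymes",
                                          "genes", "pathways")]),
               "both sides")
})

test_that("biocyc-subset dialect reads attribute-value records", {
  dir <- withr::local_tempdir()
  writeLines(c("UNIQUE-ID - CPD-1", "COMMON-NAME - malate",
               "SYNONYMS - malic acid", "DBLINKS - (KEGG \"C00149\")", "//",
               "UNIQUE-ID - CPD-2", "COMMON-NAME - fumarate", "//"),
             file.path(dir, "compounds.dat"))
  writeLines(c("UNIQUE-ID - RXN-1", "LEFT - CPD-2", "RIGHT - CPD-1",
               "REACTION-DIRECTION - REVERSIBLE",
               "ENZYMATIC-REACTION - ENZ-1", "IN-PATHWAY - PWY-1", "//"),
             file.path(dir, "reactions.dat"))
  writeLines(c("UNIQUE-ID - ENZ-1", "COMMON-NAME - fumarase",
               "GENE - G-1", "CATALYZES - RXN-1", "//"),
             file.path(dir, "enzymes.dat"))
  writeLines(c("UNIQUE-ID - G-1", "COMMON-NAME - Fum1", "PRODUCT - ENZ-1",
               "//"), file.path(dir, "genes.dat"))
  writeLines(c("UNIQUE-ID - PWY-1", "COMMON-NAME - toy pathway",
               "COMPOUNDS - CPD-1", "COMPOUNDS - CPD-2",
               "REACTION-LIST - RXN-1", "//"), file.path(dir, "pathways.dat"))

  db <- read_metabolic_db(dir, dialect = "biocyc-subset")
  expect_identical(nrow(db$compounds), 2L)
  expect_true(db$reactions$reversible[1])
  expect_identical(db$compounds$xrefs[[1]], c(KEGG = "C00149"))
  expect_identical(nrow(validate_db(db)), 0L)
  r <- resolve_ids(db, "malic acid")
  expect_identical(r$matches$entity_id, "CPD-1")
  expect_identical(r$matches$match_kind, "synonym")
})

test_that("validate_db reports dangling references and tolerates isolation", {
  db <- make_toy_database()
  expect_identical(nrow(validate_db(db)), 0L)

  # inject a reaction referencing an absent compound
  bad <- db
  bad$reactions$substrate_ids[[1]] <- c(bad$reactions$substrate_ids[[1]], "X")
  bad <- do.call(metabolic_db, bad[c("compounds", "reactions", "enzymes",
                                     "genes", "pathways")])
  rep <- validate_db(bad)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$entity_kind, "reaction")
  expect_identical(rep$field, "substrate_ids")
  expect_identical(rep$missing_id, "X")

  # the isolated gene (bmm) generates no violation
  expect_false("FBgn0000011" %in% validate_db(db)$entity)
})

test_that("index consistency: compound index mirrors reaction membership", {
  db <- make_toy_database()
  for (i in seq_len(nrow(db$reactions))) {
    rid <- db$reactions$id[i]
    for (c in c(db$reactions$substrate_ids[[i]], db$reactions$product_ids[[i]]))
      expect_true(rid %in% db$indices$compound_to_reactions[[c]],
                  label = paste(c, "->", rid))
  }
})

test_that("resolve_ids matches in priority order and reports the rest", {
  db <- make_toy_database()
  r <- resolve_ids(db, c("malate", "", "C00149", "CG1673", "no-such-thing"))
  m <- r$matches
  expect_identical(m$entity_id[m$query == "malate"], "C-MAL")
  expect_identical(m$match_kind[m$query == "malate"], "name")
  expect_identical(m$entity_id[m$query == "C00149"], "C-MAL")
  expect_identical(m$match_kind[m$query == "C00149"], "xref")
  expect_identical(m$entity_kind[m$query == "CG1673"], "gene")
  expect_setequal(r$unmatched, c("", "no-such-thing"))

  # exact id outranks name: query by id returns kind "id"
  r2 <- resolve_ids(db, "C-MAL")
  expect_identical(r2$matches$match_kind, "id")

  # deterministic and idempotent
  expect_identical(resolve_ids(db, c("malate", "C00149")),
                   resolve_ids(db, c("malate", "C00149")))
})

test_that("ambiguous matches are reported, never silently chosen", {
  db <- mini_db()
  db$compounds$synonyms <- list("shared", "shared", character(0))
  db <- do.call(metabolic_db, db[c("compounds", "reactions", "enzymes",
                                   "genes", "pathways")])
  r <- resolve_ids(db, "shared")
  expect_identical(nrow(r$matches), 0L)
  expect_identical(r$ambiguous$candidates, "A;B")
})
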