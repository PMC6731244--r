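# ---- internal helpers ------------------------------------------------------

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

join_pipe <- function(x) paste(x, collapse = "|")

parse_xrefs <- function(x) {
  toks <- split_pipe(x)
  if (length(toks) == 0) return(stats::setNames(character(0), character(0)))
  pos <- regexpr(":", toks, fixed = TRUE)
  if (any(pos < 0)) stop("malformed xref cell (expected 'namespace:value'): ", x)
  stats::setNames(substring(toks, pos + 1L), substring(toks, 1L, pos - 1L))
}

format_xrefs <- function(xr) {
  if (length(xr) == 0) return("")
  join_pipe(paste0(names(xr), ":", unname(xr)))
}

#' Construct a metabolic database object
#'
#' Assembles the five entity tables (compounds, reactions, enzymes, genes,
#' pathways) into a validated, cross-indexed database: the substrate every
#' network graph in this package is derived from.
#'
#' Multi-valued fields (substrates, synonyms, ...) are list-columns of
#' character vectors. Construction builds the reverse indices
#' (compound to reactions, enzyme to reactions, gene to enzymes) and checks
#' structural invariants: unique non-empty ids, non-empty compound names,
#' reactions with at least one participant, and no compound appearing on both
#' sides of one reaction (such reactions would create self-loops that the
#' compound-network edge semantics cannot represent, so they are rejected).
#' Referential integrity across tables is *not* enforced here; see
#' [validate_db()], which reports dangling references as data.
#'
#' @param compounds data.frame with columns `id`, `name`, `class_label`
#'   (character) and list-columns `synonyms`, `xrefs` (named character).
#' @param reactions data.frame with `id`, `reversible` (logical) and
#'   list-columns `substrate_ids`, `product_ids`, `enzyme_ids`, `pathway_ids`.
#' @param enzymes data.frame with `id`, `name` and list-columns `gene_ids`,
#'   `reaction_ids`.
#' @param genes data.frame with `id`, `symbol` and list-column `enzyme_ids`.
#' @param pathways data.frame with `id`, `name` and list-columns
#'   `compound_ids`, `reaction_ids`.
#' @param provenance free-text description of where the data came from.
#' @return An object of class `metabolic_db`.
#' @seealso [read_metabolic_db()], [validate_db()], [resolve_ids()]
#' @export
metabolic_db <- function(compounds, reactions, enzymes, genes, pathways,
                         provenance = "in-memory") {
  compounds <- as.data.frame(compounds)
  reactions <- as.data.frame(reactions)
  enzymes   <- as.data.frame(enzymes)
  genes     <- as.data.frame(genes)
  pathways  <- as.data.frame(pathways)

  chk_ids <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    if (anyNA(df$id) || any(!nzchar(df$id)))
      stop(what, ": empty or missing id")
    if (anyDuplicated(df$id))
      stop(what, ": duplicated id(s): ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  chk_ids(compounds, "compounds"); chk_ids(reactions, "reactions")
  chk_ids(enzymes, "enzymes"); chk_ids(genes, "genes")
  chk_ids(pathways, "pathways")

  if (nrow(compounds) > 0 && any(!nzchar(compounds$name)))
    stop("compounds: empty name")

  if (nrow(reactions) > 0) {
    for (i in seq_len(nrow(reactions))) {
      s <- reactions$substrate_ids[[i]]; p <- reactions$product_ids[[i]]
      if (length(s) + length(p) == 0)
        stop("reaction ", reactions$id[i], ": no substrates or products")
      both <- intersect(s, p)
      if (length(both) > 0)
        stop("reaction ", reactions$id[i],
             ": compound(s) on both sides: ", paste(both, collapse = ", "))
    }
  }

  db <- structure(
    list(compounds = compounds, reactions = reactions, enzymes = enzymes,
         genes = genes, pathways = pathways, provenance = provenance),
    class = "metabolic_db")
  db$indices <- build_indices(db)
  db
}

build_indices <- function(db) {
  cmp2rxn <- list(); enz2rxn <- list(); gene2enz <- list()
  rx <- db$reactions
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    for (c in unique(c(rx$substrate_ids[[i]], rx$product_ids[[i]])))
      cmp2rxn[[c]] <- c(cmp2rxn[[c]], rid)
    for (e in rx$enzyme_ids[[i]])
      enz2rxn[[e]] <- c(enz2rxn[[e]], rid)
  }
  ez <- db$enzymes
  for (i in seq_len(nrow(ez))) {
    eid <- ez$id[i]
    for (r in ez$reaction_ids[[i]])
      enz2rxn[[eid]] <- c(enz2rxn[[eid]], r)
  }
  gn <- db$genes
  for (i in seq_len(nrow(gn)))
    gene2enz[[gn$id[i]]] <- gn$enzyme_ids[[i]]
  # enzymes may also list their genes
  for (i in seq_len(nrow(ez)))
    for (g in ez$gene_ids[[i]])
      gene2enz[[g]] <- c(gene2enz[[g]], ez$id[i])
  list(compound_to_reactions = lapply(cmp2rxn, function(x) sort(unique(x))),
       enzyme_to_reactions   = lapply(enz2rxn, function(x) sort(unique(x))),
       gene_to_enzymes       = lapply(gene2enz, function(x) sort(unique(x))))
}

#' @export
print.metabolic_db <- function(x, ...) {
  cat("metabolic_db:", nrow(x$compounds), "compounds,",
      nrow(x$reactions), "reactions,", nrow(x$enzymes), "enzymes,",
      nrow(x$genes), "genes,", nrow(x$pathways), "pathways\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

# ---- flat-file reader / writer --------------------------------------------

db_table_files <- c(compounds = "compounds.tsv", reactions = "reactions.tsv",
                    enzymes = "enzymes.tsv", genes = "genes.tsv",
                    pathways = "pathways.tsv")

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    na.strings = NULL, check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Read a metabolic database from flat files
#'
#' Two dialects are supported. `native-tsv` is this package's own schema:
#' five UTF-8 TSV tables in one directory (`compounds.tsv`, `reactions.tsv`,
#' `enzymes.tsv`, `genes.tsv`, `pathways.tsv`) with a mandatory header row
#' and pipe-delimited list cells; xref cells are `namespace:value` pairs.
#' `biocyc-subset` accepts directories of BioCyc-style attribute-value `.dat`
#' files (`compounds.dat`, `reactions.dat`, `enzymes.dat`, `genes.dat`,
#' `pathways.dat`) and reads the subset of attributes the data model covers.
#'
#' @param path directory containing the tables.
#' @param dialect `"native-tsv"` (default) or `"biocyc-subset"`.
#' @return A `metabolic_db`.
#' @examples
#' dir <- tempfile(); write_metabolic_db(make_toy_database(), dir)
#' db <- read_metabolic_db(dir)
#' nrow(db$compounds)
#' @export
read_metabolic_db <- function(path, dialect = c("native-tsv", "biocyc-subset")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path)) stop("database directory not found: ", path)
  if (dialect == "biocyc-subset") return(read_biocyc_subset(path))

  tabs <- list()
  for (nm in names(db_table_files)) {
    f <- file.path(path, db_table_files[[nm]])
    if (!file.exists(f))
      stop("missing database table '", db_table_files[[nm]], "' in ", path)
    tabs[[nm]] <- read_tsv_strict(f)
  }

  need <- function(df, cols, table) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stop(table, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  need(tabs$compounds, c("id", "name", "synonyms", "xrefs", "class_label"),
       "compounds.tsv")
  need(tabs$reactions, c("id", "substrates", "products", "reversible",
                         "enzymes", "pathways"), "reactions.tsv")
  need(tabs$enzymes, c("id", "name", "genes", "reactions"), "enzymes.tsv")
  need(tabs$genes, c("id", "symbol", "enzymes"), "genes.tsv")
  need(tabs$pathways, c("id", "name", "compounds", "reactions"),
       "pathways.tsv")

  lcol <- function(x) lapply(x, split_pipe)
  compounds <- data.frame(id = tabs$compounds$id, name = tabs$compounds$name,
                          class_label = tabs$compounds$class_label,
                          stringsAsFactors = FALSE)
  compounds$synonyms <- lcol(tabs$compounds$synonyms)
  compounds$xrefs <- lapply(tabs$compounds$xrefs, parse_xrefs)

  rev_flag <- tabs$reactions$reversible
  bad <- !(rev_flag %in% c("true", "false", "TRUE", "FALSE", "0", "1"))
  if (any(bad))
    stop("reactions.tsv row ", which(bad)[1] + 1L,
         ": reversible must be true/false, got '", rev_flag[bad][1], "'")
  reactions <- data.frame(id = tabs$reactions$id,
                          reversible = rev_flag %in% c("true", "TRUE", "1"),
                          stringsAsFactors = FALSE)
  reactions$substrate_ids <- lcol(tabs$reactions$substrates)
  reactions$product_ids <- lcol(tabs$reactions$products)
  reactions$enzyme_ids <- lcol(tabs$reactions$enzymes)
  reactions$pathway_ids <- lcol(tabs$reactions$pathways)

  enzymes <- data.frame(id = tabs$enzymes$id, name = tabs$enzymes$name,
                        stringsAsFactors = FALSE)
  enzymes$gene_ids <- lcol(tabs$enzymes$genes)
  enzymes$reaction_ids <- lcol(tabs$enzymes$reactions)

  genes <- data.frame(id = tabs$genes$id, symbol = tabs$genes$symbol,
                      stringsAsFactors = FALSE)
  genes$enzyme_ids <- lcol(tabs$genes$enzymes)

  pathways <- data.frame(id = tabs$pathways$id, name = tabs$pathways$name,
                         stringsAsFactors = FALSE)
  pathways$compound_ids <- lcol(tabs$pathways$compounds)
  pathways$reaction_ids <- lcol(tabs$pathways$reactions)

  metabolic_db(compounds, reactions, enzymes, genes, pathways,
               provenance = paste0("native-tsv:", normalizePath(path)))
}

#' Write a metabolic database as native TSV tables
#'
#' Inverse of [read_metabolic_db()] for the `native-tsv` dialect; the
#' round-trip is bit-exact (entity-by-entity equality after re-load). Rows
#' are written in the database's current order.
#'
#' @param db a `metabolic_db`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_metabolic_db <- function(db, path) {
  stopifnot(inherits(db, "metabolic_db"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  jp <- function(col) vapply(col, join_pipe, character(1))
  wr <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(data.frame(id = db$compounds$id, name = db$compounds$name,
                synonyms = jp(db$compounds$synonyms),
                xrefs = vapply(db$compounds$xrefs, format_xrefs, character(1)),
                class_label = db$compounds$class_label), "compounds.tsv")
  wr(data.frame(id = db$reactions$id,
                substrates = jp(db$reactions$substrate_ids),
                products = jp(db$reactions$product_ids),
                reversible = ifelse(db$reactions$reversible, "true", "false"),
                enzymes = jp(db$reactions$enzyme_ids),
                pathways = jp(db$reactions$pathway_ids)), "reactions.tsv")
  wr(data.frame(id = db$enzymes$id, name = db$enzymes$name,
                genes = jp(db$enzymes$gene_ids),
                reactions = jp(db$enzymes$reaction_ids)), "enzymes.tsv")
  wr(data.frame(id = db$genes$id, symbol = db$genes$symbol,
                enzymes = jp(db$genes$enzyme_ids)), "genes.tsv")
  wr(data.frame(id = db$pathways$id, name = db$pathways$name,
                compounds = jp(db$pathways$compound_ids),
                reactions = jp(db$pathways$reaction_ids)), "pathways.tsv")
  invisible(path)
}

# BioCyc-style attribute-value records: "KEY - VALUE" lines, records
# separated by "//". Only the attributes mapped below are read.
read_biocyc_dat <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  recs <- list(); cur <- list()
  for (ln in lines) {
    if (identical(trimws(ln), "//")) {
      if (length(cur) > 0) recs[[length(recs) + 1L]] <- cur
      cur <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Z0-9-]+) - (.*)$", ln))[[1]]
    if (length(m) == 3)
      cur[[m[2]]] <- c(cur[[m[2]]], m[3])
  }
  if (length(cur) > 0) recs[[length(recs) + 1L]] <- cur
  recs
}

bc_field <- function(rec, key, default = "") {
  v <- rec[[key]]
  if (is.null(v)) default else v[1]
}

read_biocyc_subset <- function(path) {
  f <- function(nm) file.path(path, paste0(nm, ".dat"))
  for (nm in c("compounds", "reactions", "enzymes", "genes", "pathways"))
    if (!file.exists(f(nm)))
      stop("missing database table '", nm, ".dat' in ", path)

  crec <- read_biocyc_dat(f("compounds"))
  compounds <- data.frame(
    id = vapply(crec, bc_field, character(1), "UNIQUE-ID"),
    name = vapply(crec, function(r)
      bc_field(r, "COMMON-NAME", bc_field(r, "UNIQUE-ID")), character(1)),
    class_label = vapply(crec, bc_field, character(1), "TYPES"),
    stringsAsFactors = FALSE)
  compounds$synonyms <- lapply(crec, function(r)
    as.character(r[["SYNONYMS"]] %||% character(0)))
  compounds$xrefs <- lapply(crec, function(r) {
    links <- r[["DBLINKS"]] %||% character(0)
    out <- character(0)
    for (l in links) {
      m <- regmatches(l, regexec("^\\(([^ ]+) \"([^\"]*)\"", l))[[1]]
      if (length(m) == 3) out[m[2]] <- m[3]
    }
    out
  })

  rrec <- read_biocyc_dat(f("reactions"))
  reactions <- data.frame(
    id = vapply(rrec, bc_field, character(1), "UNIQUE-ID"),
    reversible = vapply(rrec, function(r)
      identical(bc_field(r, "REACTION-DIRECTION"), "REVERSIBLE"), logical(1)),
    stringsAsFactors = FALSE)
  reactions$substrate_ids <- lapply(rrec, function(r)
    as.character(r[["LEFT"]] %||% character(0)))
  reactions$product_ids <- lapply(rrec, function(r)
    as.character(r[["RIGHT"]] %||% character(0)))
  reactions$enzyme_ids <- lapply(rrec, function(r)
    as.character(r[["ENZYMATIC-REACTION"]] %||% character(0)))
  reactions$pathway_ids <- lapply(rrec, function(r)
    as.character(r[["IN-PATHWAY"]] %||% character(0)))

  erec <- read_biocyc_dat(f("enzymes"))
  enzymes <- data.frame(
    id = vapply(erec, bc_field, character(1), "UNIQUE-ID"),
    name = vapply(erec, function(r)
      bc_field(r, "COMMON-NAME", bc_field(r, "UNIQUE-ID")), character(1)),
    stringsAsFactors = FALSE)
  enzymes$gene_ids <- lapply(erec, function(r)
    as.character(r[["GENE"]] %||% character(0)))
  enzymes$reaction_ids <- lapply(erec, function(r)
    as.character(r[["CATALYZES"]] %||% character(0)))

  grec <- read_biocyc_dat(f("genes"))
  genes <- data.frame(
    id = vapply(grec, bc_field, character(1), "UNIQUE-ID"),
    symbol = vapply(grec, function(r)
      bc_field(r, "COMMON-NAME", bc_field(r, "UNIQUE-ID")), character(1)),
    stringsAsFactors = FALSE)
  genes$enzyme_ids <- lapply(grec, function(r)
    as.character(r[["PRODUCT"]] %||% character(0)))

  prec <- read_biocyc_dat(f("pathways"))
  pathways <- data.frame(
    id = vapply(prec, bc_field, character(1), "UNIQUE-ID"),
    name = vapply(prec, function(r)
      bc_field(r, "COMMON-NAME", bc_field(r, "UNIQUE-ID")), character(1)),
    stringsAsFactors = FALSE)
  pathways$compound_ids <- lapply(prec, function(r)
    as.character(r[["COMPOUNDS"]] %||% character(0)))
  pathways$reaction_ids <- lapply(prec, function(r)
    as.character(r[["REACTION-LIST"]] %||% character(0)))

  metabolic_db(compounds, reactions, enzymes, genes, pathways,
               provenance = paste0("biocyc-subset:", normalizePath(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- validation ------------------------------------------------------------

#' Check referential integrity of a metabolic database
#'
#' Scans every cross-reference (reaction substrates/products/enzymes/pathways,
#' enzyme genes/reactions, gene enzymes, pathway members) and reports each id
#' that does not resolve to an entity. Violations are data, not errors: the
#' report is empty if and only if every referenced id resolves. Entities with
#' empty reference lists (e.g. an isolated gene) are not violations.
#'
#' @param db a `metabolic_db`.
#' @return data.frame with columns `entity` (referencing entity id),
#'   `entity_kind`, `field`, `missing_id`; zero rows when the database is
#'   consistent.
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "metabolic_db"))
  cids <- db$compounds$id; rids <- db$reactions$id
  eids <- db$enzymes$id; gids <- db$genes$id

  out <- list()
  add <- function(entity, kind, field, missing) {
    for (m in missing)
      out[[length(out) + 1L]] <<- data.frame(
        entity = entity, entity_kind = kind, field = field, missing_id = m,
        stringsAsFactors = FALSE)
  }
  rx <- db$reactions
  for (i in seq_len(nrow(rx))) {
    add(rx$id[i], "reaction", "substrate_ids",
        setdiff(rx$substrate_ids[[i]], cids))
    add(rx$id[i], "reaction", "product_ids",
        setdiff(rx$product_ids[[i]], cids))
    add(rx$id[i], "reaction", "enzyme_ids", setdiff(rx$enzyme_ids[[i]], eids))
    add(rx$id[i], "reaction", "pathway_ids",
        setdiff(rx$pathway_ids[[i]], db$pathways$id))
  }
  ez <- db$enzymes
  for (i in seq_len(nrow(ez))) {
    add(ez$id[i], "enzyme", "gene_ids", setdiff(ez$gene_ids[[i]], gids))
    add(ez$id[i], "enzyme", "reaction_ids",
        setdiff(ez$reaction_ids[[i]], rids))
  }
  gn <- db$genes
  for (i in seq_len(nrow(gn)))
    add(gn$id[i], "gene", "enzyme_ids", setdiff(gn$enzyme_ids[[i]], eids))
  pw <- db$pathways
  for (i in seq_len(nrow(pw))) {
    add(pw$id[i], "pathway", "compound_ids",
        setdiff(pw$compound_ids[[i]], cids))
    add(pw$id[i], "pathway", "reaction_ids",
        setdiff(pw$reaction_ids[[i]], rids))
  }
  if (length(out) == 0)
    return(data.frame(entity = character(0), entity_kind = character(0),
                      field = character(0), missing_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- identifier resolution -------------------------------------------------

#' Resolve free-text queries against a metabolic database
#'
#' Maps each query string to at most one entity per entity class, in fixed
#' priority order: exact id, then exact name/symbol (case-insensitive), then
#' synonym (case-insensitive), then xref value. The first matching tier wins;
#' a tier that matches more than one entity of the same class makes the query
#' ambiguous for that class (reported, never silently chosen). Resolution is
#' deterministic and idempotent for a fixed database.
#'
#' @param db a `metabolic_db`.
#' @param queries non-empty character vector.
#' @return list with `matches` (data.frame: query, entity_id, entity_kind,
#'   match_kind), `unmatched` (character), `ambiguous` (data.frame: query,
#'   entity_kind, candidate ids collapsed with ";").
#' @export
resolve_ids <- function(db, queries) {
  stopifnot(inherits(db, "metabolic_db"))
  if (length(queries) == 0) stop("queries must be non-empty")
  queries <- as.character(queries)

  tiers <- list(
    compound = list(
      id = function(q) db$compounds$id[db$compounds$id == q],
      name = function(q)
        db$compounds$id[tolower(db$compounds$name) == tolower(q)],
      synonym = function(q) db$compounds$id[vapply(db$compounds$synonyms,
        function(s) tolower(q) %in% tolower(s), logical(1))],
      xref = function(q) db$compounds$id[vapply(db$compounds$xrefs,
        function(x) q %in% unname(x), logical(1))]),
    gene = list(
      id = function(q) db$genes$id[db$genes$id == q],
      name = function(q)
        db$genes$id[tolower(db$genes$symbol) == tolower(q)]),
    enzyme = list(
      id = function(q) db$enzymes$id[db$enzymes$id == q],
      name = function(q)
        db$enzymes$id[tolower(db$enzymes$name) == tolower(q)]),
    reaction = list(id = function(q) db$reactions$id[db$reactions$id == q]),
    pathway = list(
      id = function(q) db$pathways$id[db$pathways$id == q],
      name = function(q)
        db$pathways$id[tolower(db$pathways$name) == tolower(q)]))

  matches <- list(); ambiguous <- list(); unmatched <- character(0)
  for (q in queries) {
    found <- FALSE
    if (nzchar(q)) {
      # each entity class is resolved independently: a query may legitimately
      # name both a compound and a gene
      for (kind in names(tiers)) {
        for (tier in names(tiers[[kind]])) {
          hits <- unique(tiers[[kind]][[tier]](q))
          if (length(hits) == 1) {
            matches[[length(matches) + 1L]] <- data.frame(
              query = q, entity_id = hits, entity_kind = kind,
              match_kind = tier, stringsAsFactors = FALSE)
            found <- TRUE
            break
          } else if (length(hits) > 1) {
            ambiguous[[length(ambiguous) + 1L]] <- data.frame(
              query = q, entity_kind = kind,
              candidates = paste(sort(hits), collapse = ";"),
              stringsAsFactors = FALSE)
            found <- TRUE
            break
          }
        }
      }
    }
    if (!found) unmatched <- c(unmatched, q)
  }
  empty_m <- data.frame(query = character(0), entity_id = character(0),
                        entity_kind = character(0), match_kind = character(0),
                        stringsAsFactors = FALSE)
  empty_a <- data.frame(query = character(0), entity_kind = character(0),
                        candidates = character(0), stringsAsFactors = FALSE)
  list(matches = if (length(matches)) do.call(rbind, matches) else empty_m,
       unmatched = unmatched,
       ambiguous = if (length(ambiguous)) do.call(rbind, ambiguous)
                   else empty_a)
}
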