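# Property graph: Compound / Enzyme / Use nodes with four relationship
# types, export to GraphML and bulk-import CSV, and the query patterns used
# for hypothesis generation (significant neighbors, dual structure+toxicity
# neighbors, substrate-pool scans).

REL_TYPES <- c("SUBSTRUCTURE_SIMILARITY", "TOXICITY_SIMILARITY",
               "HAS_USE", "METABOLIZED_BY")

#' Read a drug-use label table
#'
#' Expects columns `compound_id`, `use`.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `compound_id`, `use`.
#' @export
read_uses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "use") %in% names(df)))
    ctg_error("use table needs compound_id and use columns", "ctg_format_error")
  unique(df[, c("compound_id", "use")])
}

#' Assemble the compound-enzyme-use property graph
#'
#' One Compound node per compound (category, superclass, community as
#' properties), one Enzyme node per EC number (ECs_D attached when
#' available), one Use node per use label. Similarity edges are stored once
#' in canonical (min id, max id) orientation and queried as undirected;
#' `HAS_USE` and `METABOLIZED_BY` run Compound to target. Rows referencing
#' unknown compounds are logged and skipped; the number skipped is recorded
#' in `skipped`.
#'
#' @param net a `similarity_network` with communities and significance
#'   flags.
#' @param compounds a `compound_table` (node annotations).
#' @param tox_edges toxicity edge `data.frame` (`id1`, `id2`, `score`), or
#'   `NULL`.
#' @param enzyme_map `data.frame` (`ec_number`, `compound_id`), or `NULL`.
#' @param uses `data.frame` (`compound_id`, `use`), or `NULL`.
#' @param ecsd_scores result of [ecsd_table()], or `NULL`.
#' @return A `property_graph`: list with `nodes` (`node_id`, `label`,
#'   `name`, `category`, `superclass`, `community`, `ecsd`),
#'   `relationships` (`start`, `end`, `type`, `score`, `zscore`,
#'   `significant`), `skipped`.
#' @export
assemble_graph <- function(net, compounds, tox_edges = NULL, enzyme_map = NULL,
                           uses = NULL, ecsd_scores = NULL) {
  stopifnot(inherits(net, "similarity_network"), inherits(compounds, "compound_table"))
  known <- compounds$compound_id
  skipped <- 0L

  membership <- net$membership %||% stats::setNames(rep(NA_integer_, length(known)), known)
  cnodes <- data.frame(node_id = compounds$compound_id, label = "Compound",
                       name = compounds$name, category = compounds$category,
                       superclass = compounds$superclass,
                       community = unname(membership[compounds$compound_id]),
                       ecsd = NA_real_, stringsAsFactors = FALSE)

  enodes <- unodes <- cnodes[0, ]
  rels <- list()

  sim <- net$edges
  ok <- sim$id1 %in% known & sim$id2 %in% known
  skipped <- skipped + sum(!ok)
  sim <- sim[ok, , drop = FALSE]
  if (nrow(sim))
    rels$sim <- data.frame(start = sim$id1, end = sim$id2,
                           type = "SUBSTRUCTURE_SIMILARITY", score = sim$score,
                           zscore = sim$zscore, significant = sim$significant,
                           stringsAsFactors = FALSE)

  if (!is.null(tox_edges) && nrow(tox_edges)) {
    ok <- tox_edges$id1 %in% known & tox_edges$id2 %in% known
    skipped <- skipped + sum(!ok)
    te <- tox_edges[ok, , drop = FALSE]
    pair <- canonical_pair(te$id1, te$id2)
    rels$tox <- data.frame(start = pair[, "id1"], end = pair[, "id2"],
                           type = "TOXICITY_SIMILARITY", score = te$score,
                           zscore = NA_real_, significant = NA,
                           stringsAsFactors = FALSE)
  }

  if (!is.null(enzyme_map) && nrow(enzyme_map)) {
    ok <- enzyme_map$compound_id %in% known
    if (any(!ok)) message(sprintf("skipping %d enzyme-map row(s) with unknown compounds",
                                  sum(!ok)))
    skipped <- skipped + sum(!ok)
    em <- unique(enzyme_map[ok, c("ec_number", "compound_id")])
    ecs <- sort(unique(em$ec_number))
    esc <- rep(NA_real_, length(ecs))
    if (!is.null(ecsd_scores))
      esc <- ecsd_scores$scores$ecsd[match(ecs, ecsd_scores$scores$ec_number)]
    enodes <- data.frame(node_id = ecs, label = "Enzyme", name = ecs,
                         category = NA_character_, superclass = NA_character_,
                         community = NA_integer_, ecsd = esc, stringsAsFactors = FALSE)
    rels$met <- data.frame(start = em$compound_id, end = em$ec_number,
                           type = "METABOLIZED_BY", score = NA_real_,
                           zscore = NA_real_, significant = NA,
                           stringsAsFactors = FALSE)
  }

  if (!is.null(uses) && nrow(uses)) {
    ok <- uses$compound_id %in% known
    if (any(!ok)) message(sprintf("skipping %d use row(s) with unknown compounds",
                                  sum(!ok)))
    skipped <- skipped + sum(!ok)
    us <- unique(uses[ok, c("compound_id", "use")])
    labels <- sort(unique(us$use))
    unodes <- data.frame(node_id = labels, label = "Use", name = labels,
                         category = NA_character_, superclass = NA_character_,
                         community = NA_integer_, ecsd = NA_real_,
                         stringsAsFactors = FALSE)
    rels$use <- data.frame(start = us$compound_id, end = us$use,
                           type = "HAS_USE", score = NA_real_,
                           zscore = NA_real_, significant = NA,
                           stringsAsFactors = FALSE)
  }

  nodes <- rbind(cnodes, enodes, unodes)
  rownames(nodes) <- NULL
  relationships <- if (length(rels)) do.call(rbind, rels)
                   else data.frame(start = character(), end = character(),
                                   type = character(), score = numeric(),
                                   zscore = numeric(), significant = logical(),
                                   stringsAsFactors = FALSE)
  relationships <- relationships[!duplicated(relationships[, c("start", "end", "type")]),
                                 , drop = FALSE]
  relationships <- relationships[order(relationships$type, relationships$start,
                                       relationships$end), , drop = FALSE]
  rownames(relationships) <- NULL
  structure(list(nodes = nodes, relationships = relationships, skipped = skipped),
            class = "property_graph")
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph: %d nodes (%s), %d relationships>\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$label),
                            names(table(x$nodes$label))), collapse = ", "),
              nrow(x$relationships)))
  invisible(x)
}

check_compound <- function(graph, compound_id) {
  if (!compound_id %in% graph$nodes$node_id[graph$nodes$label == "Compound"])
    ctg_error(sprintf("unknown compound '%s'", compound_id), "ctg_input_error")
}

# undirected view of one relationship type around a node
incident_edges <- function(graph, compound_id, type) {
  r <- graph$relationships[graph$relationships$type == type, , drop = FALSE]
  sel <- r$start == compound_id | r$end == compound_id
  r <- r[sel, , drop = FALSE]
  r$other <- ifelse(r$start == compound_id, r$end, r$start)
  r
}

order_result <- function(df) {
  df <- df[order(-df$score, df$compound_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compounds linked by significant substructure similarity
#'
#' @param graph a `property_graph`.
#' @param compound_id query compound.
#' @return `data.frame` (`compound_id`, `score`, `zscore`) ordered by score
#'   descending then id ascending.
#' @export
significant_neighbors <- function(graph, compound_id) {
  check_compound(graph, compound_id)
  r <- incident_edges(graph, compound_id, "SUBSTRUCTURE_SIMILARITY")
  r <- r[!is.na(r$significant) & r$significant, , drop = FALSE]
  order_result(data.frame(compound_id = r$other, score = r$score,
                          zscore = r$zscore, stringsAsFactors = FALSE))
}

#' Compounds with both high structure and toxicity overlap
#'
#' Returns compounds linked to the query by a significant substructure
#' edge with score at least `min_struct` AND a toxicity edge with
#' normalised score at least `min_tox`.
#'
#' @param graph a `property_graph`.
#' @param compound_id query compound.
#' @param min_struct minimum substructure similarity (default 0).
#' @param min_tox minimum toxicity similarity (default 0).
#' @return `data.frame` (`compound_id`, `score` = structure score,
#'   `tox_score`), ordered by structure score descending then id.
#' @export
dual_neighbors <- function(graph, compound_id, min_struct = 0, min_tox = 0) {
  check_compound(graph, compound_id)
  s <- incident_edges(graph, compound_id, "SUBSTRUCTURE_SIMILARITY")
  s <- s[!is.na(s$significant) & s$significant & s$score >= min_struct, , drop = FALSE]
  t <- incident_edges(graph, compound_id, "TOXICITY_SIMILARITY")
  t <- t[t$score >= min_tox, , drop = FALSE]
  both <- intersect(s$other, t$other)
  out <- data.frame(compound_id = both,
                    score = s$score[match(both, s$other)],
                    tox_score = t$score[match(both, t$other)],
                    stringsAsFactors = FALSE)
  order_result(out)
}

#' Scan a seed compound's community for alternative enzyme substrates
#'
#' Returns the compounds in the seed's similarity community that are linked
#' to the seed by a significant substructure edge, annotated with their
#' category and whether each is already a known substrate of the given EC
#' number.
#'
#' @param graph a `property_graph`.
#' @param ec_number EC number of the enzyme of interest.
#' @param seed_compound community seed compound.
#' @return `data.frame` (`compound_id`, `score`, `category`,
#'   `known_substrate`), ordered by score descending then id.
#' @export
substrate_pool_scan <- function(graph, ec_number, seed_compound) {
  check_compound(graph, seed_compound)
  if (!ec_number %in% graph$nodes$node_id[graph$nodes$label == "Enzyme"])
    ctg_error(sprintf("unknown enzyme '%s'", ec_number), "ctg_input_error")
  nodes <- graph$nodes
  seed_comm <- nodes$community[nodes$node_id == seed_compound]
  r <- incident_edges(graph, seed_compound, "SUBSTRUCTURE_SIMILARITY")
  r <- r[!is.na(r$significant) & r$significant, , drop = FALSE]
  comm <- nodes$community[match(r$other, nodes$node_id)]
  r <- r[!is.na(comm) & !is.na(seed_comm) & comm == seed_comm, , drop = FALSE]
  met <- graph$relationships[graph$relationships$type == "METABOLIZED_BY" &
                               graph$relationships$end == ec_number, , drop = FALSE]
  out <- data.frame(compound_id = r$other, score = r$score,
                    category = nodes$category[match(r$other, nodes$node_id)],
                    known_substrate = r$other %in% met$start,
                    stringsAsFactors = FALSE)
  order_result(out)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a property graph
#'
#' `format = "graphml"` writes a single GraphML file with typed node and
#' edge attribute keys. `format = "csv"` writes a bulk-import CSV pair
#' following graph-database importer conventions: `nodes.csv` with
#' `node_id:ID`, `:LABEL` and property columns, and `relationships.csv`
#' with `:START_ID`, `:END_ID`, `:TYPE` and property columns. Both formats
#' round trip through [import_graph()] with identical node and relationship
#' sets.
#'
#' @param graph a `property_graph`.
#' @param path output file (graphml) or directory (csv).
#' @param format `"graphml"` or `"csv"`.
#' @return The path(s) written, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    nodes <- graph$nodes
    names(nodes) <- c("node_id:ID", ":LABEL", "name", "category", "superclass",
                      "community:int", "ecsd:double")
    utils::write.csv(nodes, file.path(path, "nodes.csv"), row.names = FALSE, na = "")
    rel <- graph$relationships
    names(rel) <- c(":START_ID", ":END_ID", ":TYPE", "score:double",
                    "zscore:double", "significant:boolean")
    utils::write.csv(rel, file.path(path, "relationships.csv"), row.names = FALSE, na = "")
    return(invisible(file.path(path, c("nodes.csv", "relationships.csv"))))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">')
  keydefs <- rbind(
    data.frame(id = c("label", "name", "category", "superclass"),
               f = "node", type = "string"),
    data.frame(id = "community", f = "node", type = "int"),
    data.frame(id = "ecsd", f = "node", type = "double"),
    data.frame(id = "type", f = "edge", type = "string"),
    data.frame(id = c("score", "zscore"), f = "edge", type = "double"),
    data.frame(id = "significant", f = "edge", type = "boolean"))
  for (i in seq_len(nrow(keydefs)))
    w('  <key id="%s" for="%s" attr.name="%s" attr.type="%s"/>',
      keydefs$id[i], keydefs$f[i], keydefs$id[i], keydefs$type[i])
  w('  <graph id="G" edgedefault="directed">')
  dat <- function(key, val) {
    val <- as.character(val)
    ifelse(is.na(val), "",
           sprintf('<data key="%s">%s</data>', key, xml_escape(val)))
  }
  nd <- graph$nodes
  writeLines(paste0('    <node id="', xml_escape(nd$node_id), '">',
                    dat("label", nd$label), dat("name", nd$name),
                    dat("category", nd$category), dat("superclass", nd$superclass),
                    dat("community", nd$community), dat("ecsd", nd$ecsd),
                    '</node>'), con)
  r <- graph$relationships
  if (nrow(r))
    writeLines(paste0('    <edge source="', xml_escape(r$start), '" target="',
                      xml_escape(r$end), '">',
                      dat("type", r$type), dat("score", r$score),
                      dat("zscore", r$zscore),
                      dat("significant", tolower(as.character(r$significant))),
                      '</edge>'), con)
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Import a property graph written by [export_graph()]
#'
#' @param path GraphML file or CSV directory.
#' @param format `"graphml"` or `"csv"`.
#' @return A `property_graph`.
#' @export
import_graph <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    nodes <- utils::read.csv(file.path(path, "nodes.csv"), stringsAsFactors = FALSE,
                             na.strings = "",
                             colClasses = c("character", "character", "character",
                                            "character", "character", "integer",
                                            "numeric"))
    names(nodes) <- c("node_id", "label", "name", "category", "superclass",
                      "community", "ecsd")
    rel <- utils::read.csv(file.path(path, "relationships.csv"),
                           stringsAsFactors = FALSE, na.strings = "",
                           colClasses = c("character", "character", "character",
                                          "numeric", "numeric", "logical"))
    names(rel) <- c("start", "end", "type", "score", "zscore", "significant")
    return(structure(list(nodes = nodes, relationships = rel, skipped = 0L),
                     class = "property_graph"))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_data <- function(nodeset, key) {
    v <- xml2::xml_text(xml2::xml_find_first(nodeset, sprintf("./data[@key='%s']", key)))
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  }
  nnodes <- xml2::xml_find_all(doc, ".//node")
  nodes <- data.frame(
    node_id = xml2::xml_attr(nnodes, "id"), label = get_data(nnodes, "label"),
    name = get_data(nnodes, "name"), category = get_data(nnodes, "category"),
    superclass = get_data(nnodes, "superclass"),
    community = as.integer(get_data(nnodes, "community")),
    ecsd = as.numeric(get_data(nnodes, "ecsd")), stringsAsFactors = FALSE)
  nedges <- xml2::xml_find_all(doc, ".//edge")
  rel <- data.frame(
    start = xml2::xml_attr(nedges, "source"), end = xml2::xml_attr(nedges, "target"),
    type = get_data(nedges, "type"), score = as.numeric(get_data(nedges, "score")),
    zscore = as.numeric(get_data(nedges, "zscore")),
    significant = as.logical(get_data(nedges, "significant")),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, relationships = rel, skipped = 0L),
            class = "property_graph")
}
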