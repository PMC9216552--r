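# Canonical logic-table dialect: UTF-8, tab-separated, '#' comment lines,
# header source_id/target_id/polarity/logic. The permissive reader also
# accepts common header variants so tables exported by other tooling load
# without editing.
.edge_header_aliases <- list(
  source = c("source_id", "source", "from", "input", "parent"),
  target = c("target_id", "target", "to", "output", "child"),
  polarity = c("polarity", "sign", "effect", "regulation"),
  logic = c("logic", "gate", "combination"))

.node_header_aliases <- list(
  id = c("id", "node_id", "node"),
  name = c("name", "label", "display_name"),
  entity_class = c("entity_class", "class", "type", "entity_type"))

.resolve_header <- function(found, aliases, what) {
  lowered <- tolower(found)
  out <- vapply(names(aliases), function(canon) {
    hit <- which(lowered %in% aliases[[canon]])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  required <- if (what == "edge") c("source", "target", "polarity", "logic")
              else "id"
  missing_cols <- names(out)[names(out) %in% required & is.na(out)]
  if (length(missing_cols) > 0) {
    stop(what, " table lacks required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (found: ", paste(found, collapse = ", "), ")", call. = FALSE)
  }
  out
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", fileEncoding = "UTF-8")
}

#' Read a Logical Network from a logic-table TSV
#'
#' The canonical dialect is a tab-separated edge table with a header line
#' `source_id  target_id  polarity  logic`, `'#'` comment lines, polarity
#' `+`/`-` and logic `AND`/`OR`. Common header and value variants
#' (`from`/`to`, `positive`/`negative`, lower-case logic) are accepted.
#' An optional node table (`id`, `name`, `entity_class`) supplies display
#' names and entity classes; unknown classes are mapped to `"auxiliary"`
#' with a warning, and nodes appearing only in the edge table are added as
#' auxiliary.
#'
#' @param path path to the edge table.
#' @param nodes_path optional path to the node table.
#' @param normalize passed to [logic_network()].
#' @return a validated [logic_network()].
#' @seealso [write_logic_table()]
#' @export
read_logic_table <- function(path, nodes_path = NULL, normalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- .read_tsv(path)
  if (nrow(raw) == 0) {
    stop("edge table is empty (no edges): ", path, call. = FALSE)
  }
  idx <- .resolve_header(names(raw), .edge_header_aliases, "edge")
  edges <- data.frame(source = raw[[idx[["source"]]]],
                      target = raw[[idx[["target"]]]],
                      polarity = raw[[idx[["polarity"]]]],
                      logic = raw[[idx[["logic"]]]],
                      stringsAsFactors = FALSE)
  nodes <- NULL
  if (!is.null(nodes_path)) {
    if (!file.exists(nodes_path)) {
      stop("no such file: ", nodes_path, call. = FALSE)
    }
    nraw <- .read_tsv(nodes_path)
    nidx <- .resolve_header(names(nraw), .node_header_aliases, "node")
    nodes <- data.frame(id = nraw[[nidx[["id"]]]],
                        stringsAsFactors = FALSE)
    nodes$name <- if (!is.na(nidx[["name"]])) nraw[[nidx[["name"]]]] else nodes$id
    nodes$entity_class <- if (!is.na(nidx[["entity_class"]]))
      nraw[[nidx[["entity_class"]]]] else "auxiliary"
    extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(extra) > 0) {
      nodes <- rbind(nodes, data.frame(id = extra, name = extra,
                                       entity_class = "auxiliary",
                                       stringsAsFactors = FALSE))
    }
  }
  logic_network(edges, nodes = nodes, normalize = normalize)
}

#' Write a Logical Network to logic-table TSV files
#'
#' Writes the canonical 4-column edge table; with `nodes_path` also writes
#' the node table. `read_logic_table(write_logic_table(net))` reproduces an
#' isomorphic network (same node ids, same edge multiset).
#'
#' @param net a `logic_network`; refuses to serialize an empty network.
#' @param path output path for the edge table.
#' @param nodes_path optional output path for the node table.
#' @return `path`, invisibly.
#' @export
write_logic_table <- function(net, path, nodes_path = NULL) {
  stopifnot(inherits(net, "logic_network"))
  if (nrow(net$nodes) == 0 || nrow(net$edges) == 0) {
    stop("refusing to serialize an empty network", call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(c("# logicpath logic table",
               paste("#", nrow(net$nodes), "nodes,", nrow(net$edges), "edges")),
             con)
  out <- net$edges
  names(out) <- c("source_id", "target_id", "polarity", "logic")
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path)) {
    ncon <- file(nodes_path, open = "wt", encoding = "UTF-8")
    on.exit(close(ncon), add = TRUE)
    writeLines("# logicpath node table", ncon)
    write.table(net$nodes, ncon, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write test-case tables
#'
#' Test-case TSVs have columns `root`, `direction`, `key_output` and
#' optionally `predicted` and `observed` (three-class labels `up`, `down`,
#' `no_change`; empty cells read as `NA`).
#'
#' @param path file path.
#' @rdname test_case_io
#' @return `read_test_cases`: a data.frame of test cases.
#' @export
read_test_cases <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- .read_tsv(path)
  required <- c("root", "direction", "key_output")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("test-case table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("predicted", "observed")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA_character_
  }
  .validate_classes(raw$direction, c("up", "down"), "direction")
  .validate_classes(raw$predicted, .classes3, "predicted", allow_na = TRUE)
  .validate_classes(raw$observed, .classes3, "observed", allow_na = TRUE)
  raw[, c("root", "direction", "key_output", "predicted", "observed",
          setdiff(names(raw), c("root", "direction", "key_output",
                                "predicted", "observed")))]
}

#' @param cases a test-case data.frame.
#' @rdname test_case_io
#' @export
write_test_cases <- function(cases, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  write.table(cases, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

.classes3 <- c("up", "down", "no_change")

.validate_classes <- function(x, allowed, what, allow_na = FALSE) {
  bad <- !(x %in% allowed)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop("invalid ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
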