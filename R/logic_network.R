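# Entity classes recognised in node tables. Anything else is coerced to
# "auxiliary" with a warning; auxiliary nodes are also what normalization
# inserts to split mixed AND/OR fan-in.
.entity_classes <- c("protein", "gene", "rna", "complex", "set",
                     "small_molecule", "polymer", "reaction", "auxiliary")

#' Construct a Logical Network
#'
#' A Logical Network is a signed directed graph derived from a curated
#' pathway: nodes are molecular entities (proteins, complexes, sets, ...)
#' and reactions, edges carry a polarity (activating `"+"` or inhibiting
#' `"-"`) and a logic class (`"AND"` or `"OR"`) describing how a node
#' combines its inputs. Cycles (feedback loops) are permitted.
#'
#' On construction the network is validated and normalized:
#' * exact duplicate edges (same source, target and polarity) are collapsed
#'   to a single edge (a message reports how many were dropped); edges that
#'   differ only in polarity are kept, they encode dual regulation;
#' * if a node's incoming edges mix AND and OR logic, the OR group is
#'   re-routed through an inserted auxiliary node (id `<id>..or`) joined to
#'   the node by a positive AND edge, so that after normalization every
#'   fan-in carries a single logic class.
#'
#' @param edges data.frame with columns `source`, `target`, `polarity`
#'   (`"+"`/`"-"`) and `logic` (`"AND"`/`"OR"`).
#' @param nodes optional data.frame with columns `id`, `name`,
#'   `entity_class`. Nodes appearing only in `edges` are added with
#'   `entity_class = "auxiliary"`.
#' @param normalize collapse duplicates and split mixed fan-in logic
#'   (default `TRUE`). Disable only to inspect a raw table.
#' @return An object of class `logic_network`: a list with data.frame
#'   elements `nodes` (`id`, `name`, `entity_class`) and `edges`
#'   (`source`, `target`, `polarity`, `logic`).
#' @examples
#' net <- logic_network(data.frame(
#'   source = c("A", "B"), target = c("B", "C"),
#'   polarity = c("+", "-"), logic = "AND"))
#' net
#' @export
logic_network <- function(edges, nodes = NULL, normalize = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("source", "target", "polarity", "logic")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("edge table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(edges) == 0) {
    stop("a logic network must contain at least one edge", call. = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$polarity <- .canon_polarity(edges$polarity)
  edges$logic <- .canon_logic(edges$logic)

  edge_ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- data.frame(id = edge_ids, name = edge_ids,
                        entity_class = "auxiliary",
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!"id" %in% names(nodes)) {
      stop("node table lacks required column: id", call. = FALSE)
    }
    nodes$id <- as.character(nodes$id)
    if (anyDuplicated(nodes$id)) {
      stop("duplicate node id(s): ",
           paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
           call. = FALSE)
    }
    if (!"name" %in% names(nodes)) nodes$name <- nodes$id
    nodes$name <- ifelse(is.na(nodes$name), nodes$id, as.character(nodes$name))
    if (!"entity_class" %in% names(nodes)) nodes$entity_class <- "auxiliary"
    nodes$entity_class <- .canon_entity_class(nodes$entity_class)
    undeclared <- setdiff(edge_ids, nodes$id)
    orphan_edges <- edges$source %in% undeclared | edges$target %in% undeclared
    if (any(orphan_edges)) {
      stop("edge(s) reference undeclared node(s): ",
           paste(utils::head(undeclared, 10), collapse = ", "),
           if (length(undeclared) > 10) ", ...", call. = FALSE)
    }
    nodes <- nodes[, c("id", "name", "entity_class")]
  }

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "logic_network")
  if (normalize) net <- .normalize_network(net)
  rownames(net$nodes) <- NULL
  rownames(net$edges) <- NULL
  net
}

.canon_polarity <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "positive", "pos", "activation", "activate", "1")] <- "+"
  out[x %in% c("-", "negative", "neg", "inhibition", "inhibit", "-1")] <- "-"
  if (anyNA(out)) {
    stop("unrecognised edge polarity value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

.canon_logic <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (!all(x %in% c("AND", "OR"))) {
    stop("unrecognised edge logic value(s): ",
         paste(unique(x[!x %in% c("AND", "OR")]), collapse = ", "),
         call. = FALSE)
  }
  x
}

.canon_entity_class <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "auxiliary"
  unknown <- setdiff(unique(x), .entity_classes)
  if (length(unknown) > 0) {
    warning("unknown entity class(es) mapped to 'auxiliary': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    x[x %in% unknown] <- "auxiliary"
  }
  x
}

# Collapse exact duplicate edges, then split mixed AND/OR fan-in by routing
# each OR group through an inserted auxiliary node.
.normalize_network <- function(net) {
  edges <- net$edges
  key <- paste(edges$source, edges$target, edges$polarity, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    message("collapsed ", n_dup, " duplicate edge(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }

  n_logic <- tapply(edges$logic, edges$target,
                    function(l) length(unique(l)))
  mixed <- names(n_logic)[n_logic > 1]
  for (v in mixed) {
    aux_id <- paste0(v, "..or")
    while (aux_id %in% net$nodes$id) aux_id <- paste0(aux_id, ".")
    sel <- edges$target == v & edges$logic == "OR"
    edges$target[sel] <- aux_id
    edges <- rbind(edges, data.frame(source = aux_id, target = v,
                                     polarity = "+", logic = "AND",
                                     stringsAsFactors = FALSE))
    net$nodes <- rbind(net$nodes,
                       data.frame(id = aux_id, name = aux_id,
                                  entity_class = "auxiliary",
                                  stringsAsFactors = FALSE))
  }
  net$edges <- edges
  net
}

#' @export
print.logic_network <- function(x, ...) {
  roles <- infer_roles(x)
  cat("Logical Network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$polarity == "-"), " inhibitory)\n", sep = "")
  cat("  root inputs: ", sum(roles$is_root_input),
      "; terminal outputs: ", sum(roles$is_terminal_output), "\n", sep = "")
  invisible(x)
}

#' Convert a Logical Network to an igraph object
#'
#' Edge attributes `polarity` and `logic` are carried over; vertex names are
#' node ids.
#'
#' @param net a `logic_network`.
#' @return an [igraph::graph] (directed).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Infer root-input and terminal-output roles
#'
#' A root input (RI) is a node used as a reaction input but never produced
#' within the pathway, i.e. it has in-degree 0 in the logic graph; a
#' terminal output (TO) is produced but never consumed, i.e. out-degree 0.
#' A pure cycle legitimately has neither. Key outputs default to the
#' terminal outputs but any node can be designated (some assays read out
#' internal nodes).
#'
#' @param net a `logic_network`.
#' @param key_outputs optional character vector of node ids to flag as key
#'   outputs; defaults to the terminal outputs.
#' @return data.frame with columns `id`, `is_root_input`,
#'   `is_terminal_output`, `is_key_output`.
#' @examples
#' net <- logic_network(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                                 polarity = "+", logic = "AND"))
#' infer_roles(net)
#' @export
infer_roles <- function(net, key_outputs = NULL) {
  stopifnot(inherits(net, "logic_network"))
  ids <- net$nodes$id
  roles <- data.frame(
    id = ids,
    is_root_input = !(ids %in% net$edges$target),
    is_terminal_output = !(ids %in% net$edges$source),
    stringsAsFactors = FALSE)
  if (is.null(key_outputs)) {
    roles$is_key_output <- roles$is_terminal_output
  } else {
    bad <- setdiff(key_outputs, ids)
    if (length(bad) > 0) {
      stop("key output(s) not in network: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    roles$is_key_output <- ids %in% key_outputs
  }
  roles
}

#' Enumerate perturbation test cases
#'
#' A test case is a unique combination of a root input, a perturbation
#' direction (up- or downregulation), and a key output, with empty slots
#' for the predicted and observed three-class outcome. Every (root, output)
#' pair yields exactly two cases, so the full set has
#' `length(roots) * length(key_outputs) * 2` rows.
#'
#' @param net a `logic_network`.
#' @param roots character vector of root-input node ids.
#' @param key_outputs character vector of key-output node ids; must be
#'   disjoint from `roots` (a self-pair is meaningless).
#' @return data.frame with columns `root`, `direction` (`"up"`/`"down"`),
#'   `key_output`, `predicted`, `observed` (the last two `NA`).
#' @export
enumerate_test_cases <- function(net, roots, key_outputs) {
  stopifnot(inherits(net, "logic_network"))
  roots <- as.character(roots)
  key_outputs <- as.character(key_outputs)
  bad <- setdiff(c(roots, key_outputs), net$nodes$id)
  if (length(bad) > 0) {
    stop("node id(s) not in network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  overlap <- intersect(roots, key_outputs)
  if (length(overlap) > 0) {
    stop("root input(s) listed among key outputs: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(direction = c("up", "down"),
                      key_output = key_outputs, root = roots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(root = grid$root, direction = grid$direction,
             key_output = grid$key_output,
             predicted = NA_character_, observed = NA_character_,
             stringsAsFactors = FALSE)
}
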