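# Automation of the manual prediction procedure: enumerate directed simple
# paths between a root input and a key output, then apply the path-parity
# rules. Only edge polarity matters here; the AND/OR logic class plays no
# role in the manual rules.

#' Enumerate simple directed paths between two nodes
#'
#' Depth-first enumeration of all simple (node-revisit-free) directed paths
#' from `src` to `dst`, visiting successors in lexicographic node-id order
#' so the result order is deterministic. Each path carries its count of
#' inhibitory edges and the resulting parity. Two caps bound the search:
#' `max_len` (maximum number of edges per path) and `max_paths`; hitting
#' either sets the `truncated` flag on the result rather than failing
#' silently.
#'
#' @param net a `logic_network`.
#' @param src,dst node ids.
#' @param max_paths stop after this many paths (default 10000).
#' @param max_len ignore paths longer than this many edges (default 50,
#'   comfortably above the longest root-to-output distances seen in curated
#'   pathways).
#' @return object of class `path_set`: list with `paths` (list of node-id
#'   vectors), `negatives` (integer vector), `parity` (`"even"`/`"odd"`),
#'   and `truncated` (logical).
#' @examples
#' net <- logic_network(data.frame(source = c("A", "B"), target = c("B", "C"),
#'                                 polarity = c("+", "-"), logic = "AND"))
#' enumerate_paths(net, "A", "C")
#' @export
enumerate_paths <- function(net, src, dst, max_paths = 10000L,
                            max_len = 50L) {
  stopifnot(inherits(net, "logic_network"))
  ids <- net$nodes$id
  if (!src %in% ids) stop("unknown source node: ", src, call. = FALSE)
  if (!dst %in% ids) stop("unknown target node: ", dst, call. = FALSE)

  # adjacency with signs, successors sorted for deterministic order
  adj <- split(seq_len(nrow(net$edges)), net$edges$source)
  adj <- lapply(adj, function(i) i[order(net$edges$target[i])])

  state <- new.env(parent = emptyenv())
  state$paths <- list()
  state$negatives <- integer()
  state$truncated <- FALSE

  visit <- function(node, path, negs) {
    if (state$truncated) return(invisible())
    if (node == dst && length(path) > 1) {
      if (length(state$paths) >= max_paths) {
        state$truncated <- TRUE
        return(invisible())
      }
      state$paths[[length(state$paths) + 1]] <- path
      state$negatives <- c(state$negatives, negs)
      return(invisible())
    }
    if (length(path) - 1 >= max_len) {
      state$truncated <- TRUE
      return(invisible())
    }
    for (ei in adj[[node]]) {
      nxt <- net$edges$target[ei]
      if (nxt %in% path) next
      visit(nxt, c(path, nxt),
            negs + (net$edges$polarity[ei] == "-"))
    }
    invisible()
  }
  if (src != dst) visit(src, src, 0L)

  structure(list(paths = state$paths, negatives = state$negatives,
                 parity = ifelse(state$negatives %% 2 == 0, "even", "odd"),
                 truncated = state$truncated),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat("path set: ", length(x$paths), " path(s)",
      if (x$truncated) " [TRUNCATED]", "\n", sep = "")
  for (i in seq_along(x$paths)) {
    cat("  ", paste(x$paths[[i]], collapse = " -> "),
        "  (", x$negatives[i], " negative, ", x$parity[i], ")\n", sep = "")
  }
  invisible(x)
}

# Shared rule core: class from parity counts and perturbation direction.
.parity_rules <- function(n_even, n_odd, direction) {
  if (n_even + n_odd == 0 || n_even == n_odd) return("no_change")
  if (n_even > n_odd) direction else setdiff(c("up", "down"), direction)
}

#' Predict a perturbation effect with the path-parity rules
#'
#' Applies the manual prediction rules to one root-input perturbation:
#' 1. all connecting paths of even inhibitory parity (including none) --
#'    the key output moves in the same direction as the root input;
#' 2. odd parity -- opposite direction;
#' 3. no path, or paths of opposing parity in equal number -- no change;
#' 4. more than two paths -- majority parity wins (an exact tie
#'    generalizes rule 3 to no change).
#'
#' If path enumeration hit its caps the prediction is still returned but
#' flagged low-confidence via the `"low_confidence"` attribute.
#'
#' @param net a `logic_network`.
#' @param root root-input node id.
#' @param direction `"up"` or `"down"`.
#' @param key_output key-output node id.
#' @param max_paths,max_len passed to [enumerate_paths()].
#' @return `"up"`, `"down"` or `"no_change"` (attribute `low_confidence`
#'   is `TRUE` when enumeration was truncated).
#' @export
predict_curator <- function(net, root, direction, key_output,
                            max_paths = 10000L, max_len = 50L) {
  .validate_classes(direction, c("up", "down"), "direction")
  ps <- enumerate_paths(net, root, key_output, max_paths = max_paths,
                        max_len = max_len)
  pred <- .parity_rules(sum(ps$parity == "even"), sum(ps$parity == "odd"),
                        direction)
  attr(pred, "low_confidence") <- ps$truncated
  pred
}

#' Predict all test cases with the path-parity rules
#'
#' Vectorized driver over a test-case table; fills the `predicted` column
#' and adds a logical `low_confidence` column for truncated enumerations.
#'
#' @param net a `logic_network`.
#' @param cases test-case data.frame (see [enumerate_test_cases()]).
#' @param max_paths,max_len passed to [enumerate_paths()].
#' @return `cases` with `predicted` filled.
#' @export
predict_curator_cases <- function(net, cases, max_paths = 10000L,
                                  max_len = 50L) {
  preds <- lapply(seq_len(nrow(cases)), function(i) {
    predict_curator(net, cases$root[i], cases$direction[i],
                    cases$key_output[i], max_paths = max_paths,
                    max_len = max_len)
  })
  cases$predicted <- vapply(preds, as.character, character(1))
  cases$low_confidence <- vapply(preds, function(p)
    isTRUE(attr(p, "low_confidence")), logical(1))
  cases
}

#' Shortest root-to-output path length per test case
#'
#' Directed shortest-path edge count for every case; unreachable pairs get
#' `NA` (the "none" marker).
#'
#' @param net a `logic_network`.
#' @param cases test-case data.frame.
#' @return `cases` with an integer `shortest_path_length` column.
#' @export
path_length_summary <- function(net, cases) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = unique(cases$root),
                         to = unique(cases$key_output), mode = "out")
  len <- d[cbind(match(cases$root, rownames(d)),
                 match(cases$key_output, colnames(d)))]
  cases$shortest_path_length <- ifelse(is.finite(len), as.integer(len),
                                       NA_integer_)
  cases
}
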