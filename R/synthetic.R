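# Seeded generators of Logical Networks with known ground truth. The
# generator emulates the structures found in pathway-derived logic graphs:
# layered signal flow from root inputs to terminal outputs, inhibitory
# edges, OR fan-in standing for entity sets of interchangeable molecules,
# layer-skipping shortcuts, and optional feedback edges.

#' Generator configuration for synthetic Logical Networks
#'
#' Defaults describe a small signalling-cascade-like graph (5 layers of
#' width 4, at most 60 nodes by construction) on which exhaustive path
#' enumeration is sub-second, with a realistic minority of inhibitory
#' edges and entity-set style OR fan-in.
#'
#' @param seed integer seed; identical configurations generate identical
#'   networks.
#' @param n_layers number of layers (layer 1 holds the root inputs).
#' @param width nodes per layer.
#' @param p_negative probability an edge is inhibitory.
#' @param p_or probability a node combines its inputs with OR (entity-set
#'   style) rather than AND.
#' @param p_skip probability a parent is drawn from any earlier layer
#'   rather than the immediately preceding one.
#' @param p_cycle probability of adding one feedback edge from the last
#'   layer back to a non-root node.
#' @param set_fan_in maximum fan-in per node.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_layers = 5L, width = 4L,
                             p_negative = 0.3, p_or = 0.3, p_skip = 0.2,
                             p_cycle = 0, set_fan_in = 3L) {
  probs <- c(p_negative = p_negative, p_or = p_or, p_skip = p_skip,
             p_cycle = p_cycle)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_layers < 2 || width < 1 || set_fan_in < 1) {
    stop("need n_layers >= 2, width >= 1, set_fan_in >= 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_layers = as.integer(n_layers),
                 width = as.integer(width), p_negative = p_negative,
                 p_or = p_or, p_skip = p_skip, p_cycle = p_cycle,
                 set_fan_in = as.integer(set_fan_in)),
            class = "generator_config")
}

# Run code under a private RNG stream so generation never disturbs the
# caller's random state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic Logical Network
#'
#' Builds a connected layered DAG: layer-1 nodes are root inputs; every
#' later node draws 1..`set_fan_in` parents (from the previous layer, or
#' any earlier layer with probability `p_skip`) under a single logic class;
#' every non-terminal node is guaranteed at least one child so signal flow
#' reaches the last layer. With probability `p_cycle` one feedback edge is
#' added from the last layer to a random internal (non-root) node.
#'
#' @param cfg a [generator_config()].
#' @return list with elements `network` (a `logic_network`) and `roles`
#'   (as from [infer_roles()]).
#' @examples
#' gen <- generate_network(generator_config(seed = 7))
#' gen$network
#' @export
generate_network <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      sprintf("L%d_N%d", l, seq_len(cfg$width))
    })
    edges <- list()
    for (l in 2:cfg$n_layers) {
      for (v in layers[[l]]) {
        logic <- if (runif(1) < cfg$p_or) "OR" else "AND"
        n_par <- sample.int(cfg$set_fan_in, 1)
        pool_layers <- if (l > 2 && runif(1) < cfg$p_skip) 1:(l - 1) else l - 1
        pool <- unlist(layers[pool_layers])
        parents <- sample(pool, min(n_par, length(pool)))
        edges[[length(edges) + 1]] <- data.frame(
          source = parents, target = v,
          polarity = ifelse(runif(length(parents)) < cfg$p_negative, "-", "+"),
          logic = logic, stringsAsFactors = FALSE)
      }
    }
    edf <- do.call(rbind, edges)
    # guarantee every node before the last layer feeds something downstream
    for (l in 1:(cfg$n_layers - 1)) {
      for (v in layers[[l]]) {
        if (!v %in% edf$source) {
          child <- sample(layers[[l + 1]], 1)
          child_logic <- edf$logic[edf$target == child][1]
          edf <- rbind(edf, data.frame(
            source = v, target = child,
            polarity = if (runif(1) < cfg$p_negative) "-" else "+",
            logic = child_logic, stringsAsFactors = FALSE))
        }
      }
    }
    if (runif(1) < cfg$p_cycle) {
      from <- sample(layers[[cfg$n_layers]], 1)
      to <- sample(unlist(layers[-1]), 1)
      if (to != from) {
        to_logic <- edf$logic[edf$target == to][1]
        edf <- rbind(edf, data.frame(source = from, target = to,
                                     polarity = "-", logic = to_logic,
                                     stringsAsFactors = FALSE))
      }
    }
    classes <- c("protein", "gene", "rna", "complex", "set",
                 "small_molecule")
    ids <- unlist(layers)
    nodes <- data.frame(id = ids, name = ids,
                        entity_class = sample(classes, length(ids),
                                              replace = TRUE),
                        stringsAsFactors = FALSE)
    net <- suppressMessages(logic_network(edf, nodes = nodes))
    list(network = net, roles = infer_roles(net))
  })
}

# ---------------------------------------------------------------------------
# Ground-truth oracle.
#
# Deliberately naive and implemented apart from the curator-rule module:
# igraph enumerates every simple directed path, parities are tallied and a
# majority vote decides the class. Exponential in the worst case, intended
# only for networks of the generator's default scale.

.oracle_parity_vote <- function(g, edge_sign, src, dst, direction) {
  if (src == dst) return("no_change")
  paths <- igraph::all_simple_paths(g, from = src, to = dst, mode = "out")
  if (length(paths) == 0) return("no_change")
  parities <- vapply(paths, function(p) {
    eids <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1]))
    sum(edge_sign[eids]) %% 2
  }, numeric(1))
  n_even <- sum(parities == 0)
  n_odd <- sum(parities == 1)
  if (n_even == n_odd) return("no_change")
  same <- n_even > n_odd
  if (same) direction else if (direction == "up") "down" else "up"
}

#' Attach brute-force ground-truth classes to test cases
#'
#' For every root-input / key-output / direction combination, enumerates
#' all simple directed paths (via igraph) and assigns the observed class by
#' parity majority vote: no path or a tie between even- and odd-parity
#' paths gives `no_change`; an even majority transmits the perturbation
#' direction; an odd majority inverts it. This oracle is intentionally
#' independent of [predict_curator()] so the two can cross-check each
#' other.
#'
#' @param net a `logic_network`.
#' @param roles roles data.frame from [infer_roles()] (or
#'   [generate_network()]).
#' @param max_nodes refuse networks larger than this (exhaustive
#'   enumeration is exponential); default 200.
#' @return a test-case data.frame with the `observed` column filled.
#' @export
generate_ground_truth_cases <- function(net, roles, max_nodes = 200L) {
  stopifnot(inherits(net, "logic_network"))
  if (nrow(net$nodes) > max_nodes) {
    stop("network too large for exhaustive ground truth (",
         nrow(net$nodes), " nodes > ", max_nodes, ")", call. = FALSE)
  }
  roots <- roles$id[roles$is_root_input]
  outs <- setdiff(roles$id[roles$is_key_output], roots)
  cases <- enumerate_test_cases(net, roots, outs)
  g <- as_igraph(net)
  edge_sign <- as.integer(igraph::E(g)$polarity == "-")
  cases$observed <- vapply(seq_len(nrow(cases)), function(i) {
    .oracle_parity_vote(g, edge_sign, cases$root[i], cases$key_output[i],
                        cases$direction[i])
  }, character(1))
  cases
}
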