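# Shared fixtures and independent oracles for the test suite. Everything
# here is built in code; no stored data files.

# small hand-written networks ------------------------------------------------

chain_net <- function(polarities) {
  n <- length(polarities) + 1
  ids <- LETTERS[seq_len(n)]
  logic_network(data.frame(source = ids[-n], target = ids[-1],
                           polarity = polarities, logic = "AND",
                           stringsAsFactors = FALSE))
}

diamond_net <- function(pol_upper = "+", pol_lower = "+") {
  logic_network(data.frame(
    source = c("A", "A", "B", "C"),
    target = c("B", "C", "D", "D"),
    polarity = c(pol_upper, pol_lower, "+", "+"),
    logic = "OR", stringsAsFactors = FALSE))
}

# Independent closed-form oracle for pure-AND acyclic networks: evaluate
# activities in topological order, x_v = clamp(prod of edge-transformed
# parent values). Deliberately separate from solve_model()'s relaxation.
oracle_topological_eval <- function(net, perturb, cfg = solver_config()) {
  stopifnot(all(net$edges$logic == "AND"))
  g <- as_igraph(net)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  roles <- infer_roles(net)
  x <- setNames(rep(NA_real_, nrow(net$nodes)), net$nodes$id)
  for (v in ord) {
    if (roles$is_root_input[roles$id == v]) {
      x[v] <- if (v %in% names(perturb)) perturb[[v]] else cfg$baseline
    } else {
      ein <- net$edges[net$edges$target == v, , drop = FALSE]
      vals <- ifelse(ein$polarity == "-", 1 / x[ein$source], x[ein$source])
      x[v] <- min(max(prod(vals), cfg$lower_bound), cfg$upper_bound)
    }
  }
  x
}

# Independent confusion-matrix oracle: per-pair category via explicit
# lookup table rather than the package's boolean algebra.
oracle_confusion <- function(predicted, observed) {
  cat_of <- function(p, o) {
    if (p == "no_change" && o == "no_change") return("TN")
    if (p == "no_change") return("FN")
    if (o == "no_change") return("FP")
    if (p == o) return("TP")
    "FP-WD"
  }
  mapply(cat_of, predicted, observed, USE.NAMES = FALSE)
}

# A rating matrix with the agreement structure of the three-curator study:
# 100 cases, 3 raters, complete agreement on 81 cases, no case with
# three-way disagreement. Synthetic stand-in for the unreleased case-level
# ratings, constructed so that pairwise agreements are 84%, 81%, 97% and
# the label marginals give expected agreement 0.367.
synthetic_curator_ratings <- function() {
  complete <- function(lbl, k) {
    matrix(lbl, nrow = k, ncol = 3)
  }
  rbind(
    complete("up", 42), complete("down", 28), complete("no_change", 11),
    matrix(rep(c("up", "up", "down"), 3), ncol = 3, byrow = TRUE),
    matrix(rep(c("no_change", "down", "down"), 8), ncol = 3, byrow = TRUE),
    matrix(rep(c("down", "no_change", "no_change"), 8), ncol = 3,
           byrow = TRUE))
}
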