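# Continuous-activity perturbation propagation. Node activities live on a
# fold-change scale in [0.01, 100] with 1 = unperturbed. Each non-root node
# carries one equation over its inputs:
#   AND fan-in: the output value is the product of the (transformed) input
#     values; an inhibitory edge contributes the reciprocal of its input.
#   OR fan-in: the arithmetic average of the (transformed) input values --
#     entity-set semantics, every member counts equally.
# Every node has two values, xbar (used as input downstream) and x (its
# equation output); the model fixes perturbed roots, holds other roots at
# baseline, and minimizes the total xbar-vs-x disagreement, which absorbs
# inconsistency (e.g. around negative feedback loops) instead of failing.

#' Solver configuration
#'
#' @param lower_bound,upper_bound activity bounds (defaults 0.01 and 100;
#'   reciprocal bounds keep up- and downregulation symmetric on the log
#'   scale).
#' @param baseline unperturbed activity (1).
#' @param up_value,down_value activities assigned to perturbed roots
#'   (defaults saturate at the bounds: 100 and 0.01).
#' @param or_mode `"arithmetic_raw"` (default: OR averages raw transformed
#'   activities) or `"geometric_log"` (averages on the log scale, making
#'   the whole system linear).
#' @param objective `"L1"` (default) or `"L2"` disagreement distance.
#' @param tol convergence tolerance on log10 activities.
#' @param max_iter maximum relaxation sweeps before polishing.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(lower_bound = 0.01, upper_bound = 100,
                          baseline = 1, up_value = 100, down_value = 0.01,
                          or_mode = c("arithmetic_raw", "geometric_log"),
                          objective = c("L1", "L2"),
                          tol = 1e-9, max_iter = 500L) {
  or_mode <- match.arg(or_mode)
  objective <- match.arg(objective)
  if (!(lower_bound > 0 && lower_bound < baseline && baseline < upper_bound)) {
    stop("need 0 < lower_bound < baseline < upper_bound", call. = FALSE)
  }
  for (v in c(up_value, down_value)) {
    if (v < lower_bound || v > upper_bound) {
      stop("perturbation values must lie within the bounds", call. = FALSE)
    }
  }
  structure(list(lower_bound = lower_bound, upper_bound = upper_bound,
                 baseline = baseline, up_value = up_value,
                 down_value = down_value, or_mode = or_mode,
                 objective = objective, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "solver_config")
}

#' Build the perturbation-propagation model
#'
#' Compiles a Logical Network plus a set of fixed root perturbations into
#' the internal model form: per-node equation structure (parent indices,
#' edge signs, logic class) and fixed log10 activities for every root
#' (perturbed roots at their assigned value, all other roots at baseline).
#'
#' @param net a `logic_network` (fan-in logic must be uniform per node,
#'   which [logic_network()] normalization guarantees).
#' @param perturbations named numeric vector: node id -> fixed activity
#'   value, or named character vector of `"up"`/`"down"` translated via
#'   `cfg$up_value`/`cfg$down_value`. Perturbed nodes must be root inputs
#'   unless `allow_non_root = TRUE`.
#' @param cfg a [solver_config()].
#' @param allow_non_root permit fixing internal nodes (their equation is
#'   then dropped).
#' @return list of class `lp_model`.
#' @export
build_model <- function(net, perturbations = NULL, cfg = solver_config(),
                        allow_non_root = FALSE) {
  stopifnot(inherits(net, "logic_network"), inherits(cfg, "solver_config"))
  ids <- net$nodes$id
  n <- length(ids)
  roles <- infer_roles(net)

  fixed <- rep(NA_real_, n)
  names(fixed) <- ids
  fixed[roles$is_root_input] <- cfg$baseline
  if (!is.null(perturbations)) {
    if (is.null(names(perturbations)) || any(names(perturbations) == "")) {
      stop("perturbations must be a named vector", call. = FALSE)
    }
    bad <- setdiff(names(perturbations), ids)
    if (length(bad) > 0) {
      stop("perturbation on unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (is.character(perturbations)) {
      .validate_classes(perturbations, c("up", "down"), "perturbation")
      perturbations <- setNames(
        ifelse(perturbations == "up", cfg$up_value, cfg$down_value),
        names(perturbations))
    }
    if (any(perturbations < cfg$lower_bound |
              perturbations > cfg$upper_bound)) {
      stop("perturbation value(s) outside bounds", call. = FALSE)
    }
    non_root <- names(perturbations)[!names(perturbations) %in%
                                       roles$id[roles$is_root_input]]
    if (length(non_root) > 0 && !allow_non_root) {
      stop("perturbed node(s) are not root inputs: ",
           paste(non_root, collapse = ", "),
           " (set allow_non_root = TRUE to override)", call. = FALSE)
    }
    fixed[names(perturbations)] <- perturbations
  }

  # per-node equation structure over non-fixed nodes
  dangling <- ids[!roles$is_root_input & !ids %in% net$edges$target]
  if (length(dangling) > 0) {
    stop("non-root node(s) without incoming edges: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  eqs <- vector("list", n)
  for (v in which(is.na(fixed))) {
    ein <- which(net$edges$target == ids[v])
    logic <- unique(net$edges$logic[ein])
    if (length(logic) != 1) {
      stop("mixed fan-in logic at node ", ids[v],
           "; run logic_network(normalize = TRUE)", call. = FALSE)
    }
    eqs[[v]] <- list(parents = match(net$edges$source[ein], ids),
                     sign = ifelse(net$edges$polarity[ein] == "-", -1, 1),
                     logic = logic)
  }
  structure(list(net = net, ids = ids, fixed = fixed, eqs = eqs,
                 cfg = cfg), class = "lp_model")
}

# log10 equation output for node v given current log10 activities y
.eq_value <- function(eq, y, or_mode) {
  contrib <- eq$sign * y[eq$parents]
  if (eq$logic == "AND") {
    sum(contrib)
  } else if (or_mode == "geometric_log") {
    mean(contrib)
  } else {
    log10(mean(10^contrib))
  }
}

#' Solve the perturbation-propagation model
#'
#' Solves in log10 space (AND products and reciprocals become sums, bounds
#' become a symmetric box) by deterministic nonlinear Gauss-Seidel
#' relaxation from the all-baseline start: each sweep replaces every free
#' node's value with its bound-clamped equation output until the largest
#' change falls below `tol`. On feedback structures where relaxation
#' oscillates, the last iterate seeds a smoothed box-constrained
#' quasi-Newton polish (`optim(method = "L-BFGS-B")`) of the configured
#' disagreement objective. There is no randomness anywhere on this path.
#'
#' @param model from [build_model()].
#' @return object of class `solver_solution`: list with `values`
#'   (data.frame `id`, `xbar`, `x`), `objective` (total raw-scale
#'   disagreement under the configured distance), `status`
#'   (`"optimal"` when disagreement is ~0, `"feasible"` when residual
#'   disagreement remains, `"failed"` on polish failure), `iterations`.
#' @export
solve_model <- function(model) {
  stopifnot(inherits(model, "lp_model"))
  cfg <- model$cfg
  n <- length(model$ids)
  lo <- log10(cfg$lower_bound)
  hi <- log10(cfg$upper_bound)
  y <- ifelse(is.na(model$fixed), log10(cfg$baseline), log10(model$fixed))
  free <- which(is.na(model$fixed))

  iterations <- 0L
  converged <- length(free) == 0
  while (!converged && iterations < cfg$max_iter) {
    iterations <- iterations + 1L
    delta <- 0
    for (v in free) {
      new_v <- min(max(.eq_value(model$eqs[[v]], y, cfg$or_mode), lo), hi)
      delta <- max(delta, abs(new_v - y[v]))
      y[v] <- new_v
    }
    converged <- delta < cfg$tol
  }

  status <- "optimal"
  if (!converged && length(free) > 0) {
    # relaxation oscillates (feedback); minimize disagreement directly
    eps <- 1e-10
    obj_fun <- function(yf) {
      y[free] <- yf
      resid <- vapply(free, function(v) {
        xv <- min(max(.eq_value(model$eqs[[v]], y, cfg$or_mode), lo), hi)
        y[v] - xv
      }, numeric(1))
      if (cfg$objective == "L1") sum(sqrt(resid^2 + eps)) else sum(resid^2)
    }
    fit <- tryCatch(
      stats::optim(y[free], obj_fun, method = "L-BFGS-B",
                   lower = rep(lo, length(free)),
                   upper = rep(hi, length(free)),
                   control = list(maxit = 2000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) {
      status <- "failed"
    } else {
      y[free] <- fit$par
      status <- "feasible"
    }
  }

  x_out <- vapply(seq_len(n), function(v) {
    if (!is.na(model$fixed[v])) model$fixed[v]
    else 10^min(max(.eq_value(model$eqs[[v]], y, cfg$or_mode), lo), hi)
  }, numeric(1))
  xbar <- 10^y
  d <- abs(xbar - x_out)
  objective <- if (cfg$objective == "L1") sum(d) else sum(d^2)
  if (status == "optimal" && objective > 1e-6) status <- "feasible"

  structure(list(values = data.frame(id = model$ids, xbar = xbar,
                                     x = x_out, stringsAsFactors = FALSE),
                 objective = objective, status = status,
                 iterations = iterations),
            class = "solver_solution")
}

#' @export
print.solver_solution <- function(x, ...) {
  cat("solver solution: status ", x$status, ", objective ",
      format(x$objective, digits = 4), ", ", x$iterations,
      " sweep(s)\n", sep = "")
  print(utils::head(x$values, 10))
  if (nrow(x$values) > 10) cat("  ... ", nrow(x$values) - 10, " more\n")
  invisible(x)
}

#' Continuous key-output activity under a single-root perturbation
#'
#' Convenience wrapper: builds and solves the model for one test case and
#' returns the key output's activity value (`x`). An output unreachable
#' from the perturbed root stays at baseline.
#'
#' @param net a `logic_network`.
#' @param case one-row test-case data.frame (or list) with `root`,
#'   `direction`, `key_output`.
#' @param cfg a [solver_config()].
#' @return named numeric: the key output's activity; attribute `status`
#'   carries the solver status. Solver failure raises an error.
#' @export
predict_output_activity <- function(net, case, cfg = solver_config()) {
  pert <- setNames(as.character(case$direction), as.character(case$root))
  model <- build_model(net, pert, cfg)
  sol <- solve_model(model)
  if (sol$status == "failed") {
    stop("solver failed for case ", case$root, " -> ", case$key_output,
         call. = FALSE)
  }
  val <- sol$values$x[match(as.character(case$key_output), sol$values$id)]
  structure(setNames(val, as.character(case$key_output)),
            status = sol$status)
}

#' Continuous activities for a table of test cases
#'
#' One model solve per case (single-root perturbations, per the test-case
#' design); adds an `activity` column.
#'
#' @param net a `logic_network`.
#' @param cases test-case data.frame.
#' @param cfg a [solver_config()].
#' @return `cases` with numeric `activity` and character `solver_status`
#'   columns.
#' @export
predict_activity_cases <- function(net, cases, cfg = solver_config()) {
  res <- lapply(seq_len(nrow(cases)), function(i) {
    v <- predict_output_activity(net, cases[i, ], cfg)
    list(val = unname(v), status = attr(v, "status"))
  })
  cases$activity <- vapply(res, `[[`, numeric(1), "val")
  cases$solver_status <- vapply(res, `[[`, character(1), "status")
  cases
}
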