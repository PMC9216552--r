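# Discretization of continuous activities into {up, down, no_change} and
# cutoff sweeps against a reference prediction set.

#' Discretize continuous activities into three classes
#'
#' A fractional-change cutoff `c` converts a fold-change activity into a
#' three-class call. Under the default `multiplicative_symmetric`
#' convention the boundaries are reciprocal-symmetric (matching the
#' log-scale activity model): up if `value >= 1 + c`, down if
#' `value <= 1/(1 + c)`. The `additive_symmetric` convention uses
#' `1 - c` as the lower boundary instead.
#'
#' @param value positive numeric vector of activities (1 = baseline).
#' @param cutoff fractional change threshold in (0, 1); default 0.15, the
#'   15% change conventionally used after calibration.
#' @param convention `"multiplicative_symmetric"` (default) or
#'   `"additive_symmetric"`.
#' @return character vector over `up`, `down`, `no_change`.
#' @examples
#' discretize(c(1, 1.2, 0.85), cutoff = 0.15)
#' @export
discretize <- function(value,
                       cutoff = 0.15,
                       convention = c("multiplicative_symmetric",
                                      "additive_symmetric")) {
  convention <- match.arg(convention)
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(value) | value <= 0)) {
    stop("activities must be positive finite values", call. = FALSE)
  }
  lower <- if (convention == "multiplicative_symmetric") 1 / (1 + cutoff)
           else 1 - cutoff
  ifelse(value >= 1 + cutoff, "up",
         ifelse(value <= lower, "down", "no_change"))
}

#' Default and literal cutoff grids
#'
#' The default grid is `{0.01, 0.05, 0.10, ..., 0.95, 0.99}` plus 0.15;
#' the `"literal"` grid reads "1% to 99% in 5% increments" literally:
#' `{0.01, 0.06, ..., 0.96}`.
#'
#' @param which `"default"` or `"literal"`.
#' @return numeric vector of cutoffs.
#' @export
cutoff_grid <- function(which = c("default", "literal")) {
  which <- match.arg(which)
  # integer percents, then scale: avoids floating-point near-duplicates
  if (which == "literal") seq(1L, 99L, by = 5L) / 100
  else sort(unique(c(1L, seq(5L, 95L, by = 5L), 15L, 99L))) / 100
}

# Direction-aware binary confusion at one cutoff: "positive" = any
# predicted change, with the correct direction required for a TP; a
# predicted change whose reference is a change in the other direction is a
# wrong-direction FP.
.binary_counts <- function(pred, ref) {
  pred_chg <- pred != "no_change"
  ref_chg <- ref != "no_change"
  tp <- sum(pred_chg & ref_chg & pred == ref)
  fp_wd <- sum(pred_chg & ref_chg & pred != ref)
  fp <- sum(pred_chg & !ref_chg) + fp_wd
  fn <- sum(!pred_chg & ref_chg)
  tn <- sum(!pred_chg & !ref_chg)
  c(tp = tp, tn = tn, fp = fp, fp_wd = fp_wd, fn = fn)
}

#' Sweep discretization cutoffs against reference classes
#'
#' Discretizes the continuous activities at every cutoff in the grid and
#' scores them against the reference three-class calls, treating any
#' predicted change (in the correct direction) as the positive class.
#' Reports accuracy, sensitivity (TPR), specificity, precision, FDR, F1
#' and FPR per cutoff, plus the F1-maximizing cutoff (ties broken toward
#' the smallest cutoff).
#'
#' @param activity numeric vector of continuous activities.
#' @param reference character vector of reference classes (`up`, `down`,
#'   `no_change`), aligned with `activity`.
#' @param grid numeric vector of cutoffs (see [cutoff_grid()]).
#' @param convention passed to [discretize()].
#' @return list of class `cutoff_sweep`: `sweep` (one row per cutoff),
#'   `best_cutoff`, `roc` (data.frame `fpr`, `tpr`).
#' @export
sweep_cutoffs <- function(activity, reference,
                          grid = cutoff_grid("default"),
                          convention = "multiplicative_symmetric") {
  if (length(reference) == 0) {
    stop("reference set is empty", call. = FALSE)
  }
  if (length(activity) != length(reference)) {
    stop("activity and reference lengths differ", call. = FALSE)
  }
  .validate_classes(reference, .classes3, "reference")
  rows <- lapply(grid, function(cut) {
    k <- .binary_counts(discretize(activity, cut, convention), reference)
    total <- sum(k[c("tp", "tn", "fp", "fn")])
    sens <- if (k[["tp"]] + k[["fn"]] > 0)
      k[["tp"]] / (k[["tp"]] + k[["fn"]]) else NA_real_
    spec <- if (k[["tn"]] + k[["fp"]] > 0)
      k[["tn"]] / (k[["tn"]] + k[["fp"]]) else NA_real_
    prec <- if (k[["tp"]] + k[["fp"]] > 0)
      k[["tp"]] / (k[["tp"]] + k[["fp"]]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else 0
    data.frame(cutoff = cut, tp = k[["tp"]], tn = k[["tn"]],
               fp = k[["fp"]], fp_wd = k[["fp_wd"]], fn = k[["fn"]],
               accuracy = (k[["tp"]] + k[["tn"]]) / total,
               sensitivity = sens, specificity = spec, precision = prec,
               fdr = if (is.na(prec)) NA_real_ else 1 - prec,
               f1 = f1,
               fpr = if (is.na(spec)) NA_real_ else 1 - spec)
  })
  sweep <- do.call(rbind, rows)
  best <- min(sweep$cutoff[sweep$f1 == max(sweep$f1)])
  structure(list(sweep = sweep, best_cutoff = best,
                 roc = data.frame(fpr = sweep$fpr, tpr = sweep$sensitivity)),
            class = "cutoff_sweep")
}

#' @export
print.cutoff_sweep <- function(x, ...) {
  cat("cutoff sweep over", nrow(x$sweep), "cutoffs; best F1 at",
      x$best_cutoff, "\n")
  print(x$sweep[, c("cutoff", "accuracy", "sensitivity", "specificity",
                    "precision", "f1")], digits = 3, row.names = FALSE)
  invisible(x)
}
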