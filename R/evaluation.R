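# Direction-aware scoring of three-class predictions against observed
# outcomes, metric aggregation across pathways, and stratified summaries.

#' Classify one prediction/observation pair
#'
#' Confusion categories for bidirectional perturbation calls:
#' * `TP` -- predicted and observed agree on a change (up or down);
#' * `TN` -- both call no change;
#' * `FN` -- predicted no change, but a change was observed;
#' * `FP` -- a change was predicted, none observed;
#' * `FP-WD` -- a change was predicted in the direction opposite to the
#'   observed change (a wrong-direction false positive, counted inside the
#'   FP total by all derived metrics).
#'
#' @param predicted,observed character vectors over `up`, `down`,
#'   `no_change`.
#' @return character vector over `TP`, `TN`, `FP`, `FP-WD`, `FN`.
#' @export
classify_outcome <- function(predicted, observed) {
  .validate_classes(predicted, .classes3, "predicted")
  .validate_classes(observed, .classes3, "observed")
  pred_chg <- predicted != "no_change"
  obs_chg <- observed != "no_change"
  out <- character(length(predicted))
  out[pred_chg & obs_chg & predicted == observed] <- "TP"
  out[!pred_chg & !obs_chg] <- "TN"
  out[!pred_chg & obs_chg] <- "FN"
  out[pred_chg & !obs_chg] <- "FP"
  out[pred_chg & obs_chg & predicted != observed] <- "FP-WD"
  out
}

#' Score test cases into a confusion summary
#'
#' Counts the five confusion categories (`FP-WD` is a subset of the FP
#' total) and derives accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP) and FDR = 1-precision,
#' with F1 from precision and sensitivity. Metrics with a zero denominator
#' are `NA`, never silently 0.
#'
#' @param cases test-case data.frame; every row must have both `predicted`
#'   and `observed` set.
#' @return list of class `confusion_summary` with `counts` (named:
#'   tp, tn, fp_total, fp_wd, fn, total) and `metrics` (named fractions).
#' @export
score_cases <- function(cases) {
  unset <- is.na(cases$predicted) | is.na(cases$observed)
  if (any(unset)) {
    stop("case(s) with unset predicted/observed class: rows ",
         paste(utils::head(which(unset), 10), collapse = ", "),
         call. = FALSE)
  }
  cls <- classify_outcome(cases$predicted, cases$observed)
  confusion_summary(tp = sum(cls == "TP"), tn = sum(cls == "TN"),
                    fp_total = sum(cls %in% c("FP", "FP-WD")),
                    fp_wd = sum(cls == "FP-WD"), fn = sum(cls == "FN"))
}

#' Build a confusion summary from raw counts
#'
#' @param tp,tn,fp_total,fp_wd,fn non-negative counts; `fp_wd` must not
#'   exceed `fp_total`.
#' @return list of class `confusion_summary`.
#' @export
confusion_summary <- function(tp, tn, fp_total, fn, fp_wd = 0) {
  counts <- c(tp = tp, tn = tn, fp_total = fp_total, fp_wd = fp_wd, fn = fn)
  if (any(counts < 0) || fp_wd > fp_total) {
    stop("invalid confusion counts", call. = FALSE)
  }
  total <- tp + tn + fp_total + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  prec <- ratio(tp, tp + fp_total)
  sens <- ratio(tp, tp + fn)
  metrics <- c(
    accuracy = ratio(tp + tn, total),
    sensitivity = sens,
    specificity = ratio(tn, tn + fp_total),
    precision = prec,
    fdr = if (is.na(prec)) NA_real_ else 1 - prec,
    f1 = if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_)
  structure(list(counts = c(counts, total = total), metrics = metrics),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  k <- x$counts
  cat(sprintf("confusion: TP %d  TN %d  FP %d (WD %d)  FN %d  [n = %d]\n",
              k[["tp"]], k[["tn"]], k[["fp_total"]], k[["fp_wd"]],
              k[["fn"]], k[["total"]]))
  pct <- function(v) if (is.na(v)) "NA" else paste0(round_half_up(100 * v), "%")
  m <- x$metrics
  cat("  accuracy ", pct(m[["accuracy"]]),
      "  sensitivity ", pct(m[["sensitivity"]]),
      "  specificity ", pct(m[["specificity"]]),
      "  precision ", pct(m[["precision"]]), "\n", sep = "")
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used for integer-percent tables (R's `round()` rounds
#' half to even, which does not match conventional table presentation).
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate per-pathway confusion summaries
#'
#' `pooled` sums the raw counts across pathways and derives metrics from
#' the sums; `averaged` takes each pathway's metrics and reports their
#' unweighted mean and sample standard deviation, skipping `NA` entries
#' (pathways where a metric is undefined).
#'
#' @param summaries list of `confusion_summary` objects.
#' @param mode `"pooled"` or `"averaged"`.
#' @return for `pooled`, a `confusion_summary`; for `averaged`, a
#'   data.frame with `metric`, `mean`, `sd`, `n_defined`.
#' @export
aggregate_summaries <- function(summaries, mode = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  if (length(summaries) == 0) stop("no summaries to aggregate", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "confusion_summary")))
  if (mode == "pooled") {
    k <- Reduce(`+`, lapply(summaries, function(s)
      s$counts[c("tp", "tn", "fp_total", "fp_wd", "fn")]))
    return(confusion_summary(tp = k[["tp"]], tn = k[["tn"]],
                             fp_total = k[["fp_total"]],
                             fp_wd = k[["fp_wd"]], fn = k[["fn"]]))
  }
  mat <- do.call(rbind, lapply(summaries, function(s) s$metrics))
  data.frame(
    metric = colnames(mat),
    mean = apply(mat, 2, mean, na.rm = TRUE),
    sd = apply(mat, 2, sd, na.rm = TRUE),
    n_defined = apply(mat, 2, function(col) sum(!is.na(col))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratified confusion summaries
#'
#' Splits scored cases by observed effect type, shortest path length, or a
#' `pathway` column and scores each stratum separately. Strata with zero
#' cases are omitted (they appear in the `note` attribute).
#'
#' @param cases test-case data.frame with `predicted` and `observed` set;
#'   `by = "path_length"` requires a `shortest_path_length` column (see
#'   [path_length_summary()]), `by = "pathway"` a `pathway` column.
#' @param by `"effect_type"`, `"path_length"` or `"pathway"`.
#' @return named list of `confusion_summary`, one per stratum.
#' @export
stratify_cases <- function(cases,
                           by = c("effect_type", "path_length", "pathway")) {
  by <- match.arg(by)
  key <- switch(by,
    effect_type = cases$observed,
    path_length = {
      if (!"shortest_path_length" %in% names(cases)) {
        stop("path_length stratification needs a shortest_path_length ",
             "column", call. = FALSE)
      }
      ifelse(is.na(cases$shortest_path_length), "none",
             as.character(cases$shortest_path_length))
    },
    pathway = {
      if (!"pathway" %in% names(cases)) {
        stop("pathway stratification needs a pathway column", call. = FALSE)
      }
      cases$pathway
    })
  groups <- split(seq_len(nrow(cases)), key)
  out <- lapply(groups, function(i) score_cases(cases[i, , drop = FALSE]))
  out
}

#' Rank-sum comparison of two metric vectors
#'
#' Thin wrapper around [stats::wilcox.test()] (Mann-Whitney U) for
#' comparing per-pathway metric vectors between two predictors.
#'
#' @param a,b numeric vectors (NA dropped).
#' @param ... passed to `wilcox.test`.
#' @return the `htest` object.
#' @export
compare_metrics <- function(a, b, ...) {
  wilcox.test(a[!is.na(a)], b[!is.na(b)], exact = FALSE, ...)
}
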