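# Inter-rater agreement for three-class perturbation calls: pairwise
# percent agreement, Cohen's kappa, and Fleiss' kappa for a fixed panel of
# raters.

.check_rating_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 raters", call. = FALSE)
  if (nrow(m) < 1) stop("need at least 1 case", call. = FALSE)
  if (any(is.na(m))) stop("rating matrix has missing cells", call. = FALSE)
  .validate_classes(as.vector(m), .classes3, "rating")
  m
}

#' Pairwise and average percent agreement
#'
#' @param ratings cases x raters matrix (or data.frame) of labels from
#'   `up`, `down`, `no_change`; no missing cells.
#' @return list with `pairwise` (named fractions per rater pair) and
#'   `average` (unweighted mean over pairs).
#' @examples
#' m <- cbind(a = c("up", "down"), b = c("up", "up"))
#' percent_agreement(m)
#' @export
percent_agreement <- function(ratings) {
  m <- .check_rating_matrix(ratings)
  raters <- colnames(m)
  if (is.null(raters)) raters <- paste0("R", seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2)
  pw <- apply(pairs, 2, function(p) mean(m[, p[1]] == m[, p[2]]))
  names(pw) <- apply(pairs, 2, function(p)
    paste(raters[p[1]], raters[p[2]], sep = "&"))
  list(pairwise = pw, average = mean(pw))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the two raters' marginal label frequencies. Returns `NA`
#' when chance agreement is 1 (both raters constant), where kappa is
#' undefined.
#'
#' @param a,b equal-length label vectors over `up`, `down`, `no_change`.
#' @return kappa, or `NA`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("rating lengths differ", call. = FALSE)
  m <- .check_rating_matrix(cbind(a, b))
  po <- mean(m[, 1] == m[, 2])
  pa <- table(factor(m[, 1], levels = .classes3)) / nrow(m)
  pb <- table(factor(m[, 2], levels = .classes3)) / nrow(m)
  pe <- sum(pa * pb)
  if (1 - pe < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for a fixed rater panel
#'
#' Standard computation over n cases, k raters and the three-class
#' vocabulary: per-case agreement `P_i`, observed agreement `P̄` (mean of
#' `P_i`), expected agreement `P̄e` (sum of squared overall category
#' proportions), and `kappa = (P̄ - P̄e) / (1 - P̄e)`. Alternatively pass
#' precomputed `p_bar`/`p_bar_e` to obtain kappa directly.
#'
#' @param ratings cases x raters label matrix (every case rated by every
#'   rater; ragged panels are rejected by construction since a matrix has
#'   no holes).
#' @param p_bar,p_bar_e optional precomputed observed/expected agreement;
#'   when supplied, `ratings` is ignored.
#' @return list of class `agreement_result` with `p_bar`, `p_bar_e`,
#'   `kappa` (and `n_cases`, `n_raters` when computed from ratings).
#' @export
fleiss_kappa <- function(ratings = NULL, p_bar = NULL, p_bar_e = NULL) {
  if (!is.null(p_bar) || !is.null(p_bar_e)) {
    if (is.null(p_bar) || is.null(p_bar_e)) {
      stop("supply both p_bar and p_bar_e", call. = FALSE)
    }
    kappa <- (p_bar - p_bar_e) / (1 - p_bar_e)
    return(structure(list(p_bar = p_bar, p_bar_e = p_bar_e, kappa = kappa),
                     class = "agreement_result"))
  }
  m <- .check_rating_matrix(ratings)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)
  counts <- t(apply(m, 1, function(r) table(factor(r, levels = .classes3))))
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * k)
  p_bar_e <- sum(p_j^2)
  kappa <- if (1 - p_bar_e < .Machine$double.eps^0.5) NA_real_
           else (p_bar - p_bar_e) / (1 - p_bar_e)
  structure(list(p_bar = p_bar, p_bar_e = p_bar_e, kappa = kappa,
                 n_cases = n, n_raters = k),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("observed agreement %.3f, expected %.3f, Fleiss' kappa %s\n",
              x$p_bar, x$p_bar_e,
              if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa)))
  invisible(x)
}

#' Full agreement report for a rating matrix
#'
#' Combines pairwise/average percent agreement, pairwise/average Cohen's
#' kappa and Fleiss' kappa in one summary.
#'
#' @param ratings cases x raters label matrix.
#' @return list with `percent` (from [percent_agreement()]),
#'   `cohen_pairwise`, `cohen_average`, and `fleiss` (an
#'   `agreement_result`).
#' @export
agreement_report <- function(ratings) {
  m <- .check_rating_matrix(ratings)
  pct <- percent_agreement(m)
  pairs <- utils::combn(ncol(m), 2)
  ck <- apply(pairs, 2, function(p) cohens_kappa(m[, p[1]], m[, p[2]]))
  names(ck) <- names(pct$pairwise)
  list(percent = pct, cohen_pairwise = ck,
       cohen_average = mean(ck, na.rm = TRUE),
       fleiss = fleiss_kappa(m))
}
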