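test_that("every prediction/observation pair lands in exactly one
           category", {
  combos <- expand.grid(p = c("up", "down", "no_change"),
                        o = c("up", "down", "no_change"),
                        stringsAsFactors = FALSE)
  got <- classify_outcome(combos$p, combos$o)
  expect_identical(got, oracle_confusion(combos$p, combos$o))
  expect_true(all(got %in% c("TP", "TN", "FP", "FP-WD", "FN")))
  # spot checks from the category definitions
  expect_equal(classify_outcome("up", "up"), "TP")
  expect_equal(classify_outcome("down", "up"), "FP-WD")
  expect_equal(classify_outcome("up", "no_change"), "FP")
  expect_equal(classify_outcome("no_change", "down"), "FN")

  # random label pairs: counts always partition the total
  set.seed(1)
  for (i in 1:20) {
    cases <- data.frame(
      predicted = sample(c("up", "down", "no_change"), 50, replace = TRUE),
      observed = sample(c("up", "down", "no_change"), 50, replace = TRUE))
    s <- score_cases(cases)
    expect_equal(s$counts[["total"]], 50)
    expect_equal(sum(s$counts[c("tp", "tn", "fp_total", "fn")]), 50)
    expect_lte(s$counts[["fp_wd"]], s$counts[["fp_total"]])
    # cross-check against the independent oracle
    cls <- oracle_confusion(cases$predicted, cases$observed)
    expect_equal(s$counts[["tp"]], sum(cls == "TP"))
    expect_equal(s$counts[["fp_wd"]], sum(cls == "FP-WD"))
  }
  expect_error(score_cases(data.frame(predicted = "up",
                                      observed = NA_character_)),
               "unset")
})

test_that("confusion metrics use stated formulas with NA on zero
           denominators", {
  s <- confusion_summary(tp = 23, tn = 1, fp_total = 1, fn = 1, fp_wd = 1)
  expect_equal(round_half_up(100 * s$metrics[["accuracy"]]), 92)
  expect_equal(round_half_up(100 * s$metrics[["sensitivity"]]), 96)
  expect_equal(round_half_up(100 * s$metrics[["specificity"]]), 50)
  expect_equal(round_half_up(100 * s$metrics[["precision"]]), 96)
  expect_equal(s$metrics[["fdr"]], 1 - s$metrics[["precision"]])

  # no negatives at all: specificity undefined, reported NA not 0
  s <- confusion_summary(tp = 5, tn = 0, fp_total = 0, fn = 0)
  expect_true(is.na(s$metrics[["specificity"]]))
  expect_equal(s$metrics[["accuracy"]], 1)
  # no predicted positives: precision undefined
  s <- confusion_summary(tp = 0, tn = 5, fp_total = 0, fn = 2)
  expect_true(is.na(s$metrics[["precision"]]))
  expect_error(confusion_summary(tp = 1, tn = 1, fp_total = 1, fn = 1,
                                 fp_wd = 2), "invalid")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(92.5), 93)
  expect_equal(round_half_up(86.5), 87)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0.8745, 3), 0.875)
})

test_that("aggregation pools counts or averages metrics", {
  a <- confusion_summary(tp = 1, tn = 1, fp_total = 0, fn = 2)  # acc 0.5
  b <- confusion_summary(tp = 3, tn = 1, fp_total = 0, fn = 0)  # acc 1.0
  pooled <- aggregate_summaries(list(a, b), "pooled")
  expect_equal(pooled$counts[["total"]], 8)
  expect_equal(pooled$metrics[["accuracy"]], 6 / 8)
  avg <- aggregate_summaries(list(a, b), "averaged")
  expect_equal(avg$mean[avg$metric == "accuracy"], 0.75)
  expect_equal(avg$sd[avg$metric == "accuracy"], sd(c(0.5, 1)))
  # single pathway: pooled metrics equal the pathway's own
  expect_equal(aggregate_summaries(list(a), "pooled")$metrics, a$metrics)
  expect_error(aggregate_summaries(list()), "no summaries")
})

test_that("stratification partitions cases and preserves counts", {
  set.seed(3)
  cases <- data.frame(
    predicted = sample(c("up", "down", "no_change"), 60, replace = TRUE),
    observed = sample(c("up", "down", "no_change"), 60, replace = TRUE),
    pathway = rep(c("P1", "P2"), each = 30))
  by_effect <- stratify_cases(cases, "effect_type")
  expect_equal(sum(vapply(by_effect, function(s) s$counts[["total"]],
                          numeric(1))), 60)
  by_path <- stratify_cases(cases, "pathway")
  expect_setequal(names(by_path), c("P1", "P2"))
  # single stratum equals the global summary
  one <- stratify_cases(cases[cases$pathway == "P1", ], "pathway")
  expect_equal(one$P1$counts,
               score_cases(cases[cases$pathway == "P1", ])$counts)
  # planted perfect stratum scores 100%
  perfect <- data.frame(predicted = c("up", "down"),
                        observed = c("up", "down"),
                        pathway = "clean")
  expect_equal(stratify_cases(perfect, "pathway")$clean$metrics[["accuracy"]],
               1)
  expect_error(stratify_cases(cases, "path_length"),
               "shortest_path_length")
})

test_that("percent agreement: identity, total disagreement, and averages", {
  m <- cbind(r1 = rep("up", 10), r2 = rep("up", 10))
  expect_equal(percent_agreement(m)$average, 1)
  m <- cbind(r1 = rep("up", 10), r2 = rep("down", 10))
  expect_equal(percent_agreement(m)$average, 0)
  expect_error(percent_agreement(matrix("up", 5, 1)), "2 raters")
  expect_error(percent_agreement(cbind(c("up", NA), c("up", "down"))),
               "missing")
})

test_that("Cohen's kappa: perfect, independent, and degenerate labelings", {
  a <- rep(c("up", "down", "no_change"), 20)
  expect_equal(cohens_kappa(a, a), 1)
  # chance-level agreement from independently shuffled labels
  set.seed(11)
  big <- sample(c("up", "down", "no_change"), 6000, replace = TRUE)
  shuf <- sample(big)
  expect_lt(abs(cohens_kappa(big, shuf)), 0.05)
  # both raters constant: kappa undefined
  expect_true(is.na(cohens_kappa(rep("up", 5), rep("up", 5))))
  expect_error(cohens_kappa(a, a[-1]), "lengths differ")
})

test_that("Fleiss' kappa identities and the precomputed route", {
  m <- cbind(rep(c("up", "down"), 10), rep(c("up", "down"), 10),
             rep(c("up", "down"), 10))
  r <- fleiss_kappa(m)
  expect_equal(r$kappa, 1)
  expect_equal(r$p_bar, 1)
  # kappa = 0 when observed equals expected agreement
  expect_equal(fleiss_kappa(p_bar = 0.4, p_bar_e = 0.4)$kappa, 0)
  # near-zero under independence
  set.seed(5)
  m <- matrix(sample(c("up", "down", "no_change"), 3000 * 3, replace = TRUE),
              ncol = 3)
  expect_lt(abs(fleiss_kappa(m)$kappa), 0.05)
  expect_error(fleiss_kappa(p_bar = 0.5), "both")
})
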