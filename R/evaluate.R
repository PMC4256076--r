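# Variant-aware evaluation of mapping predictions on synthetic truth.

#' Classify predictions against a synthetic truth table
#'
#' Variant-aware confusion classification: a true positive is an associated
#' gene whose *correct* variant is predicted significantly; an associated
#' gene predicted significantly with the wrong variant is a false positive
#' (as is any significant non-associated gene), not a true positive. True
#' negatives are non-associated genes with no significant prediction;
#' false negatives are associated genes with no significant prediction.
#'
#' @param predictions A tibble with columns `gene`, `variant`, and the
#'   p-value column named by `p_col` ([dyver_scan()] and the `scan_*`
#'   baselines both qualify).
#' @param truth A truth tibble (`gene`, `is_associated`, `variant`), e.g.
#'   from [sim_collection()].
#' @param alpha Significance threshold applied to `p_col`.
#' @param p_col Which p-value column to threshold (default `"bonf_p"`).
#' @return A tibble `gene`, `call` (`"TP"`/`"TN"`/`"FP"`/`"FN"`),
#'   `predicted_variant`, `p`. Genes absent from `truth` are an error;
#'   genes in `truth` missing from `predictions` count as negative calls.
#' @export
classify_outcomes <- function(predictions, truth, alpha, p_col = "bonf_p") {
  missing <- setdiff(predictions$gene, truth$gene)
  if (length(missing))
    abort(paste0("predictions contain genes absent from truth: ",
                 paste(head(missing, 5), collapse = ", ")))
  pred <- tibble(gene = predictions$gene,
                 predicted_variant = predictions$variant,
                 p = predictions[[p_col]])
  tbl <- dplyr::left_join(truth, pred, by = "gene")
  sig <- !is.na(tbl$p) & tbl$p <= alpha
  correct <- sig & tbl$is_associated &
    !is.na(tbl$predicted_variant) & tbl$predicted_variant == tbl$variant
  call <- dplyr::case_when(
    correct ~ "TP",
    sig ~ "FP",
    tbl$is_associated ~ "FN",
    TRUE ~ "TN")
  tibble(gene = tbl$gene, call = call,
         predicted_variant = tbl$predicted_variant, p = tbl$p)
}

#' Variant-aware sensitivity and specificity
#'
#' @inheritParams classify_outcomes
#' @return A one-row tibble `alpha`, `tp`, `tn`, `fp`, `fn`, `sensitivity`
#'   (`TP` over associated genes), `specificity` (`TN` over non-associated
#'   genes).
#' @export
eval_confusion <- function(predictions, truth, alpha, p_col = "bonf_p") {
  calls <- classify_outcomes(predictions, truth, alpha, p_col)$call
  n_pos <- sum(truth$is_associated)
  n_neg <- sum(!truth$is_associated)
  tibble(alpha = alpha,
         tp = sum(calls == "TP"), tn = sum(calls == "TN"),
         fp = sum(calls == "FP"), fn = sum(calls == "FN"),
         sensitivity = if (n_pos > 0) sum(calls == "TP") / n_pos else NA_real_,
         specificity = if (n_neg > 0) sum(calls == "TN") / n_neg else NA_real_)
}

#' Accuracy: area under the variant-aware sensitivity curve
#'
#' Sweeps the significance threshold over a grid, plots variant-aware
#' sensitivity against 1 - specificity, and returns the trapezoidal area
#' under the curve (anchored at the origin). Because sensitivity counts
#' only correct-variant predictions, a random predictor stays near zero
#' at every threshold and scores close to 0, while a perfect predictor
#' scores 1; the curve need not reach (1, 1).
#'
#' @inheritParams classify_outcomes
#' @param grid Threshold grid spanning `(0, 1]`; default 200 log-spaced
#'   values between 1e-6 and 1.
#' @return The accuracy in `[0, 1]`, with the swept curve in attribute
#'   `curve`.
#' @export
accuracy_auc <- function(predictions, truth, grid = NULL,
                         p_col = "bonf_p") {
  grid <- grid %||% 10^seq(-6, 0, length.out = 200)
  if (length(grid) < 2) abort("threshold grid needs at least 2 points")
  grid <- sort(grid)
  curve <- purrr::map_dfr(grid, eval_confusion, predictions = predictions,
                          truth = truth, p_col = p_col)
  x <- c(0, 1 - curve$specificity)
  y <- c(0, curve$sensitivity)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  structure(auc, curve = curve)
}

# collapse consecutive repeats: "LLHH" -> "LH"
collapse_pattern <- function(pattern) {
  vapply(strsplit(pattern, ""), function(s)
    paste(rle(s)$values, collapse = ""), character(1))
}

patterns_match <- function(truth, fitted, mode = c("stringent", "flexible")) {
  mode <- match.arg(mode)
  if (mode == "stringent") truth == fitted
  else collapse_pattern(truth) == collapse_pattern(fitted)
}

#' Two-state pattern error rate
#'
#' Among the significant, correctly mapped genes of a scan, the fraction
#' whose fitted temporal two-state pattern disagrees with the truth
#' pattern. `mode = "stringent"` requires an exact pattern match;
#' `mode = "flexible"` requires only the correct order of states, allowing
#' incorrect transition timing (consecutive repeated states are collapsed
#' before comparison, so truth `"LLHH"` matches fitted `"LHHH"`). The
#' flexible error rate can never exceed the stringent one.
#'
#' @param scan A `dyver_scan` tibble (needs `gene`, `variant`, `pattern`
#'   and the p-value column).
#' @param truth Truth tibble with `gene`, `variant`, `pattern` columns.
#' @param alpha Significance cutoff defining the denominator.
#' @param mode `"stringent"` or `"flexible"`.
#' @param p_col P-value column to threshold (default `"perm_p"`).
#' @return The error rate, with attribute `n` (denominator size); `NA`
#'   when no gene qualifies.
#' @export
two_state_error_rate <- function(scan, truth, alpha,
                                 mode = c("stringent", "flexible"),
                                 p_col = "perm_p") {
  mode <- match.arg(mode)
  tbl <- dplyr::inner_join(
    tibble(gene = scan$gene, predicted_variant = scan$variant,
           fitted = scan$pattern, p = scan[[p_col]]),
    tibble(gene = truth$gene, variant = truth$variant,
           truth_pattern = truth$pattern),
    by = "gene")
  sel <- !is.na(tbl$p) & tbl$p <= alpha & !is.na(tbl$variant) &
    tbl$predicted_variant == tbl$variant
  n <- sum(sel)
  if (n == 0) {
    warn("no significant correctly-mapped genes; error rate undefined")
    return(structure(NA_real_, n = 0L))
  }
  err <- !patterns_match(tbl$truth_pattern[sel], tbl$fitted[sel], mode)
  structure(mean(err), n = n)
}

#' Benchmark mapping methods on a synthetic collection
#'
#' Runs the DyVER scan and the requested baselines on one collection and
#' reports the variant-aware accuracy of each, plus sensitivity and
#' specificity at a fixed threshold.
#'
#' @param sim A `dyver_sim` collection.
#' @param methods Subset of
#'   `c("dyver", "naive", "pca", "expression_dynamics", "random")`.
#' @param alpha Threshold for the reported sensitivity/specificity columns.
#' @param n_perm Permutations for the DyVER scan.
#' @param lambda Transition penalty for the DyVER scan.
#' @param grid Threshold grid for [accuracy_auc()].
#' @param p_col_dyver Which gene-level p-value the DyVER rows use:
#'   `"fw_p"` (familywise empirical p from shared permutations; default)
#'   or `"bonf_p"`.
#' @return A tibble: `method`, `accuracy`, `sensitivity`, `specificity`,
#'   `alpha`.
#' @export
benchmark_methods <- function(sim, methods = c("dyver", "naive", "pca",
                                               "expression_dynamics",
                                               "random"),
                              alpha = 0.1, n_perm = 199, lambda = 0.5,
                              grid = NULL, p_col_dyver = c("fw_p",
                                                           "bonf_p")) {
  methods <- match.arg(methods, several.ok = TRUE)
  p_col_dyver <- match.arg(p_col_dyver)
  purrr::map_dfr(methods, function(m) {
    if (m == "dyver") {
      res <- dyver_scan(sim$expr, sim$geno, n_perm = n_perm,
                        lambda = lambda,
                        perm_variants = if (p_col_dyver == "fw_p") "all"
                        else "top")
      pc <- p_col_dyver
    } else {
      res <- switch(m,
                    naive = scan_naive(sim$expr, sim$geno),
                    pca = scan_pca(sim$expr, sim$geno),
                    expression_dynamics =
                      scan_expression_dynamics(sim$expr, sim$geno),
                    random = scan_random(sim$expr, sim$geno))
      pc <- "bonf_p"
    }
    conf <- eval_confusion(res, sim$truth, alpha, p_col = pc)
    tibble(method = m,
           accuracy = as.numeric(accuracy_auc(res, sim$truth, grid,
                                              p_col = pc)),
           sensitivity = conf$sensitivity, specificity = conf$specificity,
           alpha = alpha)
  })
}
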