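#' DyVER score: likelihood-ratio of dynamic genetic effect
#'
#' The association statistic. Under the null hypothesis a variant has no
#' effect, so one two-state model can describe both the cross-allele
#' observed effects `D` and the same-allele background effects `B`; under
#' the alternative the two samples need separate models. The score is the
#' log-likelihood ratio
#' `maxloglik(D) + maxloglik(B) - maxloglik(D union B)`,
#' each term maximised with [fit_two_state()] at the same penalty, with the
#' pooled term fitted on the per-time-point concatenation of the two
#' samples. Significance comes from strain-label permutation
#' ([permutation_pvalue()], [dyver_scan()]); the score alone has no
#' calibrated scale.
#'
#' @param d_effects Observed-effect sample, e.g. from [observed_effects()]
#'   (tibble with columns `time`, `effect`).
#' @param b_effects Background sample, e.g. from [background_effects()].
#' @inheritParams fit_two_state
#' @return A list of class `dyver_score` with elements `score`, `fit_d`
#'   (the labelled two-state fit of the observed effects, whose `pattern`
#'   is the reported temporal model), `fit_b`, `fit_pooled`.
#' @export
dyver_score <- function(d_effects, b_effects, lambda = 0.5, pi = 0.5,
                        tol = 1e-8, max_iter = 500, sigma_floor = 1e-6) {
  check_lambda(lambda)
  times <- sort(unique(d_effects$time))
  if (nrow(b_effects) == 0)
    abort("background sample is empty at every time point; the panel is too small (need >= 2 strains per allele)")
  b_effects <- b_effects[b_effects$time %in% times, ]
  pooled <- dplyr::bind_rows(d_effects[, c("time", "effect")],
                             b_effects[, c("time", "effect")])
  fit_d <- fit_two_state(d_effects, lambda, pi, tol, max_iter, sigma_floor)
  fit_b <- fit_two_state(b_effects, lambda, pi, tol, max_iter, sigma_floor)
  fit_p <- fit_two_state(pooled, lambda, pi, tol, max_iter, sigma_floor)
  structure(list(score = fit_d$log_likelihood + fit_b$log_likelihood -
                   fit_p$log_likelihood,
                 fit_d = fit_d, fit_b = fit_b, fit_pooled = fit_p),
            class = "dyver_score")
}

#' @export
print.dyver_score <- function(x, ...) {
  cat(sprintf("DyVER score = %.4f (pattern %s)\n", x$score,
              x$fit_d$pattern))
  invisible(x)
}

#' Permutation p-value for one (gene, variant) pair
#'
#' Permutes the strain genotype labels, recomputing variance stabilisation,
#' observed and background effects and the DyVER score for every
#' permutation, and returns the add-one-smoothed empirical p-value
#' `(1 + #\{permuted score >= observed\}) / (1 + n_perm)`. Seed the R RNG
#' (`set.seed()`) for reproducibility.
#'
#' @param expr A `dyver_expr` tibble (raw log expression; stabilisation is
#'   applied internally per permutation).
#' @param geno A `dyver_geno` object.
#' @param gene,variant Identifiers.
#' @param n_perm Number of permutations (at least 99 recommended).
#' @inheritParams fit_two_state
#' @return The p-value, with attributes `score` (observed DyVER score) and
#'   `n_perm`.
#' @export
permutation_pvalue <- function(expr, geno, gene, variant, n_perm = 999,
                               lambda = 0.5, pi = 0.5, tol = 1e-8,
                               max_iter = 500, sigma_floor = 1e-6) {
  Y <- expr_matrix(expr, gene, geno$strain)
  G <- geno_matrix(geno)[, variant, drop = FALSE]
  res <- cpp_scan_gene(Y, G, lambda, pi, as.integer(n_perm), 1L, tol,
                       as.integer(max_iter), sigma_floor, 2L)
  if (is.na(res$best)) abort(paste0("variant '", variant, "' is untestable for gene '", gene, "'"))
  p <- (1 + res$perm_count) / (1 + n_perm)
  structure(p, score = res$score[1], n_perm = n_perm)
}

#' Genome scan for dynamic genetic associations
#'
#' Scores every testable variant for each gene with the DyVER score
#' (applying within-(time, allele) variance stabilisation per variant),
#' assigns each gene its top-scoring variant, and evaluates that variant's
#' significance by strain-label permutation. Per-variant p-values are
#' Bonferroni-corrected for the number of testable variants. Variants are
#' testable when at least two strains per allele are observed at two or
#' more time points; time points failing that within a testable variant are
#' dropped.
#'
#' Permutation modes: `"top"` (default) permutes labels for the top-scoring
#' variant only (the DyVER score itself ranks the variants, so only the
#' reported variant needs a p-value); `"all"` shares each permutation
#' across all variants, yielding per-variant p-values plus a familywise
#' empirical p-value `fw_p` for the gene based on the permutation
#' distribution of the maximum score over variants (already adjusted for
#' variant multiplicity, no Bonferroni needed).
#'
#' @inheritParams permutation_pvalue
#' @param genes Genes to scan (default: all genes in `expr`).
#' @param perm_variants `"top"` or `"all"` (see Details).
#' @param keep_scores Keep the full per-variant score matrix in the
#'   `scores` attribute (for locus plots).
#' @param progress Print a dot per 50 genes.
#' @return A `dyver_scan` tibble, one row per gene: `gene`, `variant`,
#'   `chrom`, `kb`, `n_variants` (testable count), `dyver_score`, `perm_p`
#'   (add-one-smoothed), `bonf_p = min(1, perm_p * n_variants)`, `fw_p`
#'   (only for `perm_variants = "all"`), `pattern` (fitted state string
#'   over retained time points), `mu_H`, `mu_L`, `dynamic_p` (Welch t-test
#'   of H-state versus L-state observed effects; `NA` for single-state
#'   patterns). Genes with no testable variant are dropped with a warning.
#' @export
dyver_scan <- function(expr, geno, genes = NULL, lambda = 0.5, pi = 0.5,
                       n_perm = 999, perm_variants = c("top", "all"),
                       tol = 1e-8, max_iter = 500, sigma_floor = 1e-6,
                       keep_scores = FALSE, progress = FALSE) {
  check_lambda(lambda)
  perm_variants <- match.arg(perm_variants)
  genes <- genes %||% unique(expr$gene)
  G <- geno_matrix(geno)
  times <- time_points(expr)
  score_tbl <- if (keep_scores) vector("list", length(genes))
  rows <- vector("list", length(genes))
  pos <- variant_positions(geno)
  for (i in seq_along(genes)) {
    g <- genes[i]
    Y <- expr_matrix(expr, g, geno$strain, times)
    res <- cpp_scan_gene(Y, G, lambda, pi, as.integer(n_perm),
                         if (perm_variants == "top") 1L else 2L,
                         tol, as.integer(max_iter), sigma_floor, 2L)
    if (is.na(res$best)) {
      warn(paste0("gene '", g, "' has no testable variant; skipped"))
      next
    }
    k_testable <- sum(!is.na(res$score))
    best <- res$best
    fit <- new_two_state_fit(res$best_fit,
                             times = times[res$retained == 1L],
                             lambda = lambda, pi = pi,
                             n_obs = rep(NA_real_, sum(res$retained)))
    perm_p <- if (n_perm > 0) (1 + res$perm_count) / (1 + n_perm)
      else NA_real_
    dyn <- dynamic_p_matrix(Y, G[, best], fit)
    rows[[i]] <- tibble(
      gene = g, variant = colnames(G)[best],
      chrom = pos$chrom[best], kb = pos$kb[best],
      n_variants = k_testable, dyver_score = res$score[best],
      perm_p = perm_p, bonf_p = min(1, perm_p * k_testable),
      fw_p = if (perm_variants == "all")
        (1 + res$max_count) / (1 + n_perm) else NA_real_,
      pattern = fit$pattern, mu_H = unname(fit$mu["H"]),
      mu_L = unname(fit$mu["L"]), dynamic_p = dyn)
    if (keep_scores)
      score_tbl[[i]] <- tibble(gene = g, variant = colnames(G),
                               chrom = pos$chrom, kb = pos$kb,
                               dyver_score = res$score)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  if (perm_variants == "top") out$fw_p <- NULL
  structure(out,
            scores = if (keep_scores) dplyr::bind_rows(score_tbl),
            lambda = lambda, n_perm = n_perm, perm_variants = perm_variants,
            class = c("dyver_scan", class(tibble())))
}

# Welch t-test between H-state and L-state observed effects, computed from
# the stabilised expression matrix (fast path used by the scan)
dynamic_p_matrix <- function(Y, g, fit) {
  if (!all(c("H", "L") %in% fit$states)) return(NA_real_)
  pools <- list(H = numeric(), L = numeric())
  times <- as.numeric(colnames(Y))
  for (j in seq_along(fit$times)) {
    t_idx <- which(times == fit$times[j])
    y <- Y[, t_idx]
    a <- y[g == 1 & !is.na(y)]
    b <- y[g == 0 & !is.na(y)]
    a <- stabilize_vec(a)
    b <- stabilize_vec(b)
    d <- as.vector(outer(a, b, "-"))
    pools[[fit$states[j]]] <- c(pools[[fit$states[j]]], d)
  }
  tryCatch(t.test(pools$H, pools$L)$p.value, error = function(e) NA_real_)
}

stabilize_vec <- function(x) {
  if (length(x) < 2) return(x)
  s <- sd(x)
  if (is.na(s) || s == 0) return(x)
  mean(x) + (x - mean(x)) / s
}

#' Welch t-test of high-effect versus low-effect observed effects
#'
#' The post-hoc *dynamic association score*: given the fitted two-state
#' pattern of a predicted association, tests whether observed effects
#' pooled over H time points differ from those pooled over L time points
#' (Welch two-sample t-test). A significant value marks the association as
#' dynamic. Undefined (`NA`) for single-state patterns, which by
#' construction show no temporal change.
#'
#' @param d_effects Observed-effect tibble (columns `time`, `effect`).
#' @param pattern State string over the retained time points (sorted unique
#'   times of `d_effects`), e.g. from a [fit_two_state()] fit.
#' @return The t-test p-value, or `NA` for a single-state pattern.
#' @export
dynamic_association_score <- function(d_effects, pattern) {
  states <- parse_states(pattern)
  times <- sort(unique(d_effects$time))
  if (length(states) != length(times))
    abort("pattern length must equal the number of retained time points")
  if (!all(c("H", "L") %in% states)) return(NA_real_)
  st <- states[match(d_effects$time, times)]
  t.test(d_effects$effect[st == "H"], d_effects$effect[st == "L"])$p.value
}

#' Gene-level multiple-testing control for a scan
#'
#' Applies Benjamini-Hochberg control at level `q` to the genes' corrected
#' association p-values, and (optionally) a second Benjamini-Hochberg pass
#' at `q_dynamic` to the dynamic-association p-values of the predicted
#' associations, mirroring the two-stage multiple-testing chain of the
#' method: Bonferroni over variants within gene, FDR over genes, then FDR
#' over dynamic scores among predicted associations.
#'
#' @param scan A `dyver_scan` tibble.
#' @param q FDR level for predicted associations (default 0.06).
#' @param q_dynamic FDR level for predicted dynamic associations (default
#'   0.15); `NULL` skips the dynamic stage.
#' @param p_col Column holding the gene-level p-value (default `bonf_p`).
#' @return The scan with logical columns `fdr_pass` and (when requested)
#'   `dynamic_pass` added.
#' @export
gene_level_fdr <- function(scan, q = 0.06, q_dynamic = 0.15,
                           p_col = "bonf_p") {
  scan$fdr_pass <- p.adjust(scan[[p_col]], method = "BH") <= q
  if (!is.null(q_dynamic)) {
    scan$dynamic_pass <- FALSE
    sel <- scan$fdr_pass & !is.na(scan$dynamic_p)
    if (any(sel))
      scan$dynamic_pass[sel] <-
        p.adjust(scan$dynamic_p[sel], method = "BH") <= q_dynamic
  }
  scan
}

#' Refit temporal patterns at a different penalty
#'
#' Re-fits the two-state model of each reported (gene, variant) association
#' at a new transition penalty, leaving scores and p-values untouched.
#' Useful for studying how the penalty trades transition count against
#' fit, without repeating the permutation stage.
#'
#' @param scan A `dyver_scan` tibble.
#' @param expr,geno The data the scan was run on.
#' @param lambda New transition penalty.
#' @inheritParams fit_two_state
#' @return The scan tibble with `pattern`, `mu_H`, `mu_L` replaced by the
#'   refit values and a `lambda` attribute updated.
#' @export
refit_patterns <- function(scan, expr, geno, lambda, pi = 0.5, tol = 1e-8,
                           max_iter = 500, sigma_floor = 1e-6) {
  check_lambda(lambda)
  G <- geno_matrix(geno)
  times <- time_points(expr)
  for (i in seq_len(nrow(scan))) {
    Y <- expr_matrix(expr, scan$gene[i], geno$strain, times)
    st <- cpp_effect_stats(Y, G[, scan$variant[i]], 2L)
    keep <- st$retained == 1L
    fit <- cpp_fit_stats(st$D_n[keep], st$D_s1[keep], st$D_s2[keep], lambda,
                         0.5, tol, as.integer(max_iter), sigma_floor)
    fit <- new_two_state_fit(fit, times = times[keep], lambda = lambda,
                             pi = pi, n_obs = st$D_n[keep])
    scan$pattern[i] <- fit$pattern
    scan$mu_H[i] <- unname(fit$mu["H"])
    scan$mu_L[i] <- unname(fit$mu["L"])
  }
  attr(scan, "lambda") <- lambda
  scan
}

#' @export
glance.dyver_scan <- function(x, ...) {
  tibble(n_genes = nrow(x), n_variants = max(x$n_variants),
         lambda = attr(x, "lambda"), n_perm = attr(x, "n_perm"),
         n_sig_0.05 = sum(x$bonf_p <= 0.05),
         median_score = stats::median(x$dyver_score))
}

#' @export
tidy.dyver_scan <- function(x, ...) as_tibble(x)
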