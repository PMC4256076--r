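# Baseline mapping methods for benchmarking: each scores every variant for
# a gene with a classical fixed-effect test and reports the most significant
# variant, Bonferroni-corrected for the number of variants tested.

# vectorised one-way two-group ANOVA (F test) of y against each allele
# column of G (observed entries only); returns p per variant
two_group_anova_p <- function(y, G) {
  obs <- !is.na(y)
  y <- y[obs]
  G <- G[obs, , drop = FALSE]
  n <- length(y)
  n1 <- colSums(G)
  n0 <- n - n1
  p <- rep(NA_real_, ncol(G))
  ok <- n1 >= 2 & n0 >= 2
  if (!any(ok)) return(p)
  s1 <- as.vector(crossprod(G, y))
  tot <- sum(y)
  m1 <- s1 / n1
  m0 <- (tot - s1) / n0
  gm <- tot / n
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  sst <- sum((y - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2))
  p[ok] <- pf(f[ok], 1, n - 2, lower.tail = FALSE)
  p
}

baseline_result <- function(genes, rows, method) {
  out <- dplyr::bind_rows(rows)
  out$method <- method
  structure(out, class = c("dyver_baseline", class(tibble())))
}

#' Per-time-point ANOVA baseline
#'
#' The naive mapping method: a one-way fixed-effect genotype ANOVA at each
#' time point independently; the variant's p-value is the minimum over time
#' points, and the reported variant is the most significant one, Bonferroni
#' -corrected for the number of variants. Time points with fewer than two
#' observed strains per allele are skipped.
#'
#' @param expr A `dyver_expr` tibble.
#' @param geno A `dyver_geno` object.
#' @param genes Genes to scan (default all).
#' @return A tibble: `gene`, `variant`, `p` (raw best), `bonf_p`, `method`.
#' @export
scan_naive <- function(expr, geno, genes = NULL) {
  genes <- genes %||% unique(expr$gene)
  G <- geno_matrix(geno)
  times <- time_points(expr)
  rows <- purrr::map(genes, function(g) {
    Y <- expr_matrix(expr, g, geno$strain, times)
    pmat <- vapply(seq_along(times),
                   function(j) two_group_anova_p(Y[, j], G),
                   numeric(ncol(G)))
    pmat <- matrix(pmat, nrow = ncol(G))
    p <- suppressWarnings(apply(pmat, 1, min, na.rm = TRUE))
    p[!is.finite(p)] <- NA_real_
    summarise_baseline(g, p, colnames(G))
  })
  baseline_result(genes, rows, "naive")
}

#' PCA projection baseline
#'
#' Projects each strain's time profile onto the first principal component
#' of the strains-by-time-points matrix and applies a one-way genotype
#' ANOVA to the scores. Strains with any missing time point are excluded
#' from the projection. The first component is used; the test is invariant
#' to its sign.
#'
#' @inheritParams scan_naive
#' @return A tibble as for [scan_naive()].
#' @export
scan_pca <- function(expr, geno, genes = NULL) {
  genes <- genes %||% unique(expr$gene)
  G <- geno_matrix(geno)
  times <- time_points(expr)
  rows <- purrr::map(genes, function(g) {
    Y <- expr_matrix(expr, g, geno$strain, times)
    complete <- stats::complete.cases(Y)
    if (sum(complete) < 3)
      return(summarise_baseline(g, rep(NA_real_, ncol(G)), colnames(G)))
    pc1 <- prcomp(Y[complete, , drop = FALSE], center = TRUE)$x[, 1]
    p <- two_group_anova_p(pc1, G[complete, , drop = FALSE])
    summarise_baseline(g, p, colnames(G))
  })
  baseline_result(genes, rows, "pca")
}

#' Expression-dynamics baseline
#'
#' Adds a linear time covariate to the genotype model: the full model fits
#' a separate intercept and slope per genotype group
#' (`y = a_i + b_i t + e`), the null model a single line shared by all
#' strains, and the genotype contribution is tested with an F test on the
#' residual sums of squares (2 numerator degrees of freedom). Captures
#' linearly diverging genetic effects directly.
#'
#' @inheritParams scan_naive
#' @return A tibble as for [scan_naive()].
#' @export
scan_expression_dynamics <- function(expr, geno, genes = NULL) {
  genes <- genes %||% unique(expr$gene)
  G <- geno_matrix(geno)
  times <- time_points(expr)
  line_rss <- function(n, st, stt, sy, sty, syy) {
    # residual sum of squares of a least-squares line from group sums
    sxx <- stt - st^2 / n
    if (n < 3 || sxx <= 0) return(NA_real_)
    slope <- (sty - st * sy / n) / sxx
    max(syy - sy^2 / n - slope^2 * sxx, 0)
  }
  rows <- purrr::map(genes, function(g) {
    Y <- expr_matrix(expr, g, geno$strain, times)
    obs <- !is.na(Y)
    tm <- matrix(times, nrow(Y), ncol(Y), byrow = TRUE)
    # per-strain sums over observed time points (variant-independent)
    cnt <- rowSums(obs)
    st <- rowSums(tm * obs)
    stt <- rowSums(tm^2 * obs)
    sy <- rowSums(Y * obs, na.rm = TRUE)
    sty <- rowSums(Y * tm * obs, na.rm = TRUE)
    syy <- rowSums(Y^2 * obs, na.rm = TRUE)
    N <- sum(cnt)
    rss0 <- line_rss(N, sum(st), sum(stt), sum(sy), sum(sty), sum(syy))
    p <- vapply(seq_len(ncol(G)), function(k) {
      a <- G[, k] == 1L
      n1 <- sum(cnt[a]); n0 <- N - n1
      if (n1 < 3 || n0 < 3) return(NA_real_)
      rss1 <- line_rss(n1, sum(st[a]), sum(stt[a]), sum(sy[a]),
                       sum(sty[a]), sum(syy[a])) +
        line_rss(n0, sum(st[!a]), sum(stt[!a]), sum(sy[!a]),
                 sum(sty[!a]), sum(syy[!a]))
      if (!is.finite(rss1) || is.na(rss0)) return(NA_real_)
      f <- ((rss0 - rss1) / 2) / (rss1 / (N - 4))
      pf(f, 2, N - 4, lower.tail = FALSE)
    }, numeric(1))
    summarise_baseline(g, p, colnames(G))
  })
  baseline_result(genes, rows, "expression_dynamics")
}

#' Random-prediction baseline
#'
#' Assigns each gene a uniformly random variant and a uniform p-value. With
#' the variant-aware sensitivity definition its accuracy is near zero,
#' anchoring the lower end of the accuracy scale.
#'
#' @inheritParams scan_naive
#' @return A tibble as for [scan_naive()].
#' @export
scan_random <- function(expr, geno, genes = NULL) {
  genes <- genes %||% unique(expr$gene)
  variants <- names(geno)[-1]
  p <- runif(length(genes))
  out <- tibble(gene = genes,
                variant = sample(variants, length(genes), replace = TRUE),
                p = p, bonf_p = pmin(1, p * length(variants)))
  out$method <- "random"
  structure(out, class = c("dyver_baseline", class(tibble())))
}

summarise_baseline <- function(gene, p, variants) {
  k <- sum(!is.na(p))
  if (k == 0)
    return(tibble(gene = gene, variant = NA_character_, p = NA_real_,
                  bonf_p = NA_real_))
  best <- which.min(p)
  p_best <- p[best]
  tibble(gene = gene, variant = variants[best], p = p_best,
         bonf_p = min(1, p_best * k))
}
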