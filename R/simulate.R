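#' Simulate a genotyped panel of homozygous strains
#'
#' Draws biallelic homozygous genotypes for a panel of inbred strains, each
#' allele with probability one half independently per strain and variant
#' (no linkage structure). Synthetic positions spread the variants over a
#' few chromosomes at a fixed kilobase spacing.
#'
#' @param n_strains,n_variants Panel dimensions (defaults 50 and 100, the
#'   simulation-study panel).
#' @param n_chrom Number of synthetic chromosomes to spread variants over.
#' @param kb_spacing Spacing between adjacent variants, in kb.
#' @return A `dyver_geno` object.
#' @export
sim_genotypes <- function(n_strains = 50, n_variants = 100, n_chrom = 5,
                          kb_spacing = 50) {
  if (n_strains < 2) abort("need at least 2 strains")
  strains <- sprintf("s%03d", seq_len(n_strains))
  variants <- sprintf("v%03d", seq_len(n_variants))
  alle <- matrix(sample(c("A", "B"), n_strains * n_variants, replace = TRUE),
                 n_strains, n_variants)
  tbl <- as_tibble(as.data.frame(alle, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(tbl) <- variants
  tbl <- dplyr::bind_cols(tibble(strain = strains), tbl)
  per_chrom <- ceiling(n_variants / n_chrom)
  chrom_idx <- rep(seq_len(n_chrom), each = per_chrom)[seq_len(n_variants)]
  pos <- tibble(variant = variants,
                chrom = paste0("chr", chrom_idx),
                kb = kb_spacing * (stats::ave(seq_len(n_variants), chrom_idx,
                                              FUN = seq_along)))
  new_dyver_geno(tbl, pos, c(A = "A", B = "B"))
}

#' Temporal genetic-effect waveforms
#'
#' Mean observed-effect curves `mu(t)` on the integer time grid `1..n_time`,
#' scaled by the effect size `h`:
#'
#' * `sustained` — a single state transition to a new level:
#'   `mu(t) = h / (1 + exp(-q (t - v T)))`, a sigmoid with steepness
#'   `q = 0.5` rising through `h/2` at `t = v T` (defaults `q = v = 0.5`).
#' * `impulse` — a single pulse: the product of a rising and a falling
#'   sigmoid of steepness `impulse_q`, switching on at
#'   `t_on = (T - l + 1)/2` and off `l` time points later, normalised so
#'   the curve's maximum equals `h`. `l` (`impulse_length`) defaults to
#'   `T/3`; with a steep `impulse_q`, exactly `l` grid points lie above
#'   `h/2`.
#' * `complex` — two impulses concatenated back-to-back, each spanning half
#'   the time points.
#' * `linear` — `mu(t) = h (t - 1) / (T - 1)`.
#'
#' The ground-truth two-state pattern thresholds the curve at `h/2`
#' (`mu > h/2` is the high-effect state).
#'
#' @param kind One of `"sustained"`, `"impulse"`, `"complex"`, `"linear"`.
#' @param n_time Number of time points (at least 3).
#' @param effect_size Effect size `h > 0`.
#' @param q,v Sustained-sigmoid steepness and midpoint fraction.
#' @param impulse_length Impulse duration `l` in time points (`l < n_time`).
#' @param impulse_q Impulse sigmoid steepness.
#' @return A tibble with columns `time`, `mu`, `state`, and attribute
#'   `pattern` (the truth state string).
#' @export
waveform <- function(kind = c("sustained", "impulse", "complex", "linear"),
                     n_time, effect_size, q = 0.5, v = 0.5,
                     impulse_length = NULL, impulse_q = 2) {
  kind <- match.arg(kind)
  if (n_time < 3) abort("need at least 3 time points")
  if (effect_size < 0) abort("effect size must be non-negative")
  h <- effect_size
  t <- seq_len(n_time)
  impulse_curve <- function(T, l) {
    if (l >= T) abort("impulse length must be shorter than the time course")
    tt <- seq_len(T)
    t_on <- (T - l + 1) / 2
    raw <- stats::plogis(impulse_q * (tt - t_on)) *
      stats::plogis(-impulse_q * (tt - t_on - l))
    raw / max(raw)
  }
  mu <- switch(kind,
    sustained = h * stats::plogis(q * (t - v * n_time)),
    impulse = h * impulse_curve(n_time, impulse_length %||%
                                  round(n_time / 3)),
    complex = {
      T1 <- ceiling(n_time / 2)
      T2 <- n_time - T1
      l1 <- impulse_length %||% max(1, round(T1 / 3))
      h * c(impulse_curve(T1, min(l1, T1 - 1)),
            impulse_curve(T2, min(l1, T2 - 1)))
    },
    linear = h * (t - 1) / (n_time - 1))
  state <- ifelse(h > 0 & mu > h / 2, "H", "L")
  structure(tibble(time = t, mu = mu, state = state),
            pattern = paste(state, collapse = ""))
}

#' Simulate a synthetic collection of genes
#'
#' A synthetic collection mirrors the simulation study design: a genotyped
#' panel plus `n_genes` genes of which `n_assoc` are associated with one
#' variant each (chosen uniformly). For an associated gene, strains carrying
#' allele A of its variant express `N(mu(t), sigma)` and allele-B strains
#' `N(0, sigma)`, so the expected observed effect traces the waveform
#' `mu(t)` with low-state mean 0 and high-state mean `effect_size`.
#' Non-associated genes express `N(0, sigma)` in all strains. Expression is
#' simulated at strain level (not at effect level) so the full pipeline —
#' variance stabilisation, observed and background effects — is exercised
#' end to end.
#'
#' @inheritParams waveform
#' @param n_genes,n_assoc Collection size and number of associated genes
#'   (defaults 500 and 300).
#' @param sigma Expression noise standard deviation (default 1; effect
#'   sizes are interpreted against this scale).
#' @param geno Optional pre-simulated `dyver_geno` panel; by default a
#'   fresh `n_strains` by `n_variants` panel is drawn.
#' @param n_strains,n_variants Panel dimensions when `geno` is `NULL`.
#' @param ... Passed on to [waveform()] (e.g. `impulse_length`).
#' @return A `dyver_sim` list: `expr` (`dyver_expr`), `geno` (`dyver_geno`),
#'   `truth` (tibble `gene`, `is_associated`, `variant`, `pattern`,
#'   `effect_size`, `waveform`), `curve` (the waveform tibble), `params`.
#' @export
sim_collection <- function(kind = c("sustained", "impulse", "complex",
                                    "linear"),
                           n_time, effect_size, n_genes = 500,
                           n_assoc = 300, sigma = 1, geno = NULL,
                           n_strains = 50, n_variants = 100, ...) {
  kind <- match.arg(kind)
  if (n_assoc > n_genes) abort("n_assoc cannot exceed n_genes")
  geno <- geno %||% sim_genotypes(n_strains, n_variants)
  wv <- waveform(kind, n_time, effect_size, ...)
  truth <- tibble(
    gene = sprintf("g%04d", seq_len(n_genes)),
    is_associated = seq_len(n_genes) <= n_assoc,
    variant = c(sample(names(geno)[-1], n_assoc, replace = TRUE),
                rep(NA_character_, n_genes - n_assoc)),
    pattern = c(rep(attr(wv, "pattern"), n_assoc),
                rep(NA_character_, n_genes - n_assoc)),
    effect_size = c(rep(effect_size, n_assoc),
                    rep(NA_real_, n_genes - n_assoc)),
    waveform = c(rep(kind, n_assoc), rep(NA_character_, n_genes - n_assoc)))
  expr <- sim_expression(geno, truth, list(wv), sigma, n_time)
  structure(list(expr = expr, geno = geno, truth = truth, curve = wv,
                 params = list(kind = kind, n_time = n_time,
                               effect_size = effect_size, sigma = sigma)),
            class = "dyver_sim")
}

# build the long expression tibble; `curves` is a list of waveform tibbles,
# truth$curve_idx (optional) selects one per associated gene (default 1)
sim_expression <- function(geno, truth, curves, sigma, n_time) {
  n_strains <- nrow(geno)
  n_genes <- nrow(truth)
  times <- seq_len(n_time)
  G <- geno_matrix(geno)
  vals <- matrix(rnorm(n_genes * n_strains * n_time, 0, sigma),
                 n_genes, n_strains * n_time)
  idx <- truth[["curve_idx"]] %||% rep(1L, n_genes)
  for (i in which(truth$is_associated)) {
    a <- G[, truth$variant[i]] == 1L
    mu <- curves[[idx[i]]]$mu
    # strains x times shift for allele-A carriers
    vals[i, ] <- vals[i, ] + as.vector(outer(as.numeric(a), mu))
  }
  tbl <- tibble(
    gene = rep(truth$gene, each = n_strains * n_time),
    strain = rep(rep(geno$strain, n_time), n_genes),
    time = rep(rep(times, each = n_strains), n_genes),
    value = as.vector(t(vals)))
  new_dyver_expr(tbl)
}

#' Sample temporal two-state paths from the Markov prior
#'
#' Draws state sequences from the sequence prior of the two-state model
#' (initial probability `pi` of `H`, switch probability `lambda` per step).
#'
#' @param n Number of paths.
#' @param n_time Time points per path.
#' @inheritParams sequence_log_prob
#' @return Character vector of pattern strings (e.g. `"LLHHL"`).
#' @export
sample_state_paths <- function(n, n_time, lambda = 0.5, pi = 0.5) {
  check_lambda(lambda)
  vapply(seq_len(n), function(i) {
    s <- integer(n_time)
    s[1] <- stats::rbinom(1, 1, pi)
    if (n_time > 1) {
      sw <- stats::rbinom(n_time - 1, 1, lambda)
      s[-1] <- (s[1] + cumsum(sw)) %% 2
    }
    paste(c("L", "H")[s + 1], collapse = "")
  }, character(1))
}

#' Simulate a collection with Markov-sampled truth patterns
#'
#' The two-state error-rate dataset: for each gene a truth state path is
#' sampled from the Markov sequence prior, and allele-A strains of the
#' gene's variant express `N(mu_H, sigma)` at H time points and
#' `N(mu_L, sigma)` at L time points (allele-B strains always
#' `N(mu_L, sigma)`), so the expected observed effect follows the sampled
#' path with high-state mean `mu_H` and low-state mean `mu_L`. Used to
#' compare fitted against true temporal patterns.
#'
#' @param n_time Number of time points.
#' @param lambda_true Transition probability the truth paths are sampled
#'   with (in `(0, 0.5]`).
#' @param mu_H,mu_L High- and low-state mean effects (defaults 0.75 and 0).
#' @param sigma Expression noise sd.
#' @param n_genes Number of genes (all associated).
#' @param pi Initial H-state probability of the prior.
#' @inheritParams sim_collection
#' @return A `dyver_sim` list as for [sim_collection()] (`waveform` is
#'   `"markov"`).
#' @export
sim_markov_collection <- function(n_time = 9, lambda_true = 0.5,
                                  mu_H = 0.75, mu_L = 0, sigma = 1,
                                  n_genes = 150, pi = 0.5, geno = NULL,
                                  n_strains = 50, n_variants = 100) {
  geno <- geno %||% sim_genotypes(n_strains, n_variants)
  paths <- sample_state_paths(n_genes, n_time, lambda_true, pi)
  curves <- lapply(paths, function(p) {
    s <- strsplit(p, "")[[1]]
    tibble(time = seq_len(n_time),
           mu = ifelse(s == "H", mu_H, mu_L), state = s)
  })
  truth <- tibble(
    gene = sprintf("g%04d", seq_len(n_genes)),
    is_associated = TRUE,
    variant = sample(names(geno)[-1], n_genes, replace = TRUE),
    pattern = paths, effect_size = mu_H - mu_L, waveform = "markov",
    curve_idx = seq_len(n_genes))
  expr <- sim_expression(geno, truth, curves, sigma, n_time)
  truth$curve_idx <- NULL
  structure(list(expr = expr, geno = geno, truth = truth, curve = NULL,
                 params = list(kind = "markov", n_time = n_time,
                               lambda_true = lambda_true, mu_H = mu_H,
                               mu_L = mu_L, sigma = sigma)),
            class = "dyver_sim")
}

#' Remove a percentage of strains at each time point
#'
#' Emulates asynchronous panels: at every time point, `k_percent` percent of
#' the strains (rounded) are dropped independently, so each time point
#' consists of a different strain subset. `k_percent = 0` is the identity.
#'
#' @param x A `dyver_sim` object or a `dyver_expr` tibble.
#' @param k_percent Percentage of strains to omit per time point
#'   (`0 <= k < 100`).
#' @return Same class as `x`, with the selected measurements removed.
#' @export
apply_missingness <- function(x, k_percent) {
  if (k_percent < 0 || k_percent >= 100)
    abort("`k_percent` must lie in [0, 100)")
  expr <- if (inherits(x, "dyver_sim")) x$expr else x
  if (k_percent == 0) return(x)
  strains <- unique(expr$strain)
  n_drop <- round(length(strains) * k_percent / 100)
  times <- unique(expr$time)
  drop_keys <- unlist(lapply(times, function(tm)
    paste(sample(strains, n_drop), tm, sep = "\r")))
  keep <- !(paste(expr$strain, expr$time, sep = "\r") %in% drop_keys)
  out <- new_dyver_expr(expr[keep, ])
  n_left <- length(strains) - n_drop
  if (n_left < 4)
    warn("fewer than 4 strains left per time point; many variants will be untestable")
  if (inherits(x, "dyver_sim")) {
    x$expr <- out
    x
  } else out
}

#' Simulate the full effect-size by time-point grid of collections
#'
#' Generates one collection per combination of effect size and number of
#' time points for a given waveform (default grid: effect sizes
#' `0.125 .. 1` in eight steps, time points `3 .. 27` in nine steps — 72
#' collections).
#'
#' @inheritParams sim_collection
#' @param effect_sizes,time_points Grid values.
#' @return A tibble with columns `effect_size`, `n_time`, `collection`
#'   (list-column of `dyver_sim` objects).
#' @export
sim_grid <- function(kind = "sustained",
                     effect_sizes = seq(0.125, 1, by = 0.125),
                     time_points = seq(3, 27, by = 3),
                     n_genes = 500, n_assoc = 300, sigma = 1,
                     n_strains = 50, n_variants = 100, ...) {
  grid <- tidyr::expand_grid(effect_size = effect_sizes,
                             n_time = time_points)
  grid$collection <- purrr::pmap(grid, function(effect_size, n_time) {
    sim_collection(kind, n_time, effect_size, n_genes, n_assoc, sigma,
                   n_strains = n_strains, n_variants = n_variants, ...)
  })
  grid
}

#' @export
print.dyver_sim <- function(x, ...) {
  cat("Synthetic collection (", x$params$kind, ")\n", sep = "")
  cat("  ", length(unique(x$truth$gene)), " genes (",
      sum(x$truth$is_associated), " associated), ",
      nrow(x$geno), " strains x ", ncol(x$geno) - 1, " variants, T = ",
      length(time_points(x$expr)), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic collection to disk
#'
#' Writes the genotype, position, long expression and truth tables of a
#' collection as tab-separated files into a directory.
#'
#' @param sim A `dyver_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(sim$geno, file.path(dir, "genotypes.tsv"),
                       file.path(dir, "positions.tsv"))
  readr::write_tsv(as_tibble(sim$expr), file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' @export
autoplot.dyver_sim <- function(object, ...) {
  if (is.null(object$curve))
    abort("this collection has per-gene truth paths; no single waveform to plot")
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time, y = .data$mu,
                               colour = .data$state)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = object$params$effect_size / 2,
                        linetype = 2, colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(H = "#c0392b", L = "#2980b9")) +
    ggplot2::labs(x = "time point", y = "mean observed effect mu(t)")
}
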