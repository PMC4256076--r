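#' Observed effects: cross-allele expression differences
#'
#' For one gene and one variant, every observed pair of strains carrying
#' opposite alleles contributes one observed effect per time point:
#' `value[A-strain] - value[B-strain]` (the sign convention is always A
#' minus B). These differences remove the shared stimulation response and
#' are the sample the two-state model is fitted to. Time points where
#' either allele group has no observed strain are dropped, not imputed.
#'
#' Input is expected to be variance-stabilised (see [stabilize_variance()]);
#' the function itself applies no transformation.
#'
#' @param expr A `dyver_expr` tibble.
#' @param geno A `dyver_geno` object.
#' @param variant,gene Identifiers selecting the allele split and the gene.
#' @param max_pairs Optional cap on the number of cross-allele pairs per
#'   time point (random subsample); `Inf` (default) keeps all
#'   `n_A * n_B` pairs.
#' @return A tibble with columns `gene`, `variant`, `time`, `strain_a`,
#'   `strain_b`, `effect`; `nrow` per time point is `n_A(t) * n_B(t)`.
#' @export
observed_effects <- function(expr, geno, variant, gene, max_pairs = Inf) {
  sub <- gene_allele_values(expr, geno, variant, gene)
  a <- dplyr::rename(sub[sub$allele == "A", c("strain", "time", "value")],
                     strain_a = "strain", value_a = "value")
  b <- dplyr::rename(sub[sub$allele == "B", c("strain", "time", "value")],
                     strain_b = "strain", value_b = "value")
  d <- dplyr::inner_join(a, b, by = "time", relationship = "many-to-many")
  d <- tibble(gene = gene, variant = variant, time = d$time,
              strain_a = d$strain_a, strain_b = d$strain_b,
              effect = d$value_a - d$value_b)
  if (is.finite(max_pairs)) {
    d <- dplyr::slice_sample(dplyr::group_by(d, .data$time),
                             n = max_pairs)
    d <- dplyr::ungroup(d)
  }
  dplyr::arrange(d, .data$time, .data$strain_a, .data$strain_b)
}

#' Background effects: same-allele expression differences
#'
#' The null counterpart of [observed_effects()]: unordered pairs of strains
#' carrying the same allele, each contributing
#' `value[i] - value[j]` for `i < j` in strain-panel order. Under no genetic
#' effect, observed and background differences are draws from the same
#' symmetric-about-zero distribution; the DyVER score contrasts the two.
#'
#' @inheritParams observed_effects
#' @return A tibble with columns `gene`, `variant`, `time`, `strain_a`,
#'   `strain_b`, `allele`, `effect`; `nrow` per time point is
#'   `choose(n_A, 2) + choose(n_B, 2)`.
#' @export
background_effects <- function(expr, geno, variant, gene) {
  sub <- gene_allele_values(expr, geno, variant, gene)
  sub$idx <- match(sub$strain, geno$strain)
  x <- dplyr::rename(sub[, c("strain", "idx", "time", "value", "allele")],
                     strain_a = "strain", idx_a = "idx", value_a = "value")
  y <- dplyr::rename(sub[, c("strain", "idx", "time", "value", "allele")],
                     strain_b = "strain", idx_b = "idx", value_b = "value")
  p <- dplyr::inner_join(x, y, by = c("time", "allele"),
                         relationship = "many-to-many")
  p <- p[p$idx_a < p$idx_b, ]
  out <- tibble(gene = gene, variant = variant, time = p$time,
                strain_a = p$strain_a, strain_b = p$strain_b,
                allele = p$allele, effect = p$value_a - p$value_b)
  dplyr::arrange(out, .data$time, .data$strain_a, .data$strain_b)
}

gene_allele_values <- function(expr, geno, variant, gene) {
  if (!gene %in% expr$gene) abort(paste0("gene '", gene, "' not found"))
  groups <- split_by_allele(geno, variant)
  sub <- as_tibble(expr)[expr$gene == gene, ]
  dplyr::inner_join(sub, groups, by = "strain")
}

# per-time sufficient statistics of an effect sample (tibble with columns
# time, effect), ordered by time
effect_stats_tbl <- function(effects, times = NULL) {
  times <- times %||% sort(unique(effects$time))
  s <- dplyr::summarise(dplyr::group_by(as_tibble(effects), .data$time),
                        n = dplyr::n(), s1 = sum(.data$effect),
                        s2 = sum(.data$effect^2), .groups = "drop")
  s <- s[match(times, s$time), ]
  list(time = times,
       n = dplyr::coalesce(s$n, 0L),
       s1 = dplyr::coalesce(s$s1, 0),
       s2 = dplyr::coalesce(s$s2, 0))
}
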