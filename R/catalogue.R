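# Post-scan cataloguing: linear-like filtering, pattern groups,
# co-association modules and pattern enrichment.

#' Mean observed-effect trajectory of reported associations
#'
#' For each row of a scan, the per-time-point mean of the observed effects
#' at the reported variant (after variance stabilisation) — the input to
#' the linear-likeness filter.
#'
#' @param scan A `dyver_scan` tibble.
#' @param expr,geno The data the scan was run on.
#' @return A tibble `gene`, `time`, `effect` (mean observed effect).
#' @export
effect_trajectories <- function(scan, expr, geno) {
  purrr::map_dfr(seq_len(nrow(scan)), function(i) {
    stab <- stabilize_variance_quiet(expr, geno, scan$variant[i],
                                     scan$gene[i])
    d <- observed_effects(stab, geno, scan$variant[i], scan$gene[i])
    dplyr::summarise(dplyr::group_by(d, .data$time),
                     gene = scan$gene[i], effect = mean(.data$effect),
                     .groups = "drop")[, c("gene", "time", "effect")]
  })
}

stabilize_variance_quiet <- function(expr, geno, variant, gene) {
  sub <- new_dyver_expr(as_tibble(expr)[expr$gene == gene, ])
  suppressWarnings(stabilize_variance(sub, geno, variant))
}

#' Flag linear-like effect trajectories
#'
#' A reported association is linear-like when its mean observed-effect
#' trajectory both (i) correlates strongly with a straight line in time
#' (absolute Pearson r above `r_threshold`) and (ii) actually moves —
#' more than `change_threshold` relative change between some pair of
#' consecutive time points (relative to the earlier value, floored at
#' `eps`). Linear-like genes are typically removed before cataloguing
#' non-linear temporal patterns; trajectories with fewer than 3 time
#' points cannot be assessed and are retained.
#'
#' @param trajectories A tibble `gene`, `time`, `effect` (e.g. from
#'   [effect_trajectories()]).
#' @param r_threshold Pearson correlation threshold (default 0.95).
#' @param change_threshold Relative consecutive change threshold
#'   (default 0.05).
#' @param eps Floor for the relative-change denominator.
#' @return A tibble `gene`, `r`, `max_rel_change`, `linear_like`.
#' @export
filter_linear_like <- function(trajectories, r_threshold = 0.95,
                               change_threshold = 0.05, eps = 1e-6) {
  tbl <- dplyr::group_by(as_tibble(trajectories), .data$gene)
  dplyr::summarise(
    tbl,
    r = if (dplyr::n() >= 3 && sd(.data$effect) > 0)
      abs(cor(.data$time, .data$effect)) else NA_real_,
    max_rel_change = if (dplyr::n() >= 2)
      max(abs(diff(.data$effect)) /
            pmax(abs(head(.data$effect, -1)), eps)) else NA_real_,
    linear_like = dplyr::n() >= 3 & !is.na(.data$r) &
      .data$r > r_threshold & .data$max_rel_change > change_threshold,
    .groups = "drop")
}

#' Group catalogued genes by fitted temporal pattern
#'
#' Partitions genes by exact fitted pattern string. Groups with at least
#' `min_size` members are reported (default 2); smaller groups
#' (singletons) are listed in the `singletons` attribute.
#'
#' @param catalogue A tibble with `gene` and `pattern` columns (e.g. a
#'   filtered [dyver_scan()] result).
#' @param min_size Minimum group size to report.
#' @return A tibble `pattern`, `n_genes`, `genes` (list-column), largest
#'   first; attribute `singletons` holds the omitted gene ids.
#' @export
group_by_pattern <- function(catalogue, min_size = 2) {
  if (nrow(catalogue) == 0)
    return(structure(tibble(pattern = character(), n_genes = integer(),
                            genes = list()), singletons = character()))
  tbl <- dplyr::summarise(
    dplyr::group_by(as_tibble(catalogue), .data$pattern),
    n_genes = dplyr::n(), genes = list(.data$gene), .groups = "drop")
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$n_genes), .data$pattern)
  structure(tbl[tbl$n_genes >= min_size, ],
            singletons = unlist(tbl$genes[tbl$n_genes < min_size]) %||%
              character())
}

#' Build co-association modules of trans-associated genes
#'
#' Groups catalogued genes that share the same trans-associated variant. An
#' association is *cis* when the variant lies within `cis_window_kb` of the
#' gene on the same chromosome, and *trans* otherwise; only trans
#' associations enter modules, and only modules with at least `min_size`
#' genes are kept.
#'
#' @param catalogue A tibble with `gene`, `variant`, `chrom`, `kb`
#'   (variant position) columns, e.g. a filtered [dyver_scan()] result.
#' @param gene_positions A tibble `gene`, `chrom`, `kb` locating the genes;
#'   genes without a position are excluded with a warning.
#' @param cis_window_kb Cis window half-width in kb (default 50).
#' @param min_size Minimum module size (default 2).
#' @return A tibble `module`, `variant`, `chrom`, `kb`, `n_genes`, `genes`
#'   (list-column); attribute `cis` holds the cis-labelled gene ids.
#' @export
build_modules <- function(catalogue, gene_positions, cis_window_kb = 50,
                          min_size = 2) {
  cat_tbl <- as_tibble(catalogue)
  gp <- dplyr::rename(as_tibble(gene_positions), gene_chrom = "chrom",
                      gene_kb = "kb")
  tbl <- dplyr::left_join(cat_tbl, gp, by = "gene")
  nop <- is.na(tbl$gene_kb)
  if (any(nop)) {
    warn(paste0(sum(nop), " gene(s) without positions excluded from modules"))
    tbl <- tbl[!nop, ]
  }
  is_cis <- tbl$chrom == tbl$gene_chrom &
    abs(tbl$kb - tbl$gene_kb) <= cis_window_kb
  trans <- tbl[!is_cis, ]
  mods <- dplyr::summarise(
    dplyr::group_by(trans, .data$variant, .data$chrom, .data$kb),
    n_genes = dplyr::n(), genes = list(sort(.data$gene)), .groups = "drop")
  mods <- mods[mods$n_genes >= min_size, ]
  mods <- dplyr::arrange(mods, dplyr::desc(.data$n_genes), .data$variant)
  mods <- dplyr::bind_cols(tibble(module = seq_len(nrow(mods))), mods)
  structure(mods, cis = tbl$gene[is_cis])
}

#' Pattern enrichment within co-association modules
#'
#' Hypergeometric over-representation test of each fitted pattern within
#' each module, against the whole catalogue as background, with
#' Benjamini-Hochberg correction across all (module, pattern) tests.
#'
#' @param modules Module table from [build_modules()].
#' @param catalogue The background catalogue (tibble with `gene`,
#'   `pattern`); must contain every module member.
#' @param q FDR level for the `enriched` flag (default 0.01).
#' @return A tibble `module`, `pattern`, `overlap`, `module_size`,
#'   `bg_count`, `bg_size`, `p`, `q_value`, `enriched`.
#' @export
pattern_enrichment <- function(modules, catalogue, q = 0.01) {
  cat_tbl <- as_tibble(catalogue)
  bg_size <- nrow(cat_tbl)
  bg <- table(cat_tbl$pattern)
  rows <- purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    genes <- modules$genes[[i]]
    if (!all(genes %in% cat_tbl$gene))
      abort("module contains genes absent from the catalogue background")
    pats <- cat_tbl$pattern[match(genes, cat_tbl$gene)]
    purrr::map_dfr(unique(pats), function(pt) {
      k <- sum(pats == pt)
      m <- as.integer(bg[pt])
      tibble(module = modules$module[i], pattern = pt, overlap = k,
             module_size = length(genes), bg_count = m, bg_size = bg_size,
             p = phyper(k - 1, m, bg_size - m, length(genes),
                        lower.tail = FALSE))
    })
  })
  rows$q_value <- p.adjust(rows$p, method = "BH")
  rows$enriched <- rows$q_value <= q
  rows
}
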