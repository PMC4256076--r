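#' Read a time-course expression table
#'
#' Reads log-scale expression indexed by (gene, strain, time point). Two
#' layouts are supported: a single long table with columns
#' `gene, strain, time, value` (extra columns are ignored; common aliases
#' such as `time_min`/`log_expr` are recognised), or one wide table per time
#' point (first column gene identifiers, remaining columns strains).
#' Missing entries are encoded as `NA` and simply mark a (strain, time) pair
#' as unobserved; the strain sets of different time points may differ.
#'
#' @param path For `layout = "long"` a single path; for `layout = "wide"` a
#'   character vector of per-time-point file paths (parallel to `times`).
#' @param layout `"long"` (default) or `"wide"`.
#' @param times Numeric time points (minutes) for the wide layout, one per
#'   file.
#' @param log2_transform Apply `log2` on load (default `FALSE`: values are
#'   assumed to be log-scale already).
#' @param strains Optional strain identifiers to intersect with (typically
#'   `geno$strain`).
#' @return A `dyver_expr` tibble with columns `gene`, `strain`, `time`,
#'   `value`, one row per observed measurement.
#' @export
read_expression_table <- function(path, layout = c("long", "wide"),
                                  times = NULL, log2_transform = FALSE,
                                  strains = NULL) {
  layout <- match.arg(layout)
  if (layout == "long") {
    tbl <- readr::read_tsv(path[1], show_col_types = FALSE, progress = FALSE)
    nm <- tolower(names(tbl))
    pick <- function(cands, what) {
      i <- which(nm %in% cands)[1]
      if (is.na(i)) abort(paste0("long expression table needs a ", what,
                                 " column (one of: ",
                                 paste(cands, collapse = ", "), ")"))
      i
    }
    gi <- pick(c("gene", "gene_id"), "gene")
    si <- pick(c("strain", "strain_id"), "strain")
    ti <- pick(c("time", "time_min", "timepoint"), "time")
    vi <- pick(c("value", "log_expr", "expr", "expression"), "value")
    tbl <- tibble(gene = as.character(tbl[[gi]]),
                  strain = as.character(tbl[[si]]),
                  time = as.numeric(tbl[[ti]]),
                  value = as.numeric(tbl[[vi]]))
  } else {
    if (is.null(times) || length(times) != length(path))
      abort("wide layout needs `times`, one per file")
    tbl <- purrr::map2_dfr(path, times, function(p, tm) {
      w <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
      names(w)[1] <- "gene"
      w$gene <- as.character(w$gene)
      long <- tidyr::pivot_longer(w, -"gene", names_to = "strain",
                                  values_to = "value")
      long$time <- tm
      long[, c("gene", "strain", "time", "value")]
    })
  }
  new_dyver_expr(tbl, log2_transform = log2_transform, strains = strains)
}

new_dyver_expr <- function(tbl, log2_transform = FALSE, strains = NULL) {
  tbl <- as_tibble(tbl)[, c("gene", "strain", "time", "value")]
  if (nrow(tbl) == 0 || length(unique(tbl$gene)) == 0)
    abort("expression table contains no genes")
  if (!is.numeric(tbl$value)) abort("expression values must be numeric")
  if (!is.null(strains)) tbl <- tbl[tbl$strain %in% strains, ]
  if (log2_transform) tbl$value <- log2(tbl$value)
  tbl <- tbl[!is.na(tbl$value), ]
  if (any(!is.finite(tbl$value))) abort("expression values must be finite")
  dup <- duplicated(tbl[, c("gene", "strain", "time")])
  if (any(dup)) {
    d <- tbl[dup, ][1, ]
    abort(paste0("duplicate (gene, strain, time) record: ", d$gene, ", ",
                 d$strain, ", t=", d$time))
  }
  tbl <- dplyr::arrange(tbl, .data$gene, .data$time, .data$strain)
  structure(tbl, class = c("dyver_expr", class(tibble())))
}

#' Time points of an expression dataset
#' @param expr A `dyver_expr` tibble.
#' @return Sorted unique time points.
#' @export
time_points <- function(expr) sort(unique(expr$time))

# strains x times value matrix for one gene (NA = unobserved)
expr_matrix <- function(expr, gene, strain_ids, times = NULL) {
  sub <- expr[expr$gene == gene, ]
  if (nrow(sub) == 0) abort(paste0("gene '", gene, "' not found"))
  times <- times %||% sort(unique(expr$time))
  m <- matrix(NA_real_, length(strain_ids), length(times),
              dimnames = list(strain_ids, times))
  si <- match(sub$strain, strain_ids)
  ti <- match(sub$time, times)
  keep <- !is.na(si) & !is.na(ti)
  m[cbind(si[keep], ti[keep])] <- sub$value[keep]
  m
}

#' Variance-stabilise expression within (time point, allele) cells
#'
#' Rescales the log expression of each gene so that, within every time point
#' and allele group of the given variant, the sample variance is fixed at 1
#' while the group mean is unchanged: `x -> m + (x - m) / s` with `m`, `s`
#' the group mean and standard deviation. The two-state model assumes the
#' variance of genetic effects does not change over time; this
#' transformation enforces that before observed effects are computed. The
#' genome scan applies the same transformation internally, conditional on
#' the tested variant's allele split.
#'
#' Groups with zero variance (or fewer than two observed strains) are passed
#' through unchanged with a warning.
#'
#' @param expr A `dyver_expr` tibble.
#' @param geno A `dyver_geno` object.
#' @param variant Variant whose allele split defines the groups.
#' @return A `dyver_expr` tibble with transformed values.
#' @export
stabilize_variance <- function(expr, geno, variant) {
  groups <- split_by_allele(geno, variant)
  tbl <- dplyr::inner_join(as_tibble(expr), groups, by = "strain")
  tbl <- dplyr::group_by(tbl, .data$gene, .data$time, .data$allele)
  tbl <- dplyr::mutate(
    tbl,
    .n = dplyr::n(), .m = mean(.data$value),
    .s = dplyr::coalesce(sd(.data$value), 0),
    value = dplyr::if_else(.data$.n >= 2 & .data$.s > 0,
                           .data$.m + (.data$value - .data$.m) / .data$.s,
                           .data$value))
  degenerate <- dplyr::summarise(
    tbl, bad = dplyr::first(.data$.n) < 2 | dplyr::first(.data$.s) == 0,
    .groups = "drop")
  if (any(degenerate$bad))
    warn(paste0(sum(degenerate$bad),
                " (gene, time, allele) cell(s) with <2 strains or zero",
                " variance left unscaled"))
  tbl <- dplyr::ungroup(tbl)
  new_dyver_expr(tbl[, c("gene", "strain", "time", "value")])
}
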