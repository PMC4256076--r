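#' Read a strain-by-variant genotype table
#'
#' Reads a tab-separated genotype table for a panel of homozygous inbred
#' strains: one row per strain (first column holds strain identifiers), one
#' column per biallelic marker. Each marker must carry at most two distinct
#' allele codes across the panel; codes are mapped to the abstract alleles
#' `"A"`/`"B"` at load, with the original labels retained for reporting.
#'
#' @param path Path to a tab-separated genotype file.
#' @param alleles Optional named character vector declaring the two-symbol
#'   alphabet, e.g. `c(A = "BY", B = "RM")`. When `NULL` the two codes are
#'   taken from the table (sorted; first maps to `"A"`). Any entry outside
#'   the declared alphabet is an error naming the offending strain and
#'   variant (heterozygous codes are therefore rejected: the method is
#'   defined for homozygous panels only).
#' @param positions Optional variant positions: a path to a tab-separated
#'   file or a data frame with columns `variant`, `chrom`, `kb` (1-based
#'   kilobase coordinates). When omitted, placeholder positions on one
#'   synthetic chromosome are assigned in column order.
#'
#' @return A `dyver_geno` tibble: column `strain` followed by one `"A"`/`"B"`
#'   column per variant, ordered by position within chromosome. Variant
#'   positions are stored in the `positions` attribute (see
#'   [variant_positions()]) and the original allele labels in the
#'   `allele_codes` attribute.
#' @seealso [split_by_allele()], [write_genotype_table()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("strain\tv1\tv2", "s1\tBY\tRM", "s2\tRM\tRM", "s3\tBY\tBY"), tf)
#' read_genotype_table(tf)
read_genotype_table <- function(path, alleles = NULL, positions = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("genotype table needs a strain column and at least one variant column")
  names(raw)[1] <- "strain"
  if (anyDuplicated(raw$strain)) abort("duplicate strain identifiers in genotype table")
  if (anyDuplicated(names(raw)[-1])) abort("duplicate variant identifiers in genotype table")
  codes <- sort(unique(unlist(lapply(raw[-1], unique), use.names = FALSE)))
  codes <- codes[!is.na(codes)]
  if (is.null(alleles)) {
    if (length(codes) > 2) {
      bad <- names(raw)[-1][vapply(raw[-1], function(x) length(unique(stats::na.omit(x))) > 2, logical(1))]
      abort(paste0("genotype table is not biallelic: found codes {",
                   paste(codes, collapse = ", "), "}",
                   if (length(bad)) paste0("; variants with >2 codes: ",
                                           paste(bad, collapse = ", "))))
    }
    alleles <- stats::setNames(codes, c("A", "B")[seq_along(codes)])
  }
  if (!all(c("A") %in% names(alleles)) || length(alleles) > 2)
    abort("`alleles` must be a named vector like c(A = ..., B = ...)")
  for (v in names(raw)[-1]) {
    x <- raw[[v]]
    known <- is.na(x) | x %in% alleles
    if (!all(known)) {
      i <- which(!known)[1]
      abort(paste0("unknown allele code '", x[i], "' at strain '",
                   raw$strain[i], "', variant '", v,
                   "' (declared alphabet: ", paste(alleles, collapse = "/"),
                   "); heterozygous or multi-allelic codes are not supported"))
    }
    if (length(unique(stats::na.omit(x))) > 2)
      abort(paste0("variant '", v, "' carries more than two allele codes"))
    raw[[v]] <- names(alleles)[match(x, alleles)]
  }
  pos <- resolve_positions(positions, names(raw)[-1])
  new_dyver_geno(raw, pos, alleles)
}

resolve_positions <- function(positions, variant_ids) {
  if (is.null(positions)) {
    return(tibble(variant = variant_ids, chrom = "chr1",
                  kb = 50 * seq_along(variant_ids)))
  }
  if (is.character(positions)) {
    positions <- readr::read_tsv(positions, show_col_types = FALSE,
                                 progress = FALSE)
  }
  positions <- as_tibble(positions)
  names(positions)[1:3] <- c("variant", "chrom", "kb")
  missing <- setdiff(variant_ids, positions$variant)
  if (length(missing))
    abort(paste0("positions missing for variants: ",
                 paste(head(missing, 5), collapse = ", ")))
  positions[match(variant_ids, positions$variant), c("variant", "chrom", "kb")]
}

new_dyver_geno <- function(tbl, positions, allele_codes) {
  # order variants by position within chromosome
  ord <- order(positions$chrom, positions$kb)
  tbl <- tbl[, c(1L, 1L + ord)]
  positions <- positions[ord, ]
  structure(as_tibble(tbl),
            positions = as_tibble(positions),
            allele_codes = allele_codes,
            class = c("dyver_geno", class(as_tibble(tbl))))
}

#' Variant positions of a genotype table
#'
#' @param geno A `dyver_geno` object.
#' @return A tibble with columns `variant`, `chrom`, `kb`.
#' @export
variant_positions <- function(geno) {
  attr(geno, "positions")
}

#' Write a genotype table back to disk
#'
#' Inverse of [read_genotype_table()]: allele codes are mapped back to the
#' original labels stored at load time.
#'
#' @param geno A `dyver_geno` object.
#' @param path Output path for the tab-separated genotype table.
#' @param positions_path Optional path for a companion variant-position
#'   table (`variant`, `chrom`, `kb`).
#' @return `geno`, invisibly.
#' @export
write_genotype_table <- function(geno, path, positions_path = NULL) {
  codes <- attr(geno, "allele_codes")
  out <- geno
  for (v in names(out)[-1]) out[[v]] <- unname(codes[out[[v]]])
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  if (!is.null(positions_path))
    readr::write_tsv(variant_positions(geno), positions_path, progress = FALSE)
  invisible(geno)
}

#' Partition strains by allele at a variant
#'
#' Splits the panel into the two allele groups of a variant. A monomorphic
#' variant (one empty group) is flagged untestable and is skipped by the
#' genome scan.
#'
#' @param geno A `dyver_geno` object.
#' @param variant Variant identifier (a column of `geno`).
#' @return A tibble with columns `strain` and `allele` (`"A"`/`"B"`), with
#'   attribute `testable` (`TRUE` unless a group is empty).
#' @export
split_by_allele <- function(geno, variant) {
  if (!variant %in% names(geno)[-1])
    abort(paste0("variant '", variant, "' not found in genotype table"))
  out <- tibble(strain = geno$strain, allele = geno[[variant]])
  out <- out[!is.na(out$allele), ]
  testable <- all(c("A", "B") %in% out$allele)
  structure(out, testable = testable, variant = variant,
            class = class(tibble()))
}

# strains x variants integer matrix: allele A -> 1, B -> 0
geno_matrix <- function(geno) {
  vs <- names(geno)[-1]
  m <- vapply(vs, function(v) as.integer(geno[[v]] == "A"),
              integer(nrow(geno)))
  dim(m) <- c(nrow(geno), length(vs))
  dimnames(m) <- list(geno$strain, vs)
  m
}
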