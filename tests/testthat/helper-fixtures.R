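# Small in-code fixtures shared across test files.

# genotype table with explicit allele assignment: `alleles` is a strains x
# variants character matrix over {"A", "B"}
make_geno <- function(alleles, strains = NULL, variants = NULL) {
  strains <- strains %||% sprintf("s%02d", seq_len(nrow(alleles)))
  variants <- variants %||% sprintf("v%02d", seq_len(ncol(alleles)))
  tbl <- tibble::as_tibble(as.data.frame(alleles, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(tbl) <- variants
  tbl <- dplyr::bind_cols(tibble::tibble(strain = strains), tbl)
  pos <- tibble::tibble(variant = variants, chrom = "chr1",
                        kb = 50 * seq_along(variants))
  dyver:::new_dyver_geno(tbl, pos, c(A = "A", B = "B"))
}

# long expression tibble from a strains x times matrix for one gene
make_expr <- function(values, strains, times = seq_len(ncol(values)),
                      gene = "g1") {
  tbl <- tibble::tibble(
    gene = gene,
    strain = rep(strains, length(times)),
    time = rep(times, each = length(strains)),
    value = as.vector(values))
  dyver:::new_dyver_expr(tbl[!is.na(tbl$value), ])
}

# effect tibble on a time grid: one row per draw
make_effects <- function(by_time) {
  tibble::tibble(
    time = rep(seq_along(by_time), lengths(by_time)),
    effect = unlist(by_time))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
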