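#' Read a flat key=value configuration file
#'
#' Parses a plain-text configuration of `key = value` lines (comments start
#' with `#`; blank lines ignored). Values that parse as numbers are
#' returned numeric; `true`/`false` become logical. Keys mirror the
#' command-line flags of the bundled `dyver` script (e.g. `penalty`,
#' `n_perm`, `seed`, `fdr_assoc`, `fdr_dynamic`, `out_dir`).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      abort(paste0("config line is not key=value: '", ln, "'"))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}
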