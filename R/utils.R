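# Internal helpers shared across modules.

#' Canonicalize gene symbols
#'
#' Trims surrounding whitespace and upper-cases. No alias resolution is
#' attempted; identifiers must be pre-mapped to a common namespace.
#'
#' @param x character vector of gene symbols.
#' @return canonicalized character vector.
#' @export
canonical_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

# Validate canonicalized gene symbols: non-empty, no internal whitespace.
check_gene_symbols <- function(genes, context = "gene symbol") {
  bad <- !nzchar(genes) | grepl("[[:space:]]", genes)
  if (any(bad)) {
    stop(sprintf("invalid %s(s): %s", context,
                 paste(sQuote(unique(genes[bad])), collapse = ", ")),
         call. = FALSE)
  }
  invisible(genes)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Usage errors (bad flags, missing files, out-of-range parameters) carry a
# dedicated condition class so the CLI can map them to exit code 1; all other
# errors are data errors (exit code 2).
usage_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pascore_usage_error", "error")))
}

# Format numbers for TSV output. digits <= 0 means full precision.
fmt_num <- function(x, digits = 6L) {
  if (digits > 0L) x <- signif(x, digits)
  format(x, trim = TRUE, scientific = FALSE, digits = 15L)
}

write_tsv <- function(df, path, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

# Matrix -> data.frame with a leading id column, for TSV export.
matrix_to_df <- function(m, id_col) {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  rownames(df) <- NULL
  df
}
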