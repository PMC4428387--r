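#' Allowed activator/repressor role (ARR) weights
#'
#' A pathway member's ARR weight encodes its role in signal transduction
#' through that pathway: 1 for an activator, -1 for a repressor, 0.5 / -0.5
#' for genes that are rather activators / rather repressors, and 0 for genes
#' that can act as either. No other weight is valid.
#'
#' @export
ARR_VALUES <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway database
#'
#' A pathway database is an ordered collection of pathways, each a set of
#' member genes with ARR weights. It is stored as a long-format member table
#' (one row per pathway/gene pair); pathway order is first-appearance order
#' and is preserved by I/O, so outputs are deterministic.
#'
#' @param members data.frame with columns \code{pathway_id},
#'   \code{pathway_name}, \code{gene}, \code{arr}.
#' @param version free-text provenance string.
#' @param validate validate invariants (unique genes per pathway, ARR values
#'   from \code{\link{ARR_VALUES}}, canonical gene symbols). Only disable for
#'   deliberately degenerate inputs, e.g. duplicated member lists in
#'   linearity checks.
#' @return object of class \code{pathway_db}.
#' @export
pathway_db <- function(members, version = "", validate = TRUE) {
  req <- c("pathway_id", "pathway_name", "gene", "arr")
  if (!is.data.frame(members) || !all(req %in% names(members))) {
    stop("members must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  members <- members[, req]
  members$pathway_id <- as.character(members$pathway_id)
  members$pathway_name <- as.character(members$pathway_name)
  members$gene <- canonical_gene(members$gene)
  members$arr <- as.numeric(members$arr)
  rownames(members) <- NULL
  db <- structure(list(members = members, version = as.character(version)),
                  class = "pathway_db")
  if (validate) validate_pathway_db(db)
  db
}

validate_pathway_db <- function(db) {
  m <- db$members
  if (nrow(m) > 0) {
    check_gene_symbols(m$gene)
    bad <- is.na(m$arr) | !vapply(m$arr, function(a) any(abs(a - ARR_VALUES) < 1e-12), logical(1))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("invalid ARR value %s for gene %s in pathway %s (allowed: %s)",
                   m$arr[i], m$gene[i], m$pathway_id[i],
                   paste(ARR_VALUES, collapse = ", ")), call. = FALSE)
    }
    key <- paste(m$pathway_id, m$gene, sep = "\r")
    if (anyDuplicated(key)) {
      d <- m[duplicated(key), , drop = FALSE]
      stop(sprintf("duplicate gene %s in pathway %s", d$gene[1], d$pathway_id[1]),
           call. = FALSE)
    }
    # one name per pathway id
    nm <- unique(m[, c("pathway_id", "pathway_name")])
    if (anyDuplicated(nm$pathway_id)) {
      stop("pathway id with conflicting names: ",
           nm$pathway_id[duplicated(nm$pathway_id)][1], call. = FALSE)
    }
  }
  invisible(db)
}

#' @export
print.pathway_db <- function(x, ...) {
  ids <- pathway_ids(x)
  cat(sprintf("pathway_db: %d pathways, %d member entries, %d distinct genes\n",
              length(ids), nrow(x$members), length(unique(x$members$gene))))
  if (nzchar(x$version)) cat("version:", x$version, "\n")
  invisible(x)
}

#' Pathway ids in database order
#' @param db a \code{pathway_db}.
#' @return character vector of pathway ids, in first-appearance order.
#' @export
pathway_ids <- function(db) {
  unique(db$members$pathway_id)
}

#' Read a pathway database from a TSV file
#'
#' Expects a tab-separated file with header columns \code{pathway_id},
#' \code{pathway_name}, \code{gene}, \code{arr}; one member per row. Gene
#' symbols are canonicalized (trimmed, upper-cased) on read, and the file is
#' rejected if that produces a duplicate member, if any ARR value is outside
#' \code{\link{ARR_VALUES}}, or if a row has the wrong number of fields.
#'
#' @param path path to the TSV file.
#' @param version provenance string to attach; defaults to the file name.
#' @return a \code{\link{pathway_db}}.
#' @export
read_pathway_db <- function(path, version = basename(path)) {
  if (!file.exists(path)) usage_error("pathway database file not found: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 4L)
  if (length(bad)) {
    stop(sprintf("malformed pathway database row at line %d of %s: expected 4 tab-separated fields, found %d",
                 bad[1], path, nf[bad[1]]), call. = FALSE)
  }
  raw <- read.delim(path, sep = "\t", quote = "", comment.char = "",
                    colClasses = "character", check.names = FALSE)
  req <- c("pathway_id", "pathway_name", "gene", "arr")
  if (!identical(names(raw), req)) {
    stop("pathway database header must be exactly: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  arr <- suppressWarnings(as.numeric(raw$arr))
  bad <- is.na(arr) | !arr %in% ARR_VALUES
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid ARR value '%s' for gene %s in pathway %s (line %d)",
                 raw$arr[i], canonical_gene(raw$gene[i]), raw$pathway_id[i],
                 i + 1L), call. = FALSE)
  }
  raw$arr <- arr
  pathway_db(raw, version = version)
}

#' Write a pathway database to a TSV file
#'
#' Inverse of \code{\link{read_pathway_db}}: writing then reading reproduces
#' the database exactly. ARR weights are rendered with one decimal place so
#' round-trips are byte-stable.
#'
#' @param db a \code{pathway_db}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  m <- db$members
  m$arr <- sprintf("%.1f", m$arr)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-pathway coverage of a gene universe
#'
#' Fraction of each pathway's members present in a given gene universe
#' (typically the genes measured in an expression matrix). Useful for
#' reporting how completely the data cover each pathway before scoring.
#'
#' @param db a \code{pathway_db}.
#' @param gene_universe character vector of gene symbols (canonicalized
#'   internally).
#' @return named numeric vector in [0, 1], one entry per pathway, in
#'   database order.
#' @export
coverage <- function(db, gene_universe) {
  stopifnot(inherits(db, "pathway_db"))
  universe <- unique(canonical_gene(gene_universe))
  ids <- pathway_ids(db)
  vapply(setNames(ids, ids), function(p) {
    g <- db$members$gene[db$members$pathway_id == p]
    mean(g %in% universe)
  }, numeric(1))
}
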