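#' Construct an expression matrix
#'
#' Gene-by-sample matrix of nonnegative expression values on the platform's
#' native linear scale (microarray intensities or gene-level counts), with
#' optional control-sample annotation. Gene symbols are canonicalized and
#' must be unique.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param platform_label free-text platform description; labels matching
#'   \code{seq}/\code{ngs} change the default normalization behaviour in the
#'   pipeline (sequencing counts are not quantile normalized by default).
#' @param control_ids character vector of control sample ids (subset of
#'   \code{colnames(values)}).
#' @return object of class \code{expr_matrix}.
#' @export
expression_matrix <- function(values, platform_label = "", control_ids = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- canonical_gene(rownames(values))
  check_gene_symbols(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols after canonicalization: ",
         rownames(values)[duplicated(rownames(values))][1],
         "; aggregate first (see aggregate_probes)", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("expression values must be finite", call. = FALSE)
  if (any(values < 0)) stop("expression values must be nonnegative", call. = FALSE)
  control_ids <- as.character(control_ids)
  missing <- setdiff(control_ids, colnames(values))
  if (length(missing)) {
    stop("control id(s) absent from samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, platform_label = as.character(platform_label),
                 control_ids = control_ids),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d controls)%s\n",
              nrow(x$values), ncol(x$values), length(x$control_ids),
              if (nzchar(x$platform_label)) paste0(" [", x$platform_label, "]") else ""))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an \code{expr_matrix}.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
samples <- function(x) colnames(x$values)

#' Case and control submatrices
#'
#' Split an annotated expression matrix into its control columns and its
#' case columns (everything not listed as a control).
#'
#' @param x an \code{expr_matrix} with at least one control id.
#' @return plain numeric matrix.
#' @export
control_values <- function(x) {
  if (!length(x$control_ids)) stop("no control ids annotated", call. = FALSE)
  x$values[, x$control_ids, drop = FALSE]
}

#' @rdname control_values
#' @export
case_values <- function(x) {
  x$values[, setdiff(colnames(x$values), x$control_ids), drop = FALSE]
}

#' Average repeated measurements per gene
#'
#' Microarrays carry several probes per gene; repeated rows for one symbol
#' are collapsed to their arithmetic mean per sample, on the linear scale,
#' before any normalization.
#'
#' @param values numeric matrix whose rownames may repeat.
#' @return matrix with unique rownames, rows in first-appearance order.
#' @export
aggregate_probes <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  g <- rownames(values)
  if (!anyDuplicated(g)) return(values)
  first <- unique(g)
  out <- rowsum(values, group = g, reorder = FALSE) /
    as.vector(table(factor(g, levels = unique(g))))
  out[first, , drop = FALSE]
}

#' Read an expression matrix from a TSV file
#'
#' Expects a header row (\code{gene} then sample ids) and one gene per row.
#' Lines starting with \code{!} (GEO series-matrix metadata) are skipped.
#' Duplicate gene rows (multiple probes) are mean-aggregated. Cells must be
#' numeric and nonnegative.
#'
#' @param path path to the TSV file.
#' @param control_ids control sample ids; each must appear in the header.
#' @param platform_label free-text platform description.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, control_ids = character(), platform_label = "") {
  if (!file.exists(path)) usage_error("expression file not found: %s", path)
  raw <- read.delim(path, sep = "\t", quote = "", comment.char = "!",
                    colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column and >=1 sample column",
                          call. = FALSE)
  gene <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, colnames(vals))))
  if (any(is.na(num) & !is.na(vals))) {
    idx <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value '%s' at data row %d, column %s",
                 vals[idx[1], idx[2]], idx[1], colnames(vals)[idx[2]]),
         call. = FALSE)
  }
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at data row %d, column %s",
                 idx[1], colnames(vals)[idx[2]]), call. = FALSE)
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at data row %d, column %s",
                 idx[1], colnames(vals)[idx[2]]), call. = FALSE)
  }
  rownames(num) <- canonical_gene(gene)
  num <- aggregate_probes(num)
  missing <- setdiff(control_ids, colnames(num))
  if (length(missing)) {
    stop("control id(s) absent from expression header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expression_matrix(num, platform_label = platform_label, control_ids = control_ids)
}

#' Write an expression matrix to a TSV file
#'
#' @param x an \code{expr_matrix}.
#' @param path output path.
#' @param digits significant digits for values (<= 0 writes full precision).
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(x, path, digits = 0L) {
  stopifnot(inherits(x, "expr_matrix"))
  write_tsv(matrix_to_df(x$values, "gene"), path, digits = digits)
}

#' Quantile normalization
#'
#' Forces every sample (column) to share a common reference distribution:
#' the across-sample mean of the per-rank sorted values. Within-column rank
#' order is preserved; tied values receive the mean of the reference values
#' their ranks span. This is the standard microarray between-array
#' normalization; sequencing count matrices can be passed through but are
#' not normalized by default in the pipeline.
#'
#' @param x an \code{expr_matrix} or plain numeric matrix with >= 2 columns.
#' @return object of the same class with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expr_matrix")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2) {
    stop("quantile normalization needs >= 2 samples; skip normalization for single-sample matrices",
         call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Restrict two expression matrices to their shared genes
#'
#' Cross-platform comparison requires a common gene set; both matrices are
#' restricted to the intersection, in lexicographic order.
#'
#' @param a,b \code{expr_matrix} objects.
#' @return list with elements \code{a} and \code{b}.
#' @export
intersect_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  shared <- sort(intersect(genes(a), genes(b)))
  if (!length(shared)) stop("no shared genes between the two matrices", call. = FALSE)
  a$values <- a$values[shared, , drop = FALSE]
  b$values <- b$values[shared, , drop = FALSE]
  list(a = a, b = b)
}
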