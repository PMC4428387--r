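#' Pearson correlation with explicit degenerate handling
#'
#' Product-moment correlation of two equal-length vectors. Returns
#' \code{NA} (the undefined flag) when either vector has zero variance
#' rather than warning, since constant profiles legitimately occur (e.g.
#' all-zero PAS under an empty flag matrix).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return correlation in [-1, 1], or \code{NA} if undefined.
#' @export
pearson <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("correlation needs >= 2 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

#' Gene-level vs pathway-level cross-platform concordance
#'
#' For samples profiled on two platforms, compares how well the platforms
#' agree at the gene level (correlation of per-gene lg CNR) versus at the
#' pathway level (correlation of per-pathway PAS). An additional
#' \code{averaged} row correlates the across-pair mean profiles, mirroring
#' replicate-averaged comparisons.
#'
#' @param cnr_a,cnr_b \code{cnr_table}s from the two platforms, computed on
#'   the same gene set in the same order (use \code{\link{intersect_genes}}
#'   upstream).
#' @param pas_a,pas_b \code{pas_matrix} objects from the same
#'   \code{pathway_db} applied to both platforms.
#' @param sample_pairs data.frame with columns \code{id_a}, \code{id_b}
#'   mapping platform-A case sample ids to platform-B ids. Defaults to
#'   matching identical ids.
#' @param method correlation estimator, see \code{\link{pearson}}.
#' @return object of class \code{concordance_report}: list with
#'   \code{per_sample} (data.frame sample, r_gene, r_pas, n_genes,
#'   n_pathways) and \code{averaged} (one-row data.frame).
#' @export
paired_concordance <- function(cnr_a, cnr_b, pas_a, pas_b,
                               sample_pairs = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(cnr_a, "cnr_table"), inherits(cnr_b, "cnr_table"),
            inherits(pas_a, "pas_matrix"), inherits(pas_b, "pas_matrix"))
  if (!identical(rownames(cnr_a$cnr), rownames(cnr_b$cnr))) {
    stop("the two platforms must be restricted to the same gene set in the same order",
         call. = FALSE)
  }
  if (!identical(rownames(pas_a$pas), rownames(pas_b$pas))) {
    stop("the two platforms must be scored with the same pathway database",
         call. = FALSE)
  }
  if (is.null(sample_pairs)) {
    shared <- intersect(colnames(cnr_a$cnr), colnames(cnr_b$cnr))
    if (!length(shared)) stop("no shared case sample ids; supply sample_pairs",
                              call. = FALSE)
    sample_pairs <- data.frame(id_a = shared, id_b = shared,
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sample_pairs),
            all(c("id_a", "id_b") %in% names(sample_pairs)))
  miss_a <- setdiff(sample_pairs$id_a, colnames(cnr_a$cnr))
  miss_b <- setdiff(sample_pairs$id_b, colnames(cnr_b$cnr))
  if (length(miss_a) || length(miss_b)) {
    stop("unknown sample id(s): ", paste(c(miss_a, miss_b), collapse = ", "),
         call. = FALSE)
  }
  n_genes <- nrow(cnr_a$cnr)
  n_pathways <- nrow(pas_a$pas)
  one <- function(ia, ib) {
    data.frame(
      sample = if (ia == ib) ia else paste(ia, ib, sep = "|"),
      r_gene = if (n_genes >= 2)
        pearson(cnr_a$log_cnr[, ia], cnr_b$log_cnr[, ib], method) else NA_real_,
      r_pas = if (n_pathways >= 2)
        pearson(pas_a$pas[, ia], pas_b$pas[, ib], method) else NA_real_,
      n_genes = n_genes, n_pathways = n_pathways,
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, Map(one, sample_pairs$id_a, sample_pairs$id_b))
  rownames(per_sample) <- NULL
  # replicate-averaged comparison: correlate the mean profiles
  ma_g <- rowMeans(cnr_a$log_cnr[, sample_pairs$id_a, drop = FALSE])
  mb_g <- rowMeans(cnr_b$log_cnr[, sample_pairs$id_b, drop = FALSE])
  ma_p <- rowMeans(pas_a$pas[, sample_pairs$id_a, drop = FALSE])
  mb_p <- rowMeans(pas_b$pas[, sample_pairs$id_b, drop = FALSE])
  averaged <- data.frame(
    sample = sprintf("averaged_over_%d", nrow(sample_pairs)),
    r_gene = if (n_genes >= 2) pearson(ma_g, mb_g, method) else NA_real_,
    r_pas = if (n_pathways >= 2) pearson(ma_p, mb_p, method) else NA_real_,
    n_genes = n_genes, n_pathways = n_pathways,
    stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, averaged = averaged,
                 method = method),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("cross-platform concordance (", x$method, ")\n", sep = "")
  print(rbind(x$per_sample, x$averaged), row.names = FALSE)
  invisible(x)
}

#' Long-format scatter tables for concordance plots
#'
#' Per-sample tables of paired gene-level lg CNR values and paired
#' pathway-level PAS values across the two platforms, suitable for plotting
#' platform-A vs platform-B value clouds.
#'
#' @inheritParams paired_concordance
#' @return list with data.frames \code{genes} (sample, gene, lg_cnr_a,
#'   lg_cnr_b) and \code{pathways} (sample, pathway, pas_a, pas_b).
#' @export
scatter_export <- function(cnr_a, cnr_b, pas_a, pas_b, sample_pairs = NULL) {
  if (is.null(sample_pairs)) {
    shared <- intersect(colnames(cnr_a$cnr), colnames(cnr_b$cnr))
    sample_pairs <- data.frame(id_a = shared, id_b = shared,
                               stringsAsFactors = FALSE)
  }
  lab <- ifelse(sample_pairs$id_a == sample_pairs$id_b, sample_pairs$id_a,
                paste(sample_pairs$id_a, sample_pairs$id_b, sep = "|"))
  gene_tabs <- Map(function(ia, ib, s) {
    data.frame(sample = s, gene = rownames(cnr_a$log_cnr),
               lg_cnr_a = cnr_a$log_cnr[, ia], lg_cnr_b = cnr_b$log_cnr[, ib],
               stringsAsFactors = FALSE)
  }, sample_pairs$id_a, sample_pairs$id_b, lab)
  path_tabs <- Map(function(ia, ib, s) {
    data.frame(sample = s, pathway = rownames(pas_a$pas),
               pas_a = pas_a$pas[, ia], pas_b = pas_b$pas[, ib],
               stringsAsFactors = FALSE)
  }, sample_pairs$id_a, sample_pairs$id_b, lab)
  genes <- do.call(rbind, gene_tabs)
  pathways <- do.call(rbind, path_tabs)
  rownames(genes) <- rownames(pathways) <- NULL
  if (!nrow(pathways)) warning("no pathways to export", call. = FALSE)
  list(genes = genes, pathways = pathways)
}

#' Write a concordance report to TSV (and optionally JSON)
#'
#' @param report a \code{concordance_report}.
#' @param path output TSV path.
#' @param json_path optional JSON mirror.
#' @param digits significant digits (<= 0 for full precision).
#' @return invisibly, \code{path}.
#' @export
write_concordance <- function(report, path, json_path = NULL, digits = 6L) {
  stopifnot(inherits(report, "concordance_report"))
  write_tsv(rbind(report$per_sample, report$averaged), path, digits = digits)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(method = report$method,
                              per_sample = report$per_sample,
                              averaged = report$averaged),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
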