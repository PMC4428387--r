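#' BTIF configuration
#'
#' The beyond-tolerance-interval flag (BTIF) marks genes whose expression in
#' a case sample lies significantly outside the control distribution. The
#' tolerance interval is a normal approximation on log10 control expression:
#' a gene is flagged when its case log10 value deviates from the control
#' mean by more than \code{z_threshold} control standard deviations
#' (default 1.96, the two-sided p > 0.05 bound). An optional minimum
#' fold-change gate additionally requires |lg CNR| >= lg(min_fold);
#' \code{min_fold = 1} disables it.
#'
#' @param z_threshold positive z cutoff on the control log10 distribution.
#' @param min_fold minimum fold change (>= 1); 1 disables the gate.
#' @return object of class \code{btif_config}.
#' @export
btif_config <- function(z_threshold = 1.96, min_fold = 1) {
  if (!is.numeric(z_threshold) || length(z_threshold) != 1 || z_threshold <= 0) {
    stop("z_threshold must be a positive number", call. = FALSE)
  }
  if (!is.numeric(min_fold) || length(min_fold) != 1 || min_fold < 1) {
    stop("min_fold must be >= 1", call. = FALSE)
  }
  structure(list(z_threshold = z_threshold, min_fold = min_fold),
            class = "btif_config")
}

#' Default expression floor
#'
#' Zero values (sequencing dropouts, background-subtracted intensities) must
#' be floored before ratios and logarithms are taken. The default floor is
#' 1e-6 times the matrix-wide median of nonzero values, i.e. far below any
#' real measurement but strictly positive.
#'
#' @param ... numeric matrices or vectors pooled for the median.
#' @return positive scalar floor.
#' @export
default_floor <- function(...) {
  v <- unlist(lapply(list(...), function(m) {
    if (inherits(m, "expr_matrix")) m <- m$values
    as.numeric(m)
  }))
  nz <- v[v > 0]
  if (!length(nz)) return(1e-6)
  1e-6 * median(nz)
}

as_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values else x
}

#' Case-to-normal ratios (CNR)
#'
#' For each gene and case sample, the ratio of the case expression level to
#' the average expression over the control samples, both floored at
#' \code{floor} to keep ratios finite and logarithms defined. Returns the
#' ratios and their decimal logarithms; BTIF flags are filled by
#' \code{\link{compute_btif}} (or \code{\link{btif_all_on}}).
#'
#' @param case genes x case-samples matrix (or \code{expr_matrix}).
#' @param controls genes x control-samples matrix (or \code{expr_matrix}),
#'   same genes in the same order as \code{case}.
#' @param floor positive floor applied to case values and to the control
#'   mean; default \code{\link{default_floor}} of both matrices.
#' @param control_average \code{"arithmetic"} (default) or
#'   \code{"geometric"} mean of control expression (geometric on floored
#'   values).
#' @return object of class \code{cnr_table} with elements \code{cnr},
#'   \code{log_cnr} (both genes x case samples), \code{btif} (NULL until
#'   filled), and the \code{floor} used.
#' @export
compute_cnr <- function(case, controls, floor = NULL,
                        control_average = c("arithmetic", "geometric")) {
  control_average <- match.arg(control_average)
  case <- as_values(case); controls <- as_values(controls)
  stopifnot(is.matrix(case), is.matrix(controls))
  if (!identical(rownames(case), rownames(controls))) {
    stop("case and control matrices must carry the same genes in the same order",
         call. = FALSE)
  }
  if (ncol(controls) < 1) stop("at least one control sample required", call. = FALSE)
  if (is.null(floor)) floor <- default_floor(case, controls)
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    stop("floor must be a positive scalar", call. = FALSE)
  }
  ctrl_avg <- switch(control_average,
    arithmetic = rowMeans(controls),
    geometric  = 10^rowMeans(log10(pmax(controls, floor))))
  denom <- pmax(ctrl_avg, floor)
  cnr <- pmax(case, floor) / denom
  structure(list(cnr = cnr, log_cnr = log10(cnr), btif = NULL,
                 floor = floor, control_average = control_average),
            class = "cnr_table")
}

#' @export
print.cnr_table <- function(x, ...) {
  cat(sprintf("cnr_table: %d genes x %d case samples; btif %s\n",
              nrow(x$cnr), ncol(x$cnr),
              if (is.null(x$btif)) "unset" else "set"))
  invisible(x)
}

#' Beyond-tolerance-interval flags (BTIF)
#'
#' Flags each (gene, case sample) as significantly perturbed (1) or
#' essentially normal (0). A gene is flagged when its case log10 expression
#' lies outside mean +/- z * sd of the control log10 expression for that
#' gene (values floored as in \code{\link{compute_cnr}}; sample sd over the
#' controls). If the controls are constant (sd = 0) any differing case value
#' is flagged. With \code{min_fold > 1} the flag additionally requires
#' |lg CNR| >= lg(min_fold).
#'
#' @param case,controls as in \code{\link{compute_cnr}}.
#' @param cnr the \code{cnr_table} from \code{\link{compute_cnr}} (its floor
#'   is reused).
#' @param cfg a \code{\link{btif_config}}.
#' @return the \code{cnr_table} with \code{btif} filled (0/1 matrix).
#' @export
compute_btif <- function(case, controls, cnr, cfg = btif_config()) {
  stopifnot(inherits(cnr, "cnr_table"), inherits(cfg, "btif_config"))
  case <- as_values(case); controls <- as_values(controls)
  if (!identical(rownames(case), rownames(cnr$cnr))) {
    stop("case matrix and cnr table must carry the same genes in the same order",
         call. = FALSE)
  }
  if (ncol(controls) < 2) {
    stop("BTIF needs >= 2 control samples to estimate the tolerance interval; use btif_all_on() for single-control designs",
         call. = FALSE)
  }
  floor <- cnr$floor
  lctrl <- log10(pmax(controls, floor))
  m <- rowMeans(lctrl)
  s <- apply(lctrl, 1, sd)
  lcase <- log10(pmax(case, floor))
  dev <- abs(lcase - m)
  crit1 <- ifelse(s > 0, dev > cfg$z_threshold * s, dev > 0)
  crit2 <- abs(cnr$log_cnr) >= log10(cfg$min_fold)
  btif <- matrix(as.numeric(crit1 & crit2), nrow = nrow(case),
                 dimnames = dimnames(cnr$cnr))
  cnr$btif <- btif
  cnr
}

#' Set every BTIF flag to 1
#'
#' Every gene contributes to PAS regardless of significance. Intended for
#' single-control designs (where a tolerance interval cannot be estimated)
#' and sensitivity analyses.
#'
#' @param cnr a \code{cnr_table}.
#' @return the table with \code{btif} all 1.
#' @export
btif_all_on <- function(cnr) {
  stopifnot(inherits(cnr, "cnr_table"))
  cnr$btif <- matrix(1, nrow = nrow(cnr$cnr), ncol = ncol(cnr$cnr),
                     dimnames = dimnames(cnr$cnr))
  cnr
}

#' Pathway activation strength (PAS)
#'
#' For each pathway p and case sample, the sum over member genes n of
#' ARR(n,p) * BTIF(n) * lg CNR(n). Positive PAS indicates pathway
#' up-regulation relative to the controls, negative PAS down-regulation;
#' the magnitude reflects the extent of the perturbation. Member genes
#' absent from the expression data contribute 0. The score is a plain sum
#' over the member list: it is linear in membership and ignores pathway
#' topology.
#'
#' @param cnr a \code{cnr_table} with \code{btif} filled.
#' @param db a \code{\link{pathway_db}}.
#' @return object of class \code{pas_matrix} with \code{pas} (pathways x
#'   case samples) and \code{n_contributing} (integer counts of members
#'   present in the data with btif = 1).
#' @export
compute_pas <- function(cnr, db) {
  stopifnot(inherits(cnr, "cnr_table"), inherits(db, "pathway_db"))
  if (is.null(cnr$btif)) {
    stop("btif flags are unset; run compute_btif() or btif_all_on() first",
         call. = FALSE)
  }
  ids <- pathway_ids(db)
  samp <- colnames(cnr$cnr)
  mem <- db$members
  present <- mem$gene %in% rownames(cnr$cnr)
  pas <- matrix(0, nrow = length(ids), ncol = length(samp),
                dimnames = list(ids, samp))
  n_contrib <- pas
  if (any(present)) {
    mp <- mem[present, , drop = FALSE]
    g <- mp$gene
    contrib <- mp$arr * cnr$btif[g, , drop = FALSE] * cnr$log_cnr[g, , drop = FALSE]
    fac <- factor(mp$pathway_id, levels = ids)
    pas_s <- rowsum(contrib, group = fac)
    n_s <- rowsum(cnr$btif[g, , drop = FALSE], group = fac)
    pas[rownames(pas_s), ] <- pas_s
    n_contrib[rownames(n_s), ] <- n_s
  }
  uncovered <- ids[!ids %in% mem$pathway_id[present]]
  if (length(uncovered)) {
    warning(sprintf("%d pathway(s) have no member present in the data (PAS = 0): %s",
                    length(uncovered),
                    paste(utils::head(uncovered, 5), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(pas = pas, n_contributing = n_contrib),
            class = "pas_matrix")
}

#' @export
print.pas_matrix <- function(x, ...) {
  cat(sprintf("pas_matrix: %d pathways x %d case samples\n",
              nrow(x$pas), ncol(x$pas)))
  invisible(x)
}

#' Write a PAS matrix (and contributing-gene counts) to TSV
#'
#' @param pas a \code{pas_matrix}.
#' @param path output path for the PAS table.
#' @param counts_path optional output path for the n_contributing table.
#' @param digits significant digits (<= 0 for full precision).
#' @return invisibly, \code{path}.
#' @export
write_pas <- function(pas, path, counts_path = NULL, digits = 6L) {
  stopifnot(inherits(pas, "pas_matrix"))
  write_tsv(matrix_to_df(pas$pas, "pathway"), path, digits = digits)
  if (!is.null(counts_path)) {
    write_tsv(matrix_to_df(pas$n_contributing, "pathway"), counts_path,
              digits = 0L)
  }
  invisible(path)
}
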