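# High-level pipeline drivers shared by the R API and the CLI.

# Decide whether to quantile normalize given the toggle and platform label.
resolve_normalize <- function(normalize, platform_label) {
  switch(normalize,
         yes = TRUE,
         no = FALSE,
         auto = !grepl("seq|ngs", platform_label, ignore.case = TRUE),
         usage_error("normalize must be one of auto/yes/no"))
}

score_one_platform <- function(expr, db, normalize = "auto", floor = NULL,
                               cfg = btif_config(), all_on = FALSE) {
  if (resolve_normalize(normalize, expr$platform_label) && ncol(expr$values) >= 2) {
    expr <- quantile_normalize(expr)
  }
  case <- case_values(expr)
  ctrl <- control_values(expr)
  if (ncol(case) == 0) stop("no case samples (all columns are controls)", call. = FALSE)
  cnr <- compute_cnr(case, ctrl, floor = floor)
  cnr <- if (all_on) btif_all_on(cnr) else compute_btif(case, ctrl, cnr, cfg)
  pas <- compute_pas(cnr, db)
  list(expr = expr, cnr = cnr, pas = pas)
}

#' Score an expression dataset against a pathway database
#'
#' End-to-end scoring: read inputs, optionally quantile normalize, compute
#' CNR and BTIF for every non-control (case) sample, and sum into PAS.
#' Writes \code{pas.tsv} and \code{n_contributing.tsv} to \code{out_dir},
#' plus CNR/BTIF audit dumps when requested.
#'
#' @param expression_path expression TSV (see \code{\link{read_expression}}).
#' @param pathway_path pathway database TSV (see
#'   \code{\link{read_pathway_db}}).
#' @param control_ids character vector of control sample ids, or path to a
#'   one-id-per-line text file.
#' @param out_dir output directory (created if absent); \code{NULL} skips
#'   writing.
#' @param normalize \code{"auto"} (quantile normalize unless the platform
#'   label looks like sequencing), \code{"yes"}, or \code{"no"}.
#' @param floor absolute expression floor; \code{NULL} for the default
#'   (\code{\link{default_floor}}).
#' @param z_threshold,min_fold BTIF parameters, see
#'   \code{\link{btif_config}}.
#' @param btif_all_on set every flag to 1 (single-control designs).
#' @param platform_label label recorded on the matrix (drives
#'   \code{normalize = "auto"}).
#' @param write_audit also write \code{cnr.tsv}, \code{log_cnr.tsv} and
#'   \code{btif.tsv}.
#' @param digits significant digits in outputs (<= 0 for full precision).
#' @return invisibly, a list with \code{expr}, \code{cnr}, \code{pas},
#'   \code{db}, and the per-pathway \code{coverage} of the data.
#' @export
run_score <- function(expression_path, pathway_path, control_ids,
                      out_dir = NULL, normalize = "auto", floor = NULL,
                      z_threshold = 1.96, min_fold = 1,
                      btif_all_on = FALSE, platform_label = "",
                      write_audit = FALSE, digits = 6L) {
  if (length(control_ids) == 1 && file.exists(control_ids)) {
    control_ids <- readLines(control_ids, warn = FALSE)
    control_ids <- control_ids[nzchar(control_ids)]
  }
  db <- read_pathway_db(pathway_path)
  expr <- read_expression(expression_path, control_ids = control_ids,
                          platform_label = platform_label)
  res <- score_one_platform(expr, db, normalize = normalize, floor = floor,
                            cfg = btif_config(z_threshold, min_fold),
                            all_on = btif_all_on)
  cov <- coverage(db, genes(res$expr))
  message(sprintf("scored %d case samples: %d genes, %d pathways (median coverage %.2f)",
                  ncol(res$pas$pas), nrow(res$cnr$cnr), nrow(res$pas$pas),
                  median(cov)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pas(res$pas, file.path(out_dir, "pas.tsv"),
              counts_path = file.path(out_dir, "n_contributing.tsv"),
              digits = digits)
    if (write_audit) {
      write_tsv(matrix_to_df(res$cnr$cnr, "gene"),
                file.path(out_dir, "cnr.tsv"), digits = digits)
      write_tsv(matrix_to_df(res$cnr$log_cnr, "gene"),
                file.path(out_dir, "log_cnr.tsv"), digits = digits)
      write_tsv(matrix_to_df(res$cnr$btif, "gene"),
                file.path(out_dir, "btif.tsv"), digits = 0L)
    }
  }
  invisible(list(expr = res$expr, cnr = res$cnr, pas = res$pas, db = db,
                 coverage = cov))
}

read_pairs_file <- function(path) {
  if (!file.exists(path)) usage_error("sample-pair file not found: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (any(nf != 2L)) {
    usage_error("malformed sample-pair file %s: line %d has %d fields (expected 2: id_a<TAB>id_b)",
                path, which(nf != 2L)[1], nf[which(nf != 2L)[1]])
  }
  p <- read.delim(path, sep = "\t", quote = "", colClasses = "character",
                  header = FALSE)
  names(p) <- c("id_a", "id_b")
  p
}

#' Cross-platform concordance pipeline
#'
#' Runs both platforms' expression matrices through the scoring pipeline on
#' their intersected gene set with a shared pathway database, then computes
#' per-sample gene-level (lg CNR) and pathway-level (PAS) correlations
#' between the platforms, plus a replicate-averaged row. Writes
#' \code{concordance.tsv} (and a JSON mirror) and the scatter tables.
#'
#' @param expression_a,expression_b expression TSV paths for the two
#'   platforms.
#' @param pathway_path shared pathway database TSV.
#' @param controls_a,controls_b control ids (vectors or files) per platform.
#' @param pairs data.frame with columns \code{id_a}, \code{id_b}, or path
#'   to a headerless two-column TSV; \code{NULL} pairs identical ids.
#' @param normalize_a,normalize_b normalization toggles per platform (see
#'   \code{\link{run_score}}).
#' @param label_a,label_b platform labels.
#' @param method correlation estimator (\code{"pearson"} or
#'   \code{"spearman"}).
#' @param out_dir output directory; \code{NULL} skips writing.
#' @inheritParams run_score
#' @return invisibly, a list with the \code{report}
#'   (\code{\link{paired_concordance}}), the two platform score sets, and
#'   the \code{scatter} tables.
#' @export
run_concordance <- function(expression_a, expression_b, pathway_path,
                            controls_a, controls_b, pairs = NULL,
                            normalize_a = "auto", normalize_b = "auto",
                            label_a = "platform_A", label_b = "platform_B",
                            method = "pearson", floor = NULL,
                            z_threshold = 1.96, min_fold = 1,
                            btif_all_on = FALSE,
                            out_dir = NULL, digits = 6L) {
  read_controls <- function(x) {
    if (length(x) == 1 && file.exists(x)) {
      x <- readLines(x, warn = FALSE)
    }
    x[nzchar(x)]
  }
  db <- read_pathway_db(pathway_path)
  ea <- read_expression(expression_a, control_ids = read_controls(controls_a),
                        platform_label = label_a)
  eb <- read_expression(expression_b, control_ids = read_controls(controls_b),
                        platform_label = label_b)
  both <- intersect_genes(ea, eb)
  cfg <- btif_config(z_threshold, min_fold)
  ra <- score_one_platform(both$a, db, normalize = normalize_a, floor = floor,
                           cfg = cfg, all_on = btif_all_on)
  rb <- score_one_platform(both$b, db, normalize = normalize_b, floor = floor,
                           cfg = cfg, all_on = btif_all_on)
  if (is.character(pairs)) pairs <- read_pairs_file(pairs)
  report <- paired_concordance(ra$cnr, rb$cnr, ra$pas, rb$pas,
                               sample_pairs = pairs, method = method)
  scatter <- scatter_export(ra$cnr, rb$cnr, ra$pas, rb$pas, sample_pairs = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_concordance(report, file.path(out_dir, "concordance.tsv"),
                      json_path = file.path(out_dir, "concordance.json"),
                      digits = digits)
    write_tsv(scatter$genes, file.path(out_dir, "scatter_genes.tsv"),
              digits = digits)
    write_tsv(scatter$pathways, file.path(out_dir, "scatter_pathways.tsv"),
              digits = digits)
  }
  invisible(list(report = report, platform_a = ra, platform_b = rb,
                 scatter = scatter, db = db))
}

#' Write a simulated two-platform dataset to disk
#'
#' Writes the fixture pathway database, one expression TSV per platform
#' (case + control columns), the control-id list, and a JSON truth file
#' (perturbed pathways with directions, and the full configuration).
#' Outputs are byte-identical for identical configurations.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the \code{\link{simulate_two_platforms}} output.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  out <- simulate_two_platforms(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pathway_db(out$db, file.path(out_dir, "pathway_db.tsv"))
  write_expression(out$platform_a, file.path(out_dir, "expression_A.tsv"))
  write_expression(out$platform_b, file.path(out_dir, "expression_B.tsv"))
  writeLines(out$platform_a$control_ids, file.path(out_dir, "controls.txt"))
  jsonlite::write_json(list(perturbed = out$truth$perturbed,
                            config = unclass(cfg)),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
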