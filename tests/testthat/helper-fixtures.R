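# Fixture builders and independent oracles used across the suite.

# Small hand-built pathway database: one growth pathway with an activator,
# a repressor and a weak activator, plus a pure-repressor pathway.
tiny_db <- function() {
  pathway_db(data.frame(
    pathway_id = c("P1", "P1", "P1", "P2", "P2"),
    pathway_name = c(rep("Growth", 3), rep("Brake", 2)),
    gene = c("GA", "GB", "GC", "GD", "GE"),
    arr = c(1, -1, 0.5, -1, -1),
    stringsAsFactors = FALSE), version = "test")
}

# Random pathway database for property tests.
random_db <- function(n_pathways = 4, max_genes = 6) {
  rows <- do.call(rbind, lapply(seq_len(n_pathways), function(p) {
    ng <- sample(1:max_genes, 1)
    data.frame(pathway_id = sprintf("RP%02d", p),
               pathway_name = sprintf("random pathway %d", p),
               gene = sprintf("RP%02dG%02d", p, seq_len(ng)),
               arr = sample(ARR_VALUES, ng, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  pathway_db(rows, version = "random")
}

# cnr_table built directly from given log_cnr and btif matrices (genes x
# samples), bypassing compute_cnr, for formula-level tests.
manual_cnr <- function(log_cnr, btif = NULL) {
  structure(list(cnr = 10^log_cnr, log_cnr = log_cnr, btif = btif,
                 floor = 1e-9, control_average = "arithmetic"),
            class = "cnr_table")
}

# Independent triple-loop PAS oracle: iterates pathways, members, samples.
pas_oracle <- function(log_cnr, btif, db) {
  ids <- pathway_ids(db)
  out <- matrix(0, length(ids), ncol(log_cnr),
                dimnames = list(ids, colnames(log_cnr)))
  for (p in ids) {
    mem <- db$members[db$members$pathway_id == p, ]
    for (i in seq_len(nrow(mem))) {
      g <- mem$gene[i]
      if (!g %in% rownames(log_cnr)) next
      for (s in seq_len(ncol(log_cnr))) {
        out[p, s] <- out[p, s] + mem$arr[i] * btif[g, s] * log_cnr[g, s]
      }
    }
  }
  out
}

# Textbook Pearson oracle from the sum formulas.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force quantile normalization oracle: sort each column, average
# across columns per rank, then map each value back through its rank; tied
# values get the mean of the reference values their positions span.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # fractional (tied) ranks span consecutive reference positions
    out[, j] <- vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[c(lo, hi)])
    }, numeric(1))
  }
  out
}

# Expression matrix around a gene x sample grid of given values.
make_expr <- function(values, control_ids = character(), label = "") {
  expression_matrix(values, platform_label = label, control_ids = control_ids)
}

write_lines_tsv <- function(lines, path) {
  writeLines(lines, path, sep = "\n")
  path
}

# Score one simulated platform with the default pipeline (no normalization:
# the simulator emits linear-scale observations directly).
score_platform <- function(out, platform) {
  e <- out[[platform]]
  cnr <- compute_cnr(case_values(e), control_values(e))
  cnr <- compute_btif(case_values(e), control_values(e), cnr)
  list(cnr = cnr, pas = compute_pas(cnr, out$db))
}

# Per-sample mean gene-level and pathway-level cross-platform correlation
# for one simulated dataset.
sim_concordance <- function(seed, ...) {
  out <- simulate_two_platforms(sim_config(seed = seed, ...))
  a <- score_platform(out, "platform_a")
  b <- score_platform(out, "platform_b")
  rep <- paired_concordance(a$cnr, b$cnr, a$pas, b$pas)
  c(r_gene = mean(rep$per_sample$r_gene), r_pas = mean(rep$per_sample$r_pas))
}
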