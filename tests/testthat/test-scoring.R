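test_that("CNR is the floored case / mean-control ratio with decimal logs", {
  case <- matrix(10, 1, 1, dimnames = list("G1", "CASE1"))
  ctrl <- matrix(c(4, 6), 1, 2, dimnames = list("G1", c("C1", "C2")))
  tab <- compute_cnr(case, ctrl, floor = 1e-6)
  expect_equal(unname(tab$cnr[1, 1]), 2)
  expect_equal(unname(tab$log_cnr[1, 1]), log10(2))

  # case equal to the control mean gives the identity ratio
  tab <- compute_cnr(matrix(5, 1, 1, dimnames = list("G1", "CASE1")), ctrl,
                     floor = 1e-6)
  expect_equal(unname(tab$cnr[1, 1]), 1)
  expect_equal(unname(tab$log_cnr[1, 1]), 0)

  # both sides floored: 0/0 becomes floor/floor = 1
  z <- matrix(0, 1, 1, dimnames = list("G1", "CASE1"))
  zc <- matrix(0, 1, 2, dimnames = list("G1", c("C1", "C2")))
  tab <- compute_cnr(z, zc, floor = 0.01)
  expect_equal(unname(tab$cnr[1, 1]), 1)
  expect_equal(unname(tab$log_cnr[1, 1]), 0)

  # geometric control averaging is available behind a flag
  tab <- compute_cnr(case, ctrl, floor = 1e-6, control_average = "geometric")
  expect_equal(unname(tab$cnr[1, 1]), 10 / sqrt(24))

  bad <- matrix(1, 1, 1, dimnames = list("G2", "CASE1"))
  expect_error(compute_cnr(bad, ctrl), "same genes")
  expect_error(compute_cnr(case, ctrl, floor = 0), "positive")
  expect_error(compute_cnr(case, ctrl, floor = -1), "positive")
})

test_that("default floor is tied to the matrix-wide median of nonzero values", {
  case <- matrix(c(0, 10), 2, 1, dimnames = list(c("G1", "G2"), "CASE1"))
  ctrl <- matrix(c(10, 1000), 2, 2, dimnames = list(c("G1", "G2"), c("C1", "C2")))
  expect_equal(default_floor(case, ctrl), 1e-6 * median(c(10, 10, 10, 1000, 1000)))
  expect_equal(default_floor(matrix(0, 2, 2)), 1e-6)
})

test_that("BTIF flags excursions beyond the control tolerance interval", {
  ctrl <- matrix(10^c(5.0, 5.1, 4.9), 1, 3,
                 dimnames = list("G1", c("C1", "C2", "C3")))
  flag_for <- function(lcase, cfg = btif_config()) {
    case <- matrix(10^lcase, 1, 1, dimnames = list("G1", "CASE1"))
    tab <- compute_cnr(case, ctrl, floor = 1e-6)
    tab <- compute_btif(case, ctrl, tab, cfg)
    unname(tab$btif[1, 1])
  }
  # control log10 mean 5.0, sd 0.1: 5.05 is inside 1.96 sd, 6.0 far outside
  expect_equal(flag_for(5.05), 0)
  expect_equal(flag_for(6.0), 1)

  # the optional fold gate vetoes significant but small ratios:
  # 5.25 deviates by 0.25 (> 1.96 * 0.1) yet lg CNR ~ 0.246 < lg 2
  expect_equal(flag_for(5.25), 1)
  expect_equal(flag_for(5.25, btif_config(min_fold = 2)), 0)
  expect_equal(flag_for(6.0, btif_config(min_fold = 2)), 1)

  # constant controls: any differing case value is beyond tolerance
  cc <- matrix(100, 1, 2, dimnames = list("G1", c("C1", "C2")))
  case <- matrix(c(100), 1, 1, dimnames = list("G1", "CASE1"))
  tab <- compute_btif(case, cc, compute_cnr(case, cc, floor = 1e-6))
  expect_equal(unname(tab$btif[1, 1]), 0)
  case2 <- matrix(200, 1, 1, dimnames = list("G1", "CASE1"))
  tab <- compute_btif(case2, cc, compute_cnr(case2, cc, floor = 1e-6))
  expect_equal(unname(tab$btif[1, 1]), 1)

  # a single control cannot define a tolerance interval
  c1 <- matrix(5, 1, 1, dimnames = list("G1", "C1"))
  tab <- compute_cnr(case, c1, floor = 1e-6)
  expect_error(compute_btif(case, c1, tab), "btif_all_on")
  expect_true(all(btif_all_on(tab)$btif == 1))

  expect_error(btif_config(z_threshold = 0), "positive")
  expect_error(btif_config(min_fold = 0.5), ">= 1")
})

test_that("PAS is the ARR- and flag-weighted sum of decimal log ratios", {
  db <- pathway_db(data.frame(pathway_id = "P1", pathway_name = "demo",
                              gene = c("A", "B", "C"), arr = c(1, -1, 0.5)))
  lc <- matrix(c(1, -1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  bt <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  pas <- compute_pas(manual_cnr(lc, bt), db)
  expect_equal(unname(pas$pas["P1", "S1"]), 2)
  expect_equal(unname(pas$n_contributing["P1", "S1"]), 2)

  # every flag off silences the pathway
  pas0 <- compute_pas(manual_cnr(lc, bt * 0), db)
  expect_equal(unname(pas0$pas["P1", "S1"]), 0)
  expect_equal(unname(pas0$n_contributing["P1", "S1"]), 0)

  # an ARR = 0 member never moves the score
  db0 <- pathway_db(data.frame(pathway_id = "P1", pathway_name = "demo",
                               gene = c("A", "B", "C", "D"),
                               arr = c(1, -1, 0.5, 0)))
  lc2 <- rbind(lc, D = 7); bt2 <- rbind(bt, D = 1)
  dimnames(lc2) <- dimnames(bt2) <- list(c("A", "B", "C", "D"), "S1")
  expect_equal(unname(compute_pas(manual_cnr(lc2, bt2), db0)$pas["P1", "S1"]), 2)

  expect_error(compute_pas(manual_cnr(lc), db), "btif")
})

test_that("PAS is linear in membership and invariant to row order", {
  db <- tiny_db()
  set.seed(11)
  g <- db$members$gene
  lc <- matrix(rnorm(length(g) * 2), length(g), 2, dimnames = list(g, c("S1", "S2")))
  bt <- matrix(rbinom(length(g) * 2, 1, 0.6), length(g), 2, dimnames = dimnames(lc))
  base <- compute_pas(manual_cnr(lc, bt), db)

  # duplicating the member list doubles every score
  dbl <- pathway_db(rbind(db$members, db$members), validate = FALSE)
  expect_equal(compute_pas(manual_cnr(lc, bt), dbl)$pas, 2 * base$pas)

  # permuting members and permuting gene rows changes nothing
  perm_members <- pathway_db(db$members[sample(nrow(db$members)), ])
  o <- sample(length(g))
  perm <- compute_pas(manual_cnr(lc[o, , drop = FALSE], bt[o, , drop = FALSE]),
                      perm_members)
  expect_equal(perm$pas, base$pas)
})

test_that("signs follow the activator/repressor convention", {
  up <- matrix(0.5, 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  on <- matrix(1, 3, 1, dimnames = dimnames(up))
  act <- pathway_db(data.frame(pathway_id = "P", pathway_name = "act",
                               gene = c("A", "B", "C"), arr = 1))
  rep_ <- pathway_db(data.frame(pathway_id = "P", pathway_name = "rep",
                                gene = c("A", "B", "C"), arr = -1))
  expect_gt(compute_pas(manual_cnr(up, on), act)$pas["P", "S1"], 0)
  expect_lt(compute_pas(manual_cnr(up, on), rep_)$pas["P", "S1"], 0)
})

test_that("PAS matches a naive triple-loop oracle on random instances", {
  for (seed in 1:40) {
    set.seed(seed)
    db <- random_db(n_pathways = sample(2:5, 1))
    g <- unique(db$members$gene)
    # include data genes outside every pathway; drop some member genes
    g_data <- c(sample(g, ceiling(length(g) * 0.8)), "ZONLYDATA1", "ZONLYDATA2")
    ns <- sample(1:3, 1)
    lc <- matrix(rnorm(length(g_data) * ns), length(g_data), ns,
                 dimnames = list(g_data, paste0("S", seq_len(ns))))
    bt <- matrix(rbinom(length(g_data) * ns, 1, 0.5), length(g_data), ns,
                 dimnames = dimnames(lc))
    got <- suppressWarnings(compute_pas(manual_cnr(lc, bt), db))
    expect_equal(got$pas, pas_oracle(lc, bt, db), tolerance = 1e-12)
    # no flagged member present => zero score
    expect_true(all(got$pas[got$n_contributing == 0] == 0))
  }
})

test_that("pathways with no measured member score zero with a warning", {
  db <- tiny_db()
  lc <- matrix(1, 1, 1, dimnames = list("GA", "S1"))
  bt <- matrix(1, 1, 1, dimnames = list("GA", "S1"))
  expect_warning(pas <- compute_pas(manual_cnr(lc, bt), db), "no member present")
  expect_equal(unname(pas$pas["P2", "S1"]), 0)
  expect_equal(unname(pas$pas["P1", "S1"]), 1)
})
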