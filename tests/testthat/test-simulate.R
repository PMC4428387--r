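test_that("fixture databases have the configured shape and are seeded", {
  db <- make_fixture_db(sim_config())
  expect_equal(length(pathway_ids(db)), 90)
  expect_equal(nrow(db$members), 90 * 30)
  expect_equal(length(unique(db$members$gene)), 2700)  # disjoint membership
  expect_true(all(db$members$arr %in% c(-1, 1)))

  all_act <- make_fixture_db(sim_config(activator_fraction = 1, n_pathways = 5,
                                        genes_per_pathway = 4))
  expect_true(all(all_act$members$arr == 1))

  five <- make_fixture_db(sim_config(arr_levels = "five", seed = 2))
  expect_true(all(five$members$arr %in% c(-1, -0.5, 0.5, 1)))

  expect_identical(make_fixture_db(sim_config(seed = 7)),
                   make_fixture_db(sim_config(seed = 7)))
  expect_false(identical(make_fixture_db(sim_config(seed = 7)),
                         make_fixture_db(sim_config(seed = 8))))
})

test_that("simulation output is reproducible and structurally consistent", {
  cfg <- sim_config(n_pathways = 8, genes_per_pathway = 6, seed = 3)
  out1 <- simulate_two_platforms(cfg)
  out2 <- simulate_two_platforms(cfg)
  expect_identical(out1, out2)

  expect_equal(genes(out1$platform_a), genes(out1$platform_b))
  expect_equal(samples(out1$platform_a), samples(out1$platform_b))
  expect_equal(out1$platform_a$control_ids, sprintf("CTRL%d", 1:4))
  expect_equal(ncol(case_values(out1$platform_a)), 3)
  expect_equal(nrow(out1$truth$perturbed), 4)  # half of 8 pathways
  expect_true(all(out1$truth$perturbed$direction %in% c(-1, 1)))

  # the RNG state of the caller is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_two_platforms(cfg))
  expect_identical(.Random.seed, before)
})

test_that("noiseless observation makes both platforms identical", {
  cfg <- sim_config(n_pathways = 6, genes_per_pathway = 5, seed = 4,
                    sigma_platform = c(0, 0), bias_sd = 0, dropout_rate = c(0, 0))
  out <- simulate_two_platforms(cfg)
  expect_equal(out$platform_a$values, out$platform_b$values)
  expect_equal(out$platform_a$values, 10^out$truth$latent)
})

test_that("a zero effect size yields exactly null PAS in the noiseless limit", {
  cfg <- sim_config(n_pathways = 6, genes_per_pathway = 5, seed = 5, delta = 0,
                    sigma_bio = 0, sigma_platform = c(0, 0), bias_sd = 0,
                    dropout_rate = c(0, 0))
  out <- simulate_two_platforms(cfg)
  cnr <- compute_cnr(case_values(out$platform_a), control_values(out$platform_a))
  pas <- compute_pas(btif_all_on(cnr), out$db)
  expect_true(all(pas$pas == 0))
})

test_that("gene-by-platform bias cancels exactly in the log ratio", {
  cfg <- sim_config(n_pathways = 10, genes_per_pathway = 8, seed = 6,
                    sigma_platform = c(0, 0), dropout_rate = c(0, 0),
                    bias_sd = 0.5)
  out <- simulate_two_platforms(cfg)
  expect_gt(max(abs(log10(out$platform_a$values) - log10(out$platform_b$values))),
            0.1)  # the raw platforms genuinely differ
  a <- compute_cnr(case_values(out$platform_a), control_values(out$platform_a))
  b <- compute_cnr(case_values(out$platform_b), control_values(out$platform_b))
  expect_lt(max(abs(a$log_cnr - b$log_cnr)), 1e-9)
})

test_that("perturbation directions are recovered from PAS signs", {
  # no noise, strong effect: every perturbed pathway's direction is read back
  cfg <- sim_config(seed = 8, delta = 1, sigma_bio = 0, sigma_platform = c(0, 0),
                    bias_sd = 0, dropout_rate = c(0, 0),
                    n_pathways = 20, genes_per_pathway = 10)
  out <- simulate_two_platforms(cfg)
  a <- score_platform(out, "platform_a")
  expect_equal(expected_pas_sign_check(out, a$pas), 1.0)

  # an up-shift of an all-repressor pathway reads out as suppression
  cfg <- sim_config(seed = 9, delta = 1, activator_fraction = 0,
                    perturbed_fraction = 1, sigma_bio = 0,
                    sigma_platform = c(0, 0), bias_sd = 0,
                    dropout_rate = c(0, 0), n_pathways = 4,
                    genes_per_pathway = 6)
  out <- simulate_two_platforms(cfg)
  a <- score_platform(out, "platform_a")
  up <- out$truth$perturbed$pathway_id[out$truth$perturbed$direction == -1]
  # direction -1 shifts repressor members up (delta * dir * sign(arr) > 0)
  for (p in up) {
    expect_lt(mean(a$pas$pas[p, ]), 0)
    expect_equal(unname(sign(mean(a$pas$pas[p, ]))),
                 out$truth$perturbed$direction[out$truth$perturbed$pathway_id == p])
  }
  expect_equal(expected_pas_sign_check(out, a$pas), 1.0)
})

test_that("pathway size averages platform noise out of the score difference", {
  vars <- vapply(c(5, 20, 80), function(g) {
    out <- simulate_two_platforms(sim_config(seed = 10, genes_per_pathway = g))
    a <- score_platform(out, "platform_a")
    b <- score_platform(out, "platform_b")
    n <- pmax((a$pas$n_contributing + b$pas$n_contributing) / 2, 1)
    var(as.vector((a$pas$pas - b$pas$pas) / n))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("pathway-level concordance gains over gene-level grow with pathway size", {
  gaps <- vapply(c(5, 20, 80), function(g) {
    r <- vapply(1:8, sim_concordance, numeric(2), genes_per_pathway = g)
    mean(r["r_pas", ] - r["r_gene", ])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_pathways = 0), "n_pathways")
  expect_error(sim_config(perturbed_fraction = 1.2), "perturbed_fraction")
  expect_error(sim_config(sigma_platform = 1), "sigma_platform")
  expect_error(sim_config(dropout_rate = c(-0.1, 0)), "dropout_rate")
})
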