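#' Simulation configuration
#'
#' Parameters for the two-platform expression simulator. The defaults
#' describe the regime the package's concordance analysis is studied in:
#' 90 pathways of 30 genes (the scale of a curated signaling-pathway
#' knowledge base), a treated-vs-untreated design with a handful of
#' replicates per arm, a moderate pathway-level effect, and two platforms
#' whose per-measurement noise is large relative to that effect — the
#' setting where gene-level ratios disagree across platforms while
#' pathway-level scores still agree.
#'
#' All noise parameters act additively on the log10 scale: an observed
#' value is \code{10^(latent + bias + noise)}, then zeroed with the
#' platform's dropout probability. Gene-by-platform bias is fixed per gene
#' within a platform, so it cancels exactly in the case-to-normal ratio;
#' per-measurement noise and dropout do not.
#'
#' @param n_pathways number of pathways in the fixture database.
#' @param genes_per_pathway members per pathway (disjoint across pathways).
#' @param activator_fraction probability a member is an activator.
#' @param arr_levels \code{"binary"} (ARR in \{-1, 1\}) or \code{"five"}
#'   (draws 0.5/-0.5 for a fifth of each role class).
#' @param n_case,n_control samples per arm.
#' @param perturbed_fraction fraction of pathways truly shifted in cases.
#' @param delta log10 effect size per perturbed member; the shift direction
#'   follows the pathway's simulated activation direction times the sign of
#'   the member's ARR.
#' @param sigma_bio per-sample biological noise sd (log10 units), shared by
#'   both platforms.
#' @param sigma_platform length-2 per-measurement noise sd (log10 units),
#'   one per platform.
#' @param bias_sd sd of the fixed gene-by-platform log10 bias.
#' @param dropout_rate length-2 probability a measurement reads zero.
#' @param base_mean,base_sd log10 mean and sd of baseline gene abundance.
#' @param seed integer seed; every random draw derives from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_pathways = 90, genes_per_pathway = 30,
                       activator_fraction = 0.7,
                       arr_levels = c("binary", "five"),
                       n_case = 3, n_control = 4,
                       perturbed_fraction = 0.5, delta = 0.5,
                       sigma_bio = 0.3,
                       sigma_platform = c(1.0, 0.8),
                       bias_sd = 0.5,
                       dropout_rate = c(0.1, 0.02),
                       base_mean = 2, base_sd = 0.7,
                       seed = 1L) {
  arr_levels <- match.arg(arr_levels)
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      usage_error("%s must be a positive integer (got %s)", nm, paste(x, collapse = ","))
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      usage_error("%s must lie in [0, 1]", nm)
  }
  chk_sd <- function(x, nm, len = 1) {
    if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < 0))
      usage_error("%s must be %s nonnegative number(s)", nm, len)
  }
  chk_count(n_pathways, "n_pathways"); chk_count(genes_per_pathway, "genes_per_pathway")
  chk_count(n_case, "n_case"); chk_count(n_control, "n_control")
  chk_frac(activator_fraction, "activator_fraction")
  chk_frac(perturbed_fraction, "perturbed_fraction")
  chk_sd(sigma_bio, "sigma_bio"); chk_sd(bias_sd, "bias_sd"); chk_sd(base_sd, "base_sd")
  chk_sd(sigma_platform, "sigma_platform", 2)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 2 ||
      any(dropout_rate < 0) || any(dropout_rate > 1)) {
    usage_error("dropout_rate must be two probabilities in [0, 1]")
  }
  if (!is.numeric(delta) || length(delta) != 1) usage_error("delta must be a number")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    usage_error("seed must be an integer")
  }
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 activator_fraction = activator_fraction,
                 arr_levels = arr_levels,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 perturbed_fraction = perturbed_fraction, delta = delta,
                 sigma_bio = sigma_bio, sigma_platform = sigma_platform,
                 bias_sd = bias_sd, dropout_rate = dropout_rate,
                 base_mean = base_mean, base_sd = base_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw the member table without touching the seed (callers seed the stream)
draw_db <- function(cfg) {
  np <- cfg$n_pathways; gp <- cfg$genes_per_pathway
  ids <- sprintf("PW%03d", seq_len(np))
  gene <- sprintf("%sG%03d", rep(ids, each = gp), rep(seq_len(gp), np))
  af <- cfg$activator_fraction
  arr <- if (cfg$arr_levels == "binary") {
    sample(c(1, -1), np * gp, replace = TRUE, prob = c(af, 1 - af))
  } else {
    sample(c(1, 0.5, -0.5, -1), np * gp, replace = TRUE,
           prob = c(0.8 * af, 0.2 * af, 0.2 * (1 - af), 0.8 * (1 - af)))
  }
  pathway_db(data.frame(pathway_id = rep(ids, each = gp),
                        pathway_name = rep(sprintf("synthetic pathway %d", seq_len(np)), each = gp),
                        gene = gene, arr = arr, stringsAsFactors = FALSE),
             version = sprintf("synthetic fixture (seed %d)", cfg$seed))
}

#' Synthetic fixture pathway database
#'
#' Draws a pathway database with disjoint memberships (each gene belongs to
#' exactly one pathway, which keeps expected PAS analytically tractable) and
#' ARR weights sampled by role. Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{pathway_db}}.
#' @export
make_fixture_db <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, draw_db(cfg))
}

#' Simulate the same samples observed on two platforms
#'
#' Generates latent log10 expression for control and case samples (baseline
#' per gene + biological noise; case samples additionally shift the members
#' of the perturbed pathways by \code{delta} in the direction implied by the
#' pathway's activation direction and each member's ARR sign), then passes
#' the SAME latent values through each platform's observation model:
#' fixed gene-by-platform bias, per-measurement noise, and dropout, all on
#' the log10 scale before exponentiation. Fully reproducible from the seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return object of class \code{sim_output}: list with \code{db}, the two
#'   \code{expr_matrix} objects \code{platform_a} / \code{platform_b}
#'   (case + control columns, controls annotated), and \code{truth}
#'   (latent matrix, perturbed pathway directions, the config).
#' @export
simulate_two_platforms <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    db <- draw_db(cfg)
    gene <- db$members$gene
    ng <- length(gene)
    ctrl <- sprintf("CTRL%d", seq_len(cfg$n_control))
    case <- sprintf("CASE%d", seq_len(cfg$n_case))
    samp <- c(ctrl, case)
    ns <- length(samp)

    base <- rnorm(ng, cfg$base_mean, cfg$base_sd)
    latent <- base + matrix(rnorm(ng * ns, 0, cfg$sigma_bio), ng, ns)
    dimnames(latent) <- list(gene, samp)

    n_pert <- round(cfg$perturbed_fraction * cfg$n_pathways)
    pert_ids <- sample(pathway_ids(db), n_pert)
    direction <- sample(c(1, -1), n_pert, replace = TRUE)
    perturbed <- data.frame(pathway_id = pert_ids, direction = direction,
                            stringsAsFactors = FALSE)
    if (n_pert > 0) {
      idx <- match(db$members$pathway_id, pert_ids)
      hit <- !is.na(idx)
      shift <- direction[idx[hit]] * cfg$delta * sign(db$members$arr[hit])
      latent[hit, case] <- latent[hit, case] + shift
    }

    observe <- function(k, label) {
      bias <- rnorm(ng, 0, cfg$bias_sd)
      eps <- matrix(rnorm(ng * ns, 0, cfg$sigma_platform[k]), ng, ns)
      obs <- 10^(latent + bias + eps)
      drop <- matrix(runif(ng * ns) < cfg$dropout_rate[k], ng, ns)
      obs[drop] <- 0
      dimnames(obs) <- dimnames(latent)
      expression_matrix(obs, platform_label = label, control_ids = ctrl)
    }
    platform_a <- observe(1, "platform_A (seq-like)")
    platform_b <- observe(2, "platform_B (array-like)")

    structure(list(db = db, platform_a = platform_a, platform_b = platform_b,
                   truth = list(latent = latent, perturbed = perturbed,
                                config = cfg)),
              class = "sim_output")
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("sim_output: %d genes x (%d control + %d case) samples on 2 platforms; %d/%d pathways perturbed\n",
              nrow(x$truth$latent), cfg$n_control, cfg$n_case,
              nrow(x$truth$perturbed), cfg$n_pathways))
  invisible(x)
}

#' Direction recovery for the simulated perturbations
#'
#' Fraction of truly perturbed pathways whose mean case PAS carries the
#' sign of the simulated activation direction. With no noise and a nonzero
#' effect this is 1 by construction of the score; with a zero effect the
#' sign is a coin flip and the fraction hovers around 0.5.
#'
#' @param out a \code{sim_output}.
#' @param pas a \code{pas_matrix} computed from \code{out} (either
#'   platform).
#' @return fraction in [0, 1]; \code{NA} if no pathway was perturbed.
#' @export
expected_pas_sign_check <- function(out, pas) {
  stopifnot(inherits(out, "sim_output"), inherits(pas, "pas_matrix"))
  pert <- out$truth$perturbed
  if (!nrow(pert)) return(NA_real_)
  mean_pas <- rowMeans(pas$pas[pert$pathway_id, , drop = FALSE])
  mean(sign(mean_pas) == pert$direction)
}
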