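#' Configuration for the synthetic multi-cohort generator
#'
#' Defines a simulated microarray study with the statistical structure the
#' downstream analysis assumes: a tightly co-expressed gene block driven by
#' one latent factor, seed (candidate) genes optionally coupled to that
#' factor, per-gene proportional-hazards effects on recurrence, a binary
#' lymph-node status linked to the factor through a logistic model, and
#' right-censored follow-up. Defaults emulate a four-cohort breast-cancer
#' recurrence study of roughly 920 cases: node prevalence 12%, about 40%
#' recurrence events, a six-gene immunoglobulin block at pairwise Spearman
#' 0.95 anchored by the seed genes LST1 and IGHM, per-gene protective block
#' effects on the Table-3 scale (log-HR about -0.16), and cohort-specific
#' location/scale shifts standing in for platform differences.
#'
#' @param n_samples Samples per cohort.
#' @param n_cohorts Number of cohorts.
#' @param n_genes Total genes, including seeds and block genes.
#' @param seed_genes Character vector of seed (candidate) gene symbols.
#' @param block_genes Character vector: the planted co-expressed block
#'   (disjoint from `seed_genes`).
#' @param block_rho Target pairwise Spearman correlation within the block,
#'   in (0, 1).
#' @param coupled_seeds Seeds coupled to the block's latent factor (subset of
#'   `seed_genes`); the remaining seeds are independent noise.
#' @param seed_rho Target Spearman of a coupled seed with a block gene;
#'   defaults to `block_rho`.
#' @param gene_log_hr True per-gene log hazard ratio (the Cox coefficient B).
#'   Either a single number applied to every block gene, or a named numeric
#'   vector over arbitrary genes. Unnamed genes have no effect.
#' @param node_log_hr Log hazard ratio of node-positive status.
#' @param node_log_or Log odds ratio of node positivity per unit of the
#'   latent factor.
#' @param node_prevalence Marginal node-positive proportion.
#' @param baseline_hazard Exponential baseline hazard (events per year).
#' @param censor_rate Target censored fraction in [0, 1).
#' @param max_followup Administrative censoring horizon in years.
#' @param cohort_shift List (length `n_cohorts`) of `c(location, scale)`
#'   applied to each cohort's expression after generation (`x * scale +
#'   location`); the clinical structure is never shifted. `NULL` gives
#'   distinct platform-like shifts with cohort 1 as the unshifted reference.
#' @param missing_event_rate,missing_node_rate Proportions of samples whose
#'   recurrence event or node status is set missing, exercising listwise
#'   deletion downstream.
#' @param rng_seed Integer seed; the whole simulation is reproducible
#'   given this value.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 230,
                       n_cohorts = 4,
                       n_genes = 400,
                       seed_genes = c("LST1", "IGHM",
                                      sprintf("CAND%02d", 3:34)),
                       block_genes = c("IGHA1", "IGHD", "IGHG1",
                                       "IGHG3", "IGLC2", "IGLJ3"),
                       block_rho = 0.95,
                       coupled_seeds = c("LST1", "IGHM"),
                       seed_rho = block_rho,
                       gene_log_hr = -0.16,
                       node_log_hr = 0.5,
                       node_log_or = 1.1,
                       node_prevalence = 0.12,
                       baseline_hazard = 0.08,
                       censor_rate = 0.6,
                       max_followup = 15,
                       cohort_shift = NULL,
                       missing_event_rate = 0,
                       missing_node_rate = 0,
                       rng_seed = 1L) {
  if (block_rho <= 0 || block_rho >= 1) stop("block_rho must be in (0, 1)")
  if (seed_rho <= 0 || seed_rho >= 1) stop("seed_rho must be in (0, 1)")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (length(intersect(seed_genes, block_genes)))
    stop("seed_genes and block_genes must be disjoint")
  if (!all(coupled_seeds %in% seed_genes))
    stop("coupled_seeds must be a subset of seed_genes")
  if (n_genes < length(seed_genes) + length(block_genes))
    stop("n_genes smaller than the named seed + block genes")
  if (is.null(names(gene_log_hr))) {
    if (length(gene_log_hr) != 1L)
      stop("unnamed gene_log_hr must be a single value (applied to the block)")
    gene_log_hr <- stats::setNames(rep(gene_log_hr, length(block_genes)),
                                   block_genes)
  }
  if (is.null(cohort_shift)) {
    pool <- list(c(0, 1), c(2, 1.5), c(-1.5, 0.7), c(3, 2))
    cohort_shift <- rep(pool, length.out = n_cohorts)
  }
  if (length(cohort_shift) != n_cohorts)
    stop("cohort_shift must have one (location, scale) pair per cohort")
  structure(list(n_samples = n_samples, n_cohorts = n_cohorts,
                 n_genes = n_genes, seed_genes = seed_genes,
                 block_genes = block_genes, block_rho = block_rho,
                 coupled_seeds = coupled_seeds, seed_rho = seed_rho,
                 gene_log_hr = gene_log_hr, node_log_hr = node_log_hr,
                 node_log_or = node_log_or,
                 node_prevalence = node_prevalence,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, max_followup = max_followup,
                 cohort_shift = cohort_shift,
                 missing_event_rate = missing_event_rate,
                 missing_node_rate = missing_node_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Loading of a gene on the shared factor needed for a target pairwise
# Spearman between two such genes. For bivariate Gaussians the population
# Spearman rho_S and Pearson r satisfy r = 2 sin(pi * rho_S / 6); two genes
# with loading a (unit total variance) have Pearson a^2, so a = sqrt(r).
factor_loading <- function(rho_s) {
  r <- 2 * sin(pi * rho_s / 6)
  if (r <= 0 || r >= 1) stop("infeasible Spearman target: ", rho_s)
  sqrt(r)
}

#' Generate one synthetic cohort
#'
#' Block genes are noisy linear functions of a single standard-normal latent
#' factor, with loadings calibrated in closed form so that the pairwise
#' Spearman correlation among block genes equals `block_rho` (and
#' seed-to-block Spearman about `sqrt(seed_rho * block_rho)` scale for
#' coupled seeds). Survival times follow an exponential proportional-hazards
#' model with linear predictor `sum_g B_g * (x_g - mu_g) + node_log_hr *
#' node`; node status is Bernoulli with a logit linear in the latent factor,
#' its intercept solved so the marginal prevalence matches
#' `node_prevalence`. Censoring combines an administrative horizon with an
#' independent exponential censoring time whose rate is solved so the
#' expected censored fraction matches `censor_rate`.
#'
#' @param cfg A [sim_config()].
#' @param cohort_index Which cohort to generate (1-based); fixes the RNG
#'   substream and the cohort label.
#' @return A [cohort_study()] for that cohort (no cohort shift applied; see
#'   [generate_multi_cohort()]).
#' @export
generate_cohort <- function(cfg, cohort_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  label <- paste0("cohort", cohort_index)

  # gene-level constants shared across cohorts
  set.seed(cfg$rng_seed)
  genes <- c(cfg$seed_genes, cfg$block_genes)
  n_noise <- cfg$n_genes - length(genes)
  if (n_noise > 0) genes <- c(genes, sprintf("GENE%04d", seq_len(n_noise)))
  mu <- stats::setNames(stats::rnorm(length(genes), mean = 7, sd = 0.8),
                        genes)

  set.seed(cfg$rng_seed + cohort_index)
  u <- stats::rnorm(n)                     # shared latent factor
  a_block <- factor_loading(cfg$block_rho)
  a_seed <- factor_loading(cfg$seed_rho)

  expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, sprintf("%s_S%04d", label,
                                                seq_len(n))))
  loading <- stats::setNames(numeric(length(genes)), genes)
  loading[cfg$block_genes] <- a_block
  loading[cfg$coupled_seeds] <- a_seed
  for (g in genes) {
    a <- loading[[g]]
    if (a > 0) expr[g, ] <- a * u + sqrt(1 - a^2) * expr[g, ]
  }
  expr <- expr + mu[rownames(expr)]

  # node status: logit-linear in the latent factor, intercept solved for
  # the marginal prevalence
  alpha <- stats::uniroot(function(a)
    mean(stats::plogis(a + cfg$node_log_or * u)) - cfg$node_prevalence,
    interval = c(-30, 30))$root
  node <- stats::rbinom(n, 1L, stats::plogis(alpha + cfg$node_log_or * u))

  # survival: exponential PH on centred expression + node
  absent <- setdiff(names(cfg$gene_log_hr), genes)
  if (length(absent))
    warning("gene_log_hr entries for absent gene(s) ignored: ",
            paste(absent, collapse = ", "))
  b <- cfg$gene_log_hr[names(cfg$gene_log_hr) %in% genes]
  lp <- rep(0, n)
  if (length(b))
    lp <- drop(crossprod(expr[names(b), , drop = FALSE] - mu[names(b)], b))
  lp <- lp + cfg$node_log_hr * node
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(lp))

  target_events <- 1 - cfg$censor_rate
  ev_frac <- function(rate) mean((t_event <= cfg$max_followup) *
                                   exp(-rate * t_event))
  if (ev_frac(0) <= target_events) {
    c_rate <- 0
    t_cens <- rep(Inf, n)
  } else {
    c_rate <- stats::uniroot(function(r) ev_frac(r) - target_events,
                             interval = c(1e-9, 50))$root
    t_cens <- stats::rexp(n, rate = c_rate)
  }
  followup <- pmin(t_event, t_cens, cfg$max_followup)
  event <- as.integer(t_event <= pmin(t_cens, cfg$max_followup))
  followup <- pmax(followup, 1e-6)         # strictly positive

  if (cfg$missing_event_rate > 0) {
    drop_ev <- stats::runif(n) < cfg$missing_event_rate
    event[drop_ev] <- NA_integer_
  }
  if (cfg$missing_node_rate > 0) {
    drop_nd <- stats::runif(n) < cfg$missing_node_rate
    node[drop_nd] <- NA_integer_
  }

  clin <- data.frame(sample_id = colnames(expr),
                     recurrence_event = event,
                     followup_time = followup,
                     node_status = node,
                     cohort = label,
                     stringsAsFactors = FALSE)
  cohort_study(expr_matrix(expr, cohort = label), clin, provenance = label)
}

#' Generate all cohorts of a synthetic study
#'
#' Runs [generate_cohort()] for each cohort and applies that cohort's
#' location/scale shift to the expression values (`x * scale + location`),
#' emulating platform differences that the harmonization step must undo.
#' Clinical variables are never shifted.
#'
#' @param cfg A [sim_config()].
#' @return List of [cohort_study()] objects, one per cohort.
#' @export
generate_multi_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_cohorts), function(i) {
    s <- generate_cohort(cfg, i)
    sh <- cfg$cohort_shift[[i]]
    shifted <- unclass(s$expression) * sh[2L] + sh[1L]
    cohort_study(expr_matrix(shifted, cohort = s$provenance),
                 s$clinical, provenance = s$provenance)
  })
}

#' Generate, harmonize and merge a full synthetic study
#'
#' Convenience wrapper: generates all cohorts, aligns every non-reference
#' cohort to the first cohort's pooled moments with
#' [harmonize_to_reference()], and merges with [merge_cohorts()].
#'
#' @param cfg A [sim_config()].
#' @param reference_index Cohort used as harmonization reference (default 1).
#' @return A merged [cohort_study()].
#' @export
simulate_study <- function(cfg, reference_index = 1L) {
  cohorts <- generate_multi_cohort(cfg)
  ref <- cohorts[[reference_index]]$expression
  harmonized <- lapply(seq_along(cohorts), function(i) {
    s <- cohorts[[i]]
    if (i == reference_index) return(s)
    cohort_study(harmonize_to_reference(s$expression, ref),
                 s$clinical, provenance = s$provenance)
  })
  merge_cohorts(harmonized)
}
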