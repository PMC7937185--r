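# Simulation configuration: the hierarchical study design and the generating
# parameters for every level of behavioral variance.

TRAITS <- c("activity", "meandering", "exploration", "aggression")
MEAN_COVARIATES <- c("intercept", "worker_size", "colony_size",
                     "myrmica_nests", "allo_nests", "habitat", "repeat_index")
DISP_COVARIATES <- MEAN_COVARIATES[MEAN_COVARIATES != "repeat_index"]

#' Default generating parameters of the synthetic study
#'
#' Per-trait mean-model coefficients, dispersion-model coefficients,
#' level-specific trait correlation matrices, raw-unit trait scales and the
#' productivity link used as [sim_config()] defaults. Exported so analyses
#' can modify one block while keeping the rest of the study conditions.
#'
#' @return matrix, list of matrices, or list, depending on the function.
#' @name sim_defaults
#' @rdname sim_config
#' @export
default_beta <- function() {
  m <- cbind(
    activity    = c(-0.11, -0.06, 0.16, 0.04, -0.22, 0.08, -0.17),
    meandering  = c(0.13, 0.007, -0.072, -0.067, 0.21, -0.15, 0.01),
    exploration = c(-0.10, 0.05, 0.14, 0.04, -0.09, 0.03, -0.01),
    aggression  = c(0.35, -0.03, 0.11, -0.004, -0.14, -0.29, 0.004)
  )
  rownames(m) <- MEAN_COVARIATES
  m
}

#' @rdname sim_config
#' @export
default_gamma <- function() {
  m <- cbind(
    activity    = c(-0.69, 0.03, -0.07, 0.097, -0.098, 0.13),
    meandering  = c(-1.02, -0.06, -0.13, 0.02, 0.07, 0.21),
    exploration = c(-0.44, -0.06, -0.16, -0.05, 0.01, 0.05),
    aggression  = c(-2.00, 0.19, -0.26, -0.35, -0.04, -0.98)
  )
  rownames(m) <- DISP_COVARIATES
  m
}

#' @rdname sim_config
#' @export
default_level_correlations <- function() {
  mk <- function(v) {
    m <- diag(4)
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    dimnames(m) <- list(TRAITS, TRAITS)
    m
  }
  # lower-triangle order: (mea,act) (exp,act) (agg,act) (exp,mea) (agg,mea) (agg,exp)
  list(
    colony     = mk(c(-0.83, 0.89, 0.15, -0.76, -0.23, 0.28)),
    individual = mk(c(-0.89, 0.91, 0.35, -0.86, -0.27, 0.35)),
    residual   = mk(c(-0.60, 0.02, -0.04, -0.003, -0.029, 0.027))
  )
}

#' @rdname sim_config
#' @export
default_trait_scales <- function() {
  list(
    activity     = list(transform = "identity", mean = 150, sd = 55),
    meandering   = list(transform = "log1p", mean = 2.5, sd = 0.5),
    exploration  = list(transform = "identity", mean = 11, sd = 4.5),
    aggression   = list(transform = "log1p", mean = 0.75, sd = 0.22),
    displacement = list(transform = "log1p", mean = 7.3, sd = 0.6)
  )
}

#' @rdname sim_config
#' @export
default_productivity_link <- function() {
  list(
    coefficients = c(
      intercept = 6.39, habitat = -0.28,
      mean_activity = -0.23, sd_activity = 0.24,
      mean_meandering = 0.88, sd_meandering = -0.95,
      mean_exploration = 0.73, sd_exploration = -0.20,
      mean_aggression = -0.13, sd_aggression = 0.25,
      mean_displacement = -0.29, sd_displacement = -0.44
    ),
    theta = 5,
    proportions = c(n_larvae = 0.50, pupae_worker = 0.30, pupae_male = 0.08,
                    pupae_gyne = 0.07, winged_gynes = 0.03, winged_males = 0.02)
  )
}

#' Simulation configuration for the hierarchical behavioral study design
#'
#' Builds the full parameterisation of the synthetic-data generator: the
#' sampling design (colonies per habitat, focal workers per colony, repeats
#' per assay), covariate distributions, and the generating parameters of the
#' double hierarchical model for each trait — mean-model coefficients `beta`,
#' dispersion-model coefficients `gamma` (on the log residual-SD scale),
#' among-individual and among-colony intercept variances, the
#' individual-level covariance between mean and log-residual-SD intercepts,
#' and trait-by-trait correlation matrices at the colony, individual and
#' residual levels. Colony-level nest-displacement behavior and
#' negative-binomial productivity outcomes have their own parameter blocks.
#'
#' All behavioral parameters are on the standardized (z-score) analysis
#' scale; `trait_scales` maps latent values to raw measurement units
#' (cm travelled, degrees/cm, grid squares, 0-3 aggression score, seconds).
#' Defaults reproduce the field study design: 12 + 11 colonies, 12 focal
#' workers each, 3 repeats per assay, colony sizes spanning 219-5964 workers.
#'
#' @param n_colonies_per_habitat integer pair: colonies in seminatural and
#'   invaded habitat.
#' @param n_workers_per_colony focal workers sampled per colony.
#' @param n_repeats_per_assay repeated trials per worker per assay.
#' @param colony_size_range min/max adult workers; sizes are drawn
#'   log-uniformly over this range.
#' @param myrmica_nest_range,allo_nest_range min/max conspecific and
#'   allospecific nest counts per 9 m^2 (truncated-Poisson draws).
#' @param beta 7 x 4 matrix (or length-7 vector recycled across traits) of
#'   mean-model coefficients, rows `intercept, worker_size, colony_size,
#'   myrmica_nests, allo_nests, habitat, repeat_index`.
#' @param gamma 6 x 4 matrix (or length-6 vector) of dispersion-model
#'   coefficients (same rows minus `repeat_index`).
#' @param sigma2_id_mu among-individual variance of mean intercepts
#'   (scalar or per-trait vector).
#' @param sigma2_colony among-colony variance of mean intercepts.
#' @param sigma2_id_sigma among-individual variance of log-residual-SD
#'   intercepts.
#' @param cov_mu_sigma covariance between the two individual intercepts;
#'   must satisfy `|cov| <= sqrt(sigma2_id_mu * sigma2_id_sigma)`.
#' @param level_correlation_matrices list with elements `colony`,
#'   `individual`, `residual`: 4 x 4 trait correlation matrices.
#' @param displacement list of colony-level nest-displacement parameters:
#'   `beta` (7), `gamma` (6), `sigma2_mu`, `sigma2_sigma`, `cov_mu_sigma`.
#' @param productivity_link list with `coefficients` (named log-scale effects
#'   of standardized colony trait means/SDs and habitat on expected total
#'   production), `theta` (NB size), `proportions` (split of total production
#'   into brood components).
#' @param worker_size_mean,worker_size_sd head-width distribution (micrometres),
#'   Normal clipped to positive.
#' @param trait_scales per-trait raw-unit transform/mean/sd, see Details.
#' @param discretize_aggression if `TRUE`, aggression raw values are cut to
#'   the ordinal 0-3 score; default keeps the continuous latent scale so the
#'   Gaussian model assumptions hold exactly.
#' @param seed integer master seed; every generator stage derives its own
#'   substream from it.
#'
#' @return object of class `sim_config` (validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' dat <- generate_dataset(cfg)
#' nrow(dat$trials)  # 23 colonies x 12 workers x 3 repeats x 4 assays
#' @export
sim_config <- function(n_colonies_per_habitat = c(12L, 11L),
                       n_workers_per_colony = 12L,
                       n_repeats_per_assay = 3L,
                       colony_size_range = c(219L, 5964L),
                       myrmica_nest_range = c(0L, 9L),
                       allo_nest_range = c(0L, 3L),
                       beta = default_beta(),
                       gamma = default_gamma(),
                       sigma2_id_mu = c(activity = 0.58, meandering = 0.36,
                                        exploration = 0.45, aggression = 0.57),
                       sigma2_colony = c(activity = 0.43, meandering = 0.43,
                                         exploration = 0.49, aggression = 0.61),
                       sigma2_id_sigma = c(activity = 0.26, meandering = 0.70,
                                           exploration = 0.40, aggression = 0.90),
                       cov_mu_sigma = NULL,
                       level_correlation_matrices = default_level_correlations(),
                       displacement = list(
                         beta = c(0.11, -0.10, -0.49, 0.06, -0.32, -0.09, -0.10),
                         gamma = c(-0.03, 0.06, 0.12, 0.14, -0.02, -0.19),
                         sigma2_mu = 0.34, sigma2_sigma = 0.50,
                         cov_mu_sigma = -0.35 * sqrt(0.34 * 0.50)
                       ),
                       productivity_link = default_productivity_link(),
                       worker_size_mean = 1000,
                       worker_size_sd = 60,
                       trait_scales = default_trait_scales(),
                       discretize_aggression = FALSE,
                       seed = 1L) {
  expand_trait <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, length(TRAITS))
    if (length(x) != length(TRAITS))
      stop_invariant(sprintf("%s must have length 1 or %d", what, length(TRAITS)))
    stats::setNames(as.numeric(x), TRAITS)
  }
  expand_coef <- function(m, rows, what) {
    if (is.null(dim(m))) m <- matrix(m, nrow = length(rows), ncol = length(TRAITS))
    if (nrow(m) != length(rows) || ncol(m) != length(TRAITS))
      stop_invariant(sprintf("%s must be a %d x %d matrix", what, length(rows), length(TRAITS)))
    dimnames(m) <- list(rows, TRAITS)
    m
  }
  sigma2_id_mu <- expand_trait(sigma2_id_mu, "sigma2_id_mu")
  sigma2_colony <- expand_trait(sigma2_colony, "sigma2_colony")
  sigma2_id_sigma <- expand_trait(sigma2_id_sigma, "sigma2_id_sigma")
  if (is.null(cov_mu_sigma)) {
    # default mean/rIIV correlations per trait on the individual level
    r_default <- c(activity = 0.21, meandering = 0.71,
                   exploration = -0.96, aggression = 0.09)
    cov_mu_sigma <- r_default * sqrt(pmax(sigma2_id_mu, 0) * pmax(sigma2_id_sigma, 0))
  }
  cov_mu_sigma <- expand_trait(cov_mu_sigma, "cov_mu_sigma")

  cfg <- list(
    n_colonies_per_habitat = as.integer(n_colonies_per_habitat),
    n_workers_per_colony = as.integer(n_workers_per_colony),
    n_repeats_per_assay = as.integer(n_repeats_per_assay),
    colony_size_range = as.integer(colony_size_range),
    myrmica_nest_range = as.integer(myrmica_nest_range),
    allo_nest_range = as.integer(allo_nest_range),
    beta = expand_coef(beta, MEAN_COVARIATES, "beta"),
    gamma = expand_coef(gamma, DISP_COVARIATES, "gamma"),
    sigma2_id_mu = sigma2_id_mu,
    sigma2_colony = sigma2_colony,
    sigma2_id_sigma = sigma2_id_sigma,
    cov_mu_sigma = cov_mu_sigma,
    level_correlation_matrices = level_correlation_matrices,
    displacement = displacement,
    productivity_link = productivity_link,
    worker_size_mean = worker_size_mean,
    worker_size_sd = worker_size_sd,
    trait_scales = trait_scales,
    discretize_aggression = isTRUE(discretize_aggression),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant: positive counts, non-negative
#' variances, the Cauchy-Schwarz bound on the mean/log-SD intercept
#' covariance, and symmetry/unit-diagonal/positive-semidefiniteness of each
#' level correlation matrix. Errors name the violated invariant.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(n_colonies_per_habitat) != 2L || any(n_colonies_per_habitat < 1L))
      stop_invariant("n_colonies_per_habitat must be a pair of counts >= 1")
    if (!is_count(n_workers_per_colony))
      stop_invariant("n_workers_per_colony must be a count >= 1")
    if (!is_count(n_repeats_per_assay))
      stop_invariant("n_repeats_per_assay must be a count >= 1")
    if (length(colony_size_range) != 2L || any(colony_size_range < 1L) ||
        colony_size_range[1] > colony_size_range[2])
      stop_invariant("colony_size_range must be an increasing pair of positive integers")
    for (rng in list(myrmica_nest_range, allo_nest_range))
      if (length(rng) != 2L || any(rng < 0L) || rng[1] > rng[2])
        stop_invariant("nest count ranges must be ordered pairs of counts >= 0")
    if (any(sigma2_id_mu < 0) || any(sigma2_colony < 0) || any(sigma2_id_sigma < 0))
      stop_invariant("all variances must be >= 0")
    bound <- sqrt(sigma2_id_mu * sigma2_id_sigma)
    if (any(abs(cov_mu_sigma) > bound + 1e-12))
      stop_invariant("|cov_mu_sigma| must be <= sqrt(sigma2_id_mu * sigma2_id_sigma)")
    for (lev in c("colony", "individual", "residual"))
      check_corr_matrix(level_correlation_matrices[[lev]],
                        paste0("level_correlation_matrices$", lev))
    d <- displacement
    if (d$sigma2_mu < 0 || d$sigma2_sigma < 0)
      stop_invariant("displacement variances must be >= 0")
    if (abs(d$cov_mu_sigma) > sqrt(d$sigma2_mu * d$sigma2_sigma) + 1e-12)
      stop_invariant("|displacement cov_mu_sigma| must be <= sqrt(sigma2_mu * sigma2_sigma)")
    if (productivity_link$theta <= 0)
      stop_invariant("productivity NB size (theta) must be > 0")
  })
  invisible(cfg)
}
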