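## Synthetic communities along a known disturbance gradient.
##
## Each site s carries a disturbance level g_s in [0, 1] (0 = pristine).
## Family f occupies site s with probability plogis(alpha_f + beta_f * g_s);
## the default occupancy-tolerance link is linear in the tolerance score,
## beta_f = -b * (score_f - 5): families scoring above the neutral midpoint
## decline with disturbance, tolerant low-scoring families do not. When
## present, abundance is 1 + NegBin(mu, theta) so presence and counts stay
## consistent. Environmental covariates respond linearly to the gradient
## with Gaussian noise, on scales chosen near the survey's summary table
## (ammonia and conductivity rise with disturbance, dissolved-oxygen
## saturation and elevation fall).

#' Specification of a synthetic disturbance-gradient community
#'
#' @param n_sites number of sites.
#' @param gradient disturbance values in `[0, 1]`, one per site (default
#'   evenly spaced from 0 to 1).
#' @param scores named integer vector of family tolerance scores used for the
#'   occupancy-tolerance link; defaults to the packaged BMWP-Col scores.
#'   Unscored families may be added through `extra_families` (they get
#'   `beta = 0`).
#' @param alpha baseline occupancy intercept (logit scale) shared by all
#'   families.
#' @param b slope of the occupancy-tolerance link, `beta_f = -b *
#'   (score_f - 5)`; must be `> 0` so that sensitive families (score >= 7)
#'   decline with disturbance. The default 1.5 makes score-10 families all
#'   but extirpated at full disturbance (occupancy < 1%).
#' @param mu,theta negative-binomial mean and dispersion of the
#'   abundance-when-present model (counts are `1 + NB(mu, theta)`).
#' @param extra_families character vector of families without tolerance
#'   scores to include with disturbance-independent occupancy.
#' @param env_model data frame describing the covariate responses, columns
#'   `variable`, `intercept`, `slope`, `sd` (value = intercept + slope * g +
#'   Normal(0, sd)); the default covers ammonia, dissolved-oxygen saturation,
#'   conductivity, total phosphorus and elevation on survey-like scales.
#' @return A `synthetic_spec` object (validated list).
#' @export
synthetic_spec <- function(n_sites = 50,
                           gradient = seq(0, 1, length.out = n_sites),
                           scores = bmwp_col_table()$scores,
                           alpha = 1, b = 1.5, mu = 10, theta = 1,
                           extra_families = character(),
                           env_model = default_env_model()) {
  if (any(gradient < 0 | gradient > 1)) stop("gradient values must lie in [0, 1]")
  if (length(gradient) != n_sites) stop("one gradient value per site required")
  if (b <= 0) stop("'b' must be positive (sensitive families must decline)")
  if (mu <= 0 || theta <= 0) stop("'mu' and 'theta' must be positive")
  beta <- -b * (scores - 5)
  beta <- c(beta, stats::setNames(rep(0, length(extra_families)), extra_families))
  stopifnot(all(beta[names(scores)[scores >= 7]] < 0),
            all(beta[names(scores)[scores <= 4]] >= 0))
  structure(list(n_sites = n_sites, gradient = gradient, scores = scores,
                 alpha = alpha, b = b, beta = beta, mu = mu, theta = theta,
                 families = names(beta), env_model = env_model),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_env_model <- function() {
  data.frame(
    variable  = c("NH3", "DO_saturation", "conductivity", "TP", "elevation"),
    intercept = c(0.10, 104, 40, 0.05, 4035),
    slope     = c(0.55, -8, 160, 0.30, -90),
    sd        = c(0.06, 1.5, 20, 0.04, 15),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic community along a disturbance gradient
#'
#' Draws presence, abundance and correlated environmental covariates from a
#' [synthetic_spec()]; fully reproducible from `seed`. The realised gradient,
#' occupancy probabilities and generator parameters are returned as ground
#' truth alongside the data.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (mandatory).
#' @return A list with `community` (a [community_matrix]), `env` (data frame
#'   of covariates with a `site` column) and `truth` (gradient, occupancy
#'   probabilities, spec, seed).
#' @examples
#' sim <- generate_gradient_community(synthetic_spec(n_sites = 10), seed = 1)
#' sim$truth$gradient
#' @export
generate_gradient_community <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  g <- spec$gradient
  n <- spec$n_sites
  fams <- spec$families
  occ <- sapply(fams, function(f) stats::plogis(spec$alpha + spec$beta[[f]] * g))
  occ <- matrix(occ, nrow = n, dimnames = list(NULL, fams))
  sites <- sprintf("S%02d", seq_len(n))
  with_seed(seed, {
    pres <- matrix(stats::rbinom(n * length(fams), 1L, as.vector(occ)),
                   n, length(fams))
    counts <- pres * (1L + matrix(stats::rnbinom(n * length(fams),
                                                 mu = spec$mu, size = spec$theta),
                                  n, length(fams)))
    env <- data.frame(site = sites, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(spec$env_model))) {
      row <- spec$env_model[i, ]
      env[[row$variable]] <- row$intercept + row$slope * g +
        stats::rnorm(n, 0, row$sd)
    }
  })
  cm <- community_matrix(counts, site_ids = sites, family_ids = fams)
  rownames(occ) <- sites
  list(community = cm, env = env,
       truth = list(gradient = stats::setNames(g, sites), occupancy = occ,
                    spec = spec, seed = seed))
}

#' Packaged high-Andean stream survey fixture
#'
#' The presence/absence matrix of a 15-site, 20-family benthic
#' macroinvertebrate survey of a high-Andean river basin, together with the
#' families' BMWP-Col tolerance scores, functional feeding group labels and
#' the sites' published ecological-condition grouping.
#'
#' @return A list with `community` (presence [community_matrix], sites in the
#'   published order), `traits` ([trait_table]), `bmwp_col`
#'   ([tolerance_table]) and `classes` (named character vector site ->
#'   published condition class).
#' @examples
#' fx <- antisana_fixture()
#' score_all_sites(fx$community, fx$bmwp_col)
#' @export
antisana_fixture <- function() {
  path <- system.file("extdata", "antisana_presence.tsv", package = "bioticindices")
  cm <- read_community_matrix(path, layout = "wide",
                              orientation = "sites-in-columns")
  classes <- c(AL3 = "very bad",
               A1 = "poor", AL1 = "poor", AL2 = "poor", ALB1 = "poor",
               ALB2 = "poor", H5 = "poor", H6 = "poor", J1A = "poor",
               J1C = "poor",
               H1 = "moderate", H2 = "moderate", H3 = "moderate",
               H4 = "moderate", J1B = "moderate")
  list(community = cm, traits = antisana_traits(), bmwp_col = bmwp_col_table(),
       classes = classes[rownames(cm)])
}
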