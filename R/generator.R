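# ---------------------------------------------------------------------------
# Synthetic two-census inventories with exactly calibrated con-phenological
# demographic feedbacks. The generator is the study-condition oracle for the
# whole pipeline: every planted effect size can be recovered both by direct
# empirical frequencies and by the model-fitting machinery.
# ---------------------------------------------------------------------------

#' Parameters of the synthetic inventory generator
#'
#' Feedback knobs are expressed exactly as the demographic contrasts are later
#' reported: relative percentage differences (con - hetero)/hetero x 100,
#' evaluated at the reference stand compositions (relEV 0 and 1 for survival
#' and growth, relEV 0.9 vs 0.1 for the recruitment ratio), with all other
#' covariates at their reference values. The defaults plant the headline
#' effect sizes: a 14\% deciduous survival advantage in deciduous stands, 17\%
#' evergreen advantage in evergreen stands, 43\% / 4\% growth advantages, and
#' a 5-fold con:hetero recruitment ratio.
#'
#' @param n_plots number of plots.
#' @param seed integer seed governing all draws.
#' @param area_ha plot area (ha).
#' @param interval_yr census interval (years).
#' @param stand_lambda expected initial stem count per plot above
#'   \code{stand_min}.
#' @param stand_min minimum initial stem count.
#' @param stand_shape Gamma shape of an optional per-plot stocking intensity
#'   mixture (smaller = more between-plot stocking heterogeneity; the default
#'   Inf gives homogeneous Poisson stem counts).
#' @param dbh_meanlog,dbh_sdlog lognormal initial diameter distribution (cm).
#' @param relev_mix initial stand composition design: fractions of purely
#'   evergreen, purely deciduous, near-purely evergreen and near-purely
#'   deciduous plots (the near-pure targets are Beta(12, 1.2) draws and their
#'   mirror); the rest draw a uniform target relEV. Compositions therefore
#'   span \[0, 1\] with mass at and near both extremes, so each leaf type is
#'   observed across the whole feedback gradient (without the near-pure
#'   components, a leaf type would never be seen close to the opposite
#'   boundary and the relEV = 0/1 contrasts would rest on extrapolation).
#' @param base_survival per-interval survival probability of the disadvantaged
#'   phenology in the opposite stand type (the anchor for the survival
#'   calibration).
#' @param target_survival_advantage_de planted relative survival advantage
#'   (\%) of deciduous over evergreen trees at relEV = 0.
#' @param target_survival_advantage_ev same for evergreen trees at relEV = 1.
#' @param base_growth per-interval diameter increment (cm) of the
#'   disadvantaged phenology in the opposite stand type.
#' @param target_growth_advantage_ev planted relative growth advantage (\%)
#'   of evergreen trees at relEV = 1.
#' @param target_growth_advantage_de same for deciduous trees at relEV = 0.
#' @param sigma_growth Gaussian increment noise sd (cm per interval).
#' @param base_recruitment expected recruits per plot per interval per
#'   phenology at relEV = 0.5 and reference covariates.
#' @param target_recruitment_ratio planted con:hetero recruitment-rate ratio
#'   at relEV 0.9 vs 0.1 (same in both directions by construction).
#' @param recruit_dbh_cm entry diameter of recruits (12.7 cm, the smallest
#'   measured tree).
#' @param beta_env vector of 3 coefficients of the leading environmental PCs
#'   shared by both phenologies in all three rates (log/logit scale).
#' @param beta_dbh,beta_ba,beta_density common-scale effects of standardized
#'   tree size, plot basal area and stem density. The size effect is negative
#'   (large trees die and slow down, a senescence stand-in) so simulated
#'   stands turn over on realistic timescales instead of accumulating
#'   immortal giants.
#' @param beta_conba effect of standardized con-phenological basal area on
#'   log recruitment.
#' @param mat_survival_asym phenology-contrasted mean-annual-temperature
#'   effect on the survival logit (evergreen trees favoured at cold MAT,
#'   deciduous at warm): 0 by default, set > 0 for hysteresis experiments.
#' @param near_shape Beta shape pair of the near-pure mixture components.
#' @param mat_recruit_asym same asymmetry on log recruitment.
#' @param abundance list controlling the plot-abundance model (see
#'   [generate_abundance_table()]): intercepts/slopes of the zero probability
#'   and positive mean per type, and the coupling knob \code{rho <= 0}.
#' @return object of class \code{generator_params}.
#' @export
generator_params <- function(n_plots = 3000, seed = 1,
                             area_ha = 0.1, interval_yr = 5,
                             stand_lambda = 14, stand_min = 6,
                             stand_shape = Inf,
                             dbh_meanlog = log(18), dbh_sdlog = 0.35,
                             relev_mix = c(pure_ev = 0.10, pure_de = 0.10,
                                           near_ev = 0.15, near_de = 0.15),
                             near_shape = c(12, 1.2),
                             base_survival = 0.80,
                             target_survival_advantage_de = 14,
                             target_survival_advantage_ev = 17,
                             base_growth = 1.5,
                             target_growth_advantage_ev = 43,
                             target_growth_advantage_de = 4,
                             sigma_growth = 0.7,
                             base_recruitment = 1.3,
                             target_recruitment_ratio = 5,
                             recruit_dbh_cm = 12.7,
                             beta_env = c(0.12, -0.08, 0.05),
                             beta_dbh = -0.10, beta_ba = -0.08,
                             beta_density = -0.05, beta_conba = 0.03,
                             mat_survival_asym = 0, mat_recruit_asym = 0,
                             abundance = list(pi0_intercept = -1.2,
                                              pi0_slope = 0.8,
                                              mu_intercept = 2.6,
                                              mu_slope = 0.5,
                                              rho = 0)) {
  p <- as.list(environment())
  if (any(relev_mix < 0) || sum(relev_mix) > 1)
    stop("relev_mix fractions must be non-negative and sum to at most 1")
  structure(p, class = "generator_params")
}

# Reference (standardization) constants used inside the true vital-rate
# functions, chosen as the closed-form means of the generated distributions so
# that "covariates at training means" coincides with the calibration point.
generator_scales <- function(p) {
  dbh_mean <- exp(p$dbh_meanlog + p$dbh_sdlog^2 / 2)
  dbh_sd <- dbh_mean * sqrt(exp(p$dbh_sdlog^2) - 1)
  n_mean <- p$stand_lambda + p$stand_min
  ba_tree <- basal_area_m2(1) * exp(2 * p$dbh_meanlog + 2 * p$dbh_sdlog^2)
  ba_mean <- n_mean * ba_tree
  list(dbh0 = dbh_mean, dbh_s = dbh_sd,
       ba0 = ba_mean, ba_s = max(ba_mean / 3, 1e-6),
       dens0 = n_mean, dens_s = max(sqrt(p$stand_lambda), 1),
       conba0 = ba_mean / 2, conba_s = max(ba_mean / 3, 1e-6),
       mat0 = 10.5, mat_s = 7.2)
}

#' Closed-form calibration of the true vital-rate functions
#'
#' Converts the relative-advantage knobs into (logit-/log-)linear
#' coefficients, anchored at the reference covariates. An infeasible knob
#' (e.g. a survival advantage pushing the implied probability to 1 or above)
#' raises an error naming the offending knob.
#'
#' @param params a [generator_params()] object.
#' @return object of class \code{true_vital_rates} exposing the same
#'   prediction interface as fitted model sets.
#' @export
calibrate_vital_rates <- function(params) {
  p <- params
  s0 <- p$base_survival
  s_de0 <- s0 * (1 + p$target_survival_advantage_de / 100)
  s_ev1 <- s0 * (1 + p$target_survival_advantage_ev / 100)
  if (s_de0 >= 1 || s_de0 <= 0)
    stop("target_survival_advantage_de infeasible: implied survival ", round(s_de0, 3))
  if (s_ev1 >= 1 || s_ev1 <= 0)
    stop("target_survival_advantage_ev infeasible: implied survival ", round(s_ev1, 3))
  surv <- list(
    EV = c(intercept = stats::qlogis(s0),
           relev = stats::qlogis(s_ev1) - stats::qlogis(s0)),
    DE = c(intercept = stats::qlogis(s_de0),
           relev = stats::qlogis(s0) - stats::qlogis(s_de0))
  )
  g0 <- p$base_growth
  if (g0 <= 0) stop("base_growth must be positive")
  grow <- list(
    EV = c(intercept = g0, relev = g0 * p$target_growth_advantage_ev / 100),
    DE = c(intercept = g0 * (1 + p$target_growth_advantage_de / 100),
           relev = -g0 * p$target_growth_advantage_de / 100)
  )
  if (p$target_recruitment_ratio <= 0)
    stop("target_recruitment_ratio infeasible: must be positive")
  b_rec <- log(p$target_recruitment_ratio) / 0.8  # con-fraction slope
  rec <- list(
    EV = c(intercept = log(p$base_recruitment) - b_rec / 2, relev = b_rec),
    DE = c(intercept = log(p$base_recruitment) + b_rec / 2, relev = -b_rec)
  )
  structure(list(params = p, scales = generator_scales(p),
                 survival = surv, growth = grow, recruitment = rec,
                 sigma_growth = p$sigma_growth,
                 interval_yr = p$interval_yr),
            class = "true_vital_rates")
}

# shared covariate contribution (identical for both phenologies, so contrasts
# at any common covariate value equal the planted reference contrasts)
true_common_term <- function(tv, newdata, rate) {
  p <- tv$params; sc <- tv$scales
  env <- as.matrix(newdata[, paste0("env_pc", 1:3), drop = FALSE]) %*% p$beta_env
  z_ba <- (newdata$plot_ba - sc$ba0) / sc$ba_s
  z_dens <- (newdata$stem_density - sc$dens0) / sc$dens_s
  term <- drop(env) + p$beta_ba * z_ba + p$beta_density * z_dens
  if (rate %in% c("survival", "growth"))
    term <- term + p$beta_dbh * (newdata$dbh_prev - sc$dbh0) / sc$dbh_s
  if (rate == "recruitment")
    term <- term + p$beta_conba * (newdata$con_ba - sc$conba0) / sc$conba_s
  term
}

true_mat_term <- function(tv, newdata, rate, phenology) {
  p <- tv$params; sc <- tv$scales
  asym <- switch(rate, survival = p$mat_survival_asym,
                 recruitment = p$mat_recruit_asym, 0)
  if (asym == 0 || is.null(newdata$mat)) return(0)
  sgn <- if (phenology == "EV") -1 else 1
  sgn * asym * (newdata$mat - sc$mat0) / sc$mat_s
}

#' Predict true (generator) vital rates
#'
#' @param object a \code{true_vital_rates} object.
#' @param rate one of "survival", "growth", "recruitment".
#' @param phenology "EV" or "DE".
#' @param newdata data.frame with dbh_prev, plot_ba, stem_density, con_ba,
#'   relev, env_pc1..env_pc10 and optionally mat, as needed by the rate.
#' @return survival probability, expected diameter increment (cm/interval) or
#'   expected recruit count (per plot per interval).
#' @export
predict_true_rate <- function(object, rate, phenology, newdata) {
  co <- object[[rate]][[phenology]]
  lin <- co["intercept"] + co["relev"] * newdata$relev +
    true_common_term(object, newdata, rate) +
    true_mat_term(object, newdata, rate, phenology)
  switch(rate,
         survival = stats::plogis(lin),
         growth = lin,
         recruitment = exp(lin))
}

#' Generate synthetic plot environments
#'
#' Ten iid standard-normal environmental principal components per plot;
#' mean annual temperature as an affine map of the first component onto
#' \[-2, 23\] degrees C (the empirical MAT range of temperate forest
#' inventories); coordinates in a temperate-band box; and seven determinant
#' covariates (MAT, annual precipitation, coldest-quarter temperature,
#' driest-quarter precipitation, soil pH, soil N density, soil C:N) as noisy
#' functions of the components.
#'
#' @param params a [generator_params()] object.
#' @return plot table (no trees); 0 rows when \code{n_plots = 0}.
#' @export
generate_environment <- function(params) {
  p <- params
  n <- p$n_plots
  cols <- c("plot_id", "lon", "lat", "area_ha", "interval_yr",
            paste0("env_pc", 1:10), "mat_c", "det_mat", "det_precip",
            "det_tcold", "det_pdry", "det_soil_ph", "det_soil_n", "det_soil_cn")
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  set.seed(p$seed)
  pcs <- matrix(stats::rnorm(n * 10), n, 10)
  colnames(pcs) <- paste0("env_pc", 1:10)
  pc1 <- pcs[, 1]
  mat <- if (n > 1 && diff(range(pc1)) > 0)
    -2 + (pc1 - min(pc1)) / diff(range(pc1)) * 25 else rep(10.5, n)
  # plots cluster around landscape centers (as real inventory networks do),
  # so 10-arc-minute fishing-net cells actually accumulate enough plots
  n_centers <- max(1, n %/% 20)
  c_lon <- stats::runif(n_centers, -100, -70)
  c_lat <- stats::runif(n_centers, 30, 48)
  ci <- sample.int(n_centers, n, replace = TRUE)
  out <- data.frame(plot_id = sprintf("p%05d", seq_len(n)),
                    lon = c_lon[ci] + stats::runif(n, -0.05, 0.05),
                    lat = c_lat[ci] + stats::runif(n, -0.05, 0.05),
                    area_ha = p$area_ha, interval_yr = p$interval_yr,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  out$mat_c <- mat
  out$det_mat <- mat
  out$det_precip <- 800 + 250 * pcs[, 2] + stats::rnorm(n, 0, 60)
  out$det_tcold <- mat - 12 + 2 * pcs[, 3] + stats::rnorm(n, 0, 1)
  out$det_pdry <- pmax(0, 120 + 40 * pcs[, 4] + stats::rnorm(n, 0, 15))
  out$det_soil_ph <- 5.5 + 0.6 * pcs[, 5] + stats::rnorm(n, 0, 0.15)
  out$det_soil_n <- pmax(0.05, 0.5 + 0.15 * pcs[, 6] + stats::rnorm(n, 0, 0.04))
  out$det_soil_cn <- pmax(5, 14 + 3 * pcs[, 7] + stats::rnorm(n, 0, 0.8))
  out
}

#' Generate a synthetic two-census inventory
#'
#' Draws an initial stand per plot (stem count, lognormal diameters, leaf
#' phenology Bernoulli in the plot's target composition), then exposes every
#' tree to the true vital rates over one census interval: survival as a
#' Bernoulli in the true probability, survivor growth as the true expected
#' increment plus Gaussian noise, and recruits as Poisson counts per phenology
#' entering at 12.7 cm. The feedback predictor entering the true rates is the
#' realized basal-area relEV of the initial stand.
#'
#' @param env_plots plot table from [generate_environment()].
#' @param params a [generator_params()] object.
#' @param true_rates optional pre-calibrated [calibrate_vital_rates()] result.
#' @return list with \code{trees}, \code{plots} (env_plots) and
#'   \code{true_rates}.
#' @export
generate_two_census_inventory <- function(env_plots, params,
                                          true_rates = calibrate_vital_rates(params)) {
  p <- params
  n <- nrow(env_plots)
  set.seed(p$seed + 1L)
  # target composition mixture: pure / near-pure (both sides) / uniform
  u <- stats::runif(n)
  target <- stats::runif(n)
  edges <- cumsum(c(0, p$relev_mix))
  grp <- cut(u, c(edges, 1), labels = FALSE, include.lowest = TRUE)
  target[grp == 1] <- 1
  target[grp == 2] <- 0
  target[grp == 3] <- stats::rbeta(sum(grp == 3), p$near_shape[1], p$near_shape[2])
  target[grp == 4] <- stats::rbeta(sum(grp == 4), p$near_shape[2], p$near_shape[1])
  lam_i <- if (is.finite(p$stand_shape))
    stats::rgamma(n, shape = p$stand_shape, rate = p$stand_shape / p$stand_lambda)
  else rep(p$stand_lambda, n)
  n0 <- stats::rpois(n, lam_i) + p$stand_min
  plot_idx <- rep.int(seq_len(n), n0)
  ntree <- length(plot_idx)
  dbh_prev <- stats::rlnorm(ntree, p$dbh_meanlog, p$dbh_sdlog)
  is_ev <- stats::runif(ntree) < target[plot_idx]
  ba <- basal_area_m2(dbh_prev)
  ba_plot <- as.numeric(tapply(ba, factor(plot_idx, levels = seq_len(n)), sum, default = 0))
  ba_ev <- as.numeric(tapply(ba * is_ev, factor(plot_idx, levels = seq_len(n)), sum, default = 0))
  relev <- ba_ev / ba_plot
  covar <- function(idx, phen_is_ev) {
    data.frame(dbh_prev = dbh_prev[idx],
               plot_ba = ba_plot[plot_idx[idx]],
               stem_density = n0[plot_idx[idx]],
               con_ba = NA_real_,
               relev = relev[plot_idx[idx]],
               mat = env_plots$mat_c[plot_idx[idx]],
               env_plots[plot_idx[idx], paste0("env_pc", 1:10)])
  }
  phen <- ifelse(is_ev, "EV", "DE")
  p_surv <- numeric(ntree)
  for (ph in c("EV", "DE")) {
    idx <- which(phen == ph)
    p_surv[idx] <- predict_true_rate(true_rates, "survival", ph, covar(idx))
  }
  survived <- stats::runif(ntree) < p_surv
  incr <- numeric(ntree)
  for (ph in c("EV", "DE")) {
    idx <- which(phen == ph & survived)
    if (length(idx))
      incr[idx] <- predict_true_rate(true_rates, "growth", ph, covar(idx)) +
        stats::rnorm(length(idx), 0, p$sigma_growth)
  }
  trees <- data.frame(
    tree_id = sprintf("t%07d", seq_len(ntree)),
    plot_id = env_plots$plot_id[plot_idx],
    species_id = ifelse(is_ev, "sp_ev1", "sp_de1"),
    phenology = phen,
    dbh_prev_cm = dbh_prev,
    dbh_curr_cm = ifelse(survived, dbh_prev + incr, NA_real_),
    fate = ifelse(survived, "survivor", "died"),
    stringsAsFactors = FALSE
  )
  # recruits: Poisson per plot per phenology
  rec_list <- list()
  for (ph in c("EV", "DE")) {
    nd <- data.frame(dbh_prev = NA_real_, plot_ba = ba_plot, stem_density = n0,
                     con_ba = if (ph == "EV") ba_ev else ba_plot - ba_ev,
                     relev = relev, mat = env_plots$mat_c,
                     env_plots[, paste0("env_pc", 1:10)])
    lam <- predict_true_rate(true_rates, "recruitment", ph, nd)
    k <- stats::rpois(n, lam)
    if (sum(k)) {
      ridx <- rep.int(seq_len(n), k)
      rec_list[[ph]] <- data.frame(
        tree_id = paste0("r", ph, sprintf("%06d", seq_along(ridx))),
        plot_id = env_plots$plot_id[ridx],
        species_id = if (ph == "EV") "sp_ev1" else "sp_de1",
        phenology = ph, dbh_prev_cm = NA_real_,
        dbh_curr_cm = p$recruit_dbh_cm, fate = "recruit",
        stringsAsFactors = FALSE)
    }
  }
  trees <- rbind(trees, do.call(rbind, rec_list))
  rownames(trees) <- NULL
  # two distinct species per type in a slice of plots so species filters bite
  alt <- trees$plot_id %in% env_plots$plot_id[seq_len(max(1, n %/% 2))] &
    (seq_len(nrow(trees)) %% 3 == 0)
  trees$species_id[alt] <- paste0(trees$species_id[alt], "b")
  list(trees = trees, plots = env_plots, true_rates = true_rates)
}

#' Generate a plot-level abundance table from the hurdle model
#'
#' Per leaf type, a zero-adjusted Poisson: with probability
#' \eqn{\pi_0(env)} the count is 0, otherwise a zero-truncated Poisson with
#' mean parameter \eqn{\mu(env)}. The evergreen type becomes rarer (higher
#' \eqn{\pi_0}, lower \eqn{\mu}) toward warm environments and the deciduous
#' type mirrors it. A coupling knob \eqn{\rho \le 0} adds a shared
#' plot-level latent factor entering the two \eqn{\mu}'s with opposite signs,
#' creating negative EV-DE dependence beyond the environment (the alternative
#' the null model is tested against).
#'
#' @param env_plots plot table.
#' @param params a [generator_params()] object; the \code{abundance} block
#'   holds \code{pi0_intercept}, \code{pi0_slope}, \code{mu_intercept},
#'   \code{mu_slope} and \code{rho}.
#' @return data.frame plot_id, ev_count, de_count.
#' @export
generate_abundance_table <- function(env_plots, params) {
  p <- params; a <- p$abundance
  if (a$rho > 0) stop("coupling rho must be <= 0")
  n <- nrow(env_plots)
  set.seed(p$seed + 2L)
  pc1 <- env_plots$env_pc1
  kappa <- sqrt(-a$rho)
  # bounded two-state latent factor (plots tipped toward one dominance
  # state): gives env-independent negative dependence without the marginal
  # overdispersion blow-up an unbounded normal factor would add
  z <- sample(c(-1, 1), n, replace = TRUE)
  draw <- function(sgn) {
    # the latent state suppresses the disfavoured type's presence (zero part)
    # and abundance (positive part) jointly, as tipped stands do
    pi0 <- stats::plogis(a$pi0_intercept + sgn * a$pi0_slope * pc1 -
                           sgn * kappa * z)
    mu <- exp(a$mu_intercept - sgn * a$mu_slope * pc1 + sgn * kappa * z)
    rzap(n, pi0, mu)
  }
  data.frame(plot_id = env_plots$plot_id,
             ev_count = draw(+1), de_count = draw(-1),
             stringsAsFactors = FALSE)
}

#' Beta-mixture relEV samples for bimodality unit tests
#'
#' @param spec either a preset name ("unimodal_left" for deciduous-heavy mass
#'   near 0, "unimodal_right" for evergreen-heavy, "bimodal" for a symmetric
#'   two-component mixture) or a list with \code{weights}, \code{shape1},
#'   \code{shape2}.
#' @param n sample size.
#' @param seed integer seed.
#' @return vector of fractions in \[0, 1\].
#' @export
generate_relev_samples <- function(spec, n, seed = 1) {
  if (is.character(spec)) {
    spec <- switch(spec,
      unimodal_left = list(weights = 1, shape1 = 1.5, shape2 = 8),
      unimodal_right = list(weights = 1, shape1 = 8, shape2 = 1.5),
      bimodal = list(weights = c(0.5, 0.5), shape1 = c(1.5, 10),
                     shape2 = c(10, 1.5)),
      stop("unknown relEV preset: ", spec))
  }
  w <- spec$weights
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  set.seed(seed)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::rbeta(n, spec$shape1[comp], spec$shape2[comp])
}
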