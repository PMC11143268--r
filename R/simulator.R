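# ---------------------------------------------------------------------------
# Individual-based forest succession simulator. Each plot carries a tree list
# (phenology, dbh); per 5-year step: stand-replacing disturbance, survival,
# growth, recruitment, in that fixed order, with plot covariates frozen at
# the step start. Driven either by fitted vital-rate models or by the
# generator's true rates.
# ---------------------------------------------------------------------------

#' Natural stand-replacing disturbance rate
#'
#' The overall North American stand-replacing probability per year minus the
#' part attributable to management gives the natural background rate used in
#' the simulations: 0.009 - 0.0054 = 0.0036 per year.
#'
#' @param total overall annual stand-replacement probability.
#' @param managed annual stand replacement due to management.
#' @export
natural_disturbance_rate <- function(total = 0.009, managed = 0.0054) {
  total - managed
}

#' Succession simulation configuration
#'
#' @param n_plots number of simulated plots (default 1000).
#' @param horizon_years simulated time span (default 2000).
#' @param step_years time step, matching the census interval the rates were
#'   fitted on (default 5; must divide the horizon).
#' @param p_disturb_annual annual stand-replacing disturbance probability
#'   (default [natural_disturbance_rate()], 0.0036); compounded to
#'   \eqn{1-(1-p)^{step}} per step.
#' @param init initialization scheme: \code{"uniform"} (target relEV drawn
#'   uniformly), \code{"bimodal_half"} (half the plots purely evergreen, half
#'   purely deciduous), \code{"hysteresis_ev"} (80\% purely evergreen, 20\%
#'   purely deciduous), \code{"hysteresis_de"} (the mirror image).
#' @param trees_init initial trees per plot (default 20).
#' @param dbh_init initial diameter (12.7 cm, the smallest measured tree).
#' @param area_ha plot area.
#' @param record_every record the relEV trajectory every this many steps
#'   (NULL records only the final state).
#' @param seed integer seed.
#' @export
sim_config <- function(n_plots = 1000, horizon_years = 2000, step_years = 5,
                       p_disturb_annual = natural_disturbance_rate(),
                       init = c("uniform", "bimodal_half", "hysteresis_ev",
                                "hysteresis_de"),
                       trees_init = 20, dbh_init = 12.7, area_ha = 0.1,
                       record_every = NULL, seed = 1) {
  init <- match.arg(init)
  if (p_disturb_annual < 0 || p_disturb_annual > 1)
    stop("p_disturb_annual must lie in [0, 1]")
  if (horizon_years %% step_years != 0)
    stop("step_years must divide horizon_years")
  structure(list(n_plots = n_plots, horizon_years = horizon_years,
                 step_years = step_years, p_disturb_annual = p_disturb_annual,
                 init = init, trees_init = trees_init, dbh_init = dbh_init,
                 area_ha = area_ha, record_every = record_every, seed = seed),
            class = "sim_config")
}

init_targets <- function(config) {
  n <- config$n_plots
  switch(config$init,
         uniform = stats::runif(n),
         bimodal_half = rep(c(1, 0), c(floor(n / 2), n - floor(n / 2))),
         hysteresis_ev = rep(c(1, 0), c(round(0.8 * n), n - round(0.8 * n))),
         hysteresis_de = rep(c(0, 1), c(round(0.8 * n), n - round(0.8 * n))))
}

#' Initialize the simulation state
#'
#' Each plot receives \code{trees_init} trees at \code{dbh_init} cm whose
#' phenologies are Bernoulli draws in the plot's target relEV (so pure
#' targets give exactly pure stands). Environments are sampled with
#' replacement from a reference plot table and stay fixed per plot.
#'
#' @param config a [sim_config()].
#' @param env_reference plot table supplying env_pc1..env_pc10 and mat_c.
#' @param env_rows optional row indices into \code{env_reference} (e.g. to
#'   restrict to a MAT section); default samples with replacement.
#' @return a \code{sim_state} list.
#' @export
init_sim_state <- function(config, env_reference, env_rows = NULL) {
  set.seed(config$seed)
  n <- config$n_plots
  if (is.null(env_rows))
    env_rows <- sample.int(nrow(env_reference), n, replace = TRUE)
  env <- env_reference[env_rows, c(paste0("env_pc", 1:10), "mat_c"), drop = FALSE]
  names(env)[names(env) == "mat_c"] <- "mat"
  rownames(env) <- NULL
  target <- init_targets(config)
  phen <- matrix(stats::runif(n * config$trees_init) < target, n)
  trees <- data.frame(
    plot = rep(seq_len(n), each = config$trees_init),
    is_ev = as.vector(t(phen)),
    dbh = config$dbh_init)
  state <- list(trees = trees, env = env, n_plots = n,
                target_relev = target,
                last_relev = ifelse(is.na(target), 0.5, target),
                time = 0, config = config)
  state$last_relev <- plot_relev(state)
  state$last_relev[is.na(state$last_relev)] <- target[is.na(state$last_relev)]
  class(state) <- "sim_state"
  state
}

plot_covariates <- function(state) {
  n <- state$n_plots
  f <- factor(state$trees$plot, levels = seq_len(n))
  ba <- basal_area_m2(state$trees$dbh)
  plot_ba <- as.numeric(tapply(ba, f, sum, default = 0))
  ba_ev <- as.numeric(tapply(ba * state$trees$is_ev, f, sum, default = 0))
  dens <- as.numeric(tapply(rep(1, nrow(state$trees)), f, sum, default = 0))
  relev <- ifelse(plot_ba > 0, ba_ev / plot_ba, NA_real_)
  data.frame(plot_ba = plot_ba, ba_ev = ba_ev, ba_de = plot_ba - ba_ev,
             stem_density = dens, relev = relev)
}

plot_relev <- function(state) plot_covariates(state)$relev

# ---------------------------------------------------------------------------
# Compiled rate predictors. A plot's environmental covariates never change
# within a simulation, so each model's environmental smooth terms are
# evaluated once per plot up front; per step only the dynamic terms (tree
# size, stand basal area, stem density, con-phenological basal area, relEV)
# are evaluated. This makes long runs an order of magnitude faster than
# calling predict() on the full model every step.
# ---------------------------------------------------------------------------

compile_fitted_rate <- function(vfit, env_df) {
  m <- vfit$fit
  beta <- stats::coef(m)
  env_vars <- c(paste0("env_pc", 1:10), "mat")
  n_env <- nrow(env_df)
  env_off <- rep(0, n_env)
  dyn <- list()
  for (s in m$smooth) {
    v <- s$term
    ix <- s$first.para:s$last.para
    bi <- beta[ix]
    if (v %in% env_vars) {
      d <- env_df[, v, drop = FALSE]
      d[[v]] <- pmin(pmax(d[[v]], vfit$ranges[[v]][1]), vfit$ranges[[v]][2])
      env_off <- env_off + drop(mgcv::PredictMat(s, d) %*% bi)
    } else {
      dyn[[v]] <- local({
        s_ <- s; bi_ <- bi; rng <- vfit$ranges[[v]]; v_ <- v
        function(x) {
          d <- stats::setNames(data.frame(pmin(pmax(x, rng[1]), rng[2])), v_)
          drop(mgcv::PredictMat(s_, d) %*% bi_)
        }
      })
    }
  }
  b_relev <- if ("relev" %in% names(beta)) unname(beta["relev"]) else 0
  relev_rng <- vfit$ranges[["relev"]]
  intercept <- unname(beta["(Intercept)"])
  linkinv <- m$family$linkinv
  rate <- vfit$rate
  function(plot_idx, dbh = NULL, plot_ba, stem_density, con_ba = NULL, relev) {
    eta <- intercept + env_off[plot_idx]
    if (!is.null(dyn$dbh_prev)) eta <- eta + dyn$dbh_prev(dbh)
    eta <- eta + dyn$plot_ba(plot_ba) + dyn$stem_density(stem_density)
    if (!is.null(dyn$con_ba)) eta <- eta + dyn$con_ba(con_ba)
    if (b_relev != 0 && !is.null(relev_rng))
      eta <- eta + b_relev * pmin(pmax(relev, relev_rng[1]), relev_rng[2])
    mu <- linkinv(eta)
    if (rate == "growth") mu <- mu - dbh  # dbh_curr -> increment
    mu
  }
}

compile_true_rate <- function(tv, rate, phenology, env_df) {
  p <- tv$params; sc <- tv$scales
  env <- as.matrix(env_df[, paste0("env_pc", 1:3), drop = FALSE]) %*% p$beta_env
  env <- drop(env)
  asym <- switch(rate, survival = p$mat_survival_asym,
                 recruitment = p$mat_recruit_asym, 0)
  if (asym != 0 && !is.null(env_df$mat)) {
    sgn <- if (phenology == "EV") -1 else 1
    env <- env + sgn * asym * (env_df$mat - sc$mat0) / sc$mat_s
  }
  co <- tv[[rate]][[phenology]]
  function(plot_idx, dbh = NULL, plot_ba, stem_density, con_ba = NULL, relev) {
    lin <- co["intercept"] + co["relev"] * relev + env[plot_idx] +
      p$beta_ba * (plot_ba - sc$ba0) / sc$ba_s +
      p$beta_density * (stem_density - sc$dens0) / sc$dens_s
    if (rate %in% c("survival", "growth") && !is.null(dbh))
      lin <- lin + p$beta_dbh * (dbh - sc$dbh0) / sc$dbh_s
    if (rate == "recruitment" && !is.null(con_ba))
      lin <- lin + p$beta_conba * (con_ba - sc$conba0) / sc$conba_s
    unname(switch(rate, survival = stats::plogis(lin), growth = lin,
                  recruitment = exp(lin)))
  }
}

#' Compile vital-rate models against a fixed set of plot environments
#'
#' @param models fitted [fit_vital_rates()] set or [calibrate_vital_rates()]
#'   truth.
#' @param env_df per-plot environment table (env_pc1..env_pc10, mat).
#' @return a \code{compiled_rates} object used by [sim_step()].
#' @export
compile_rates <- function(models, env_df) {
  out <- list(sigma = sim_growth_sigma(models))
  for (ph in c("EV", "DE")) {
    out[[ph]] <- lapply(stats::setNames(nm = c("survival", "growth", "recruitment")),
      function(rate) {
        if (inherits(models, "vital_rate_models"))
          compile_fitted_rate(models[[ph]][[rate]], env_df)
        else compile_true_rate(models, rate, ph, env_df)
      })
  }
  class(out) <- "compiled_rates"
  out
}

sim_growth_sigma <- function(models) {
  if (inherits(models, "vital_rate_models")) models$EV$growth$sigma
  else if (inherits(models, "compiled_rates")) models$sigma
  else models$sigma_growth
}

#' Advance the simulation by one step
#'
#' Order within a step: (1) stand-replacing disturbance with probability
#' \eqn{1-(1-p_d)^{step}}; a disturbed plot resets to the initial tree count
#' at 12.7 cm with phenologies drawn in the plot's pre-disturbance relEV.
#' (2) Survival: each tree survives with its modelled probability.
#' (3) Growth: survivors grow by the predicted increment plus Gaussian
#' residual noise, floored at zero (no shrinkage). (4) Recruitment: Poisson
#' counts per phenology at the modelled rate, entering at 12.7 cm. All plot
#' covariates are frozen at the step start. Empty undisturbed plots still
#' recruit, using the plot's last defined relEV.
#'
#' @param state a \code{sim_state}.
#' @param models fitted [fit_vital_rates()] set or [calibrate_vital_rates()]
#'   truth.
#' @param config the [sim_config()] in use.
#' @return the advanced state.
#' @export
sim_step <- function(state, models, config = state$config) {
  n <- state$n_plots
  step <- config$step_years
  p_step <- 1 - (1 - config$p_disturb_annual)^step
  rates <- if (inherits(models, "compiled_rates")) models
           else compile_rates(models, state$env)
  cov0 <- plot_covariates(state)
  relev_now <- ifelse(is.na(cov0$relev), state$last_relev, cov0$relev)
  disturbed <- stats::runif(n) < p_step

  trees <- state$trees
  keep <- !(trees$plot %in% which(disturbed))
  trees <- trees[keep, , drop = FALSE]

  if (nrow(trees)) {
    pl <- trees$plot
    surv_p <- numeric(nrow(trees))
    for (ph in c("EV", "DE")) {
      sel <- if (ph == "EV") trees$is_ev else !trees$is_ev
      if (!any(sel)) next
      surv_p[sel] <- rates[[ph]]$survival(pl[sel], dbh = trees$dbh[sel],
                                          plot_ba = cov0$plot_ba[pl[sel]],
                                          stem_density = cov0$stem_density[pl[sel]],
                                          relev = relev_now[pl[sel]])
    }
    alive <- stats::runif(nrow(trees)) < surv_p
    trees <- trees[alive, , drop = FALSE]
    if (nrow(trees)) {
      pl <- trees$plot
      incr <- numeric(nrow(trees))
      for (ph in c("EV", "DE")) {
        sel <- if (ph == "EV") trees$is_ev else !trees$is_ev
        if (!any(sel)) next
        incr[sel] <- rates[[ph]]$growth(pl[sel], dbh = trees$dbh[sel],
                                        plot_ba = cov0$plot_ba[pl[sel]],
                                        stem_density = cov0$stem_density[pl[sel]],
                                        relev = relev_now[pl[sel]])
      }
      incr <- pmax(incr + stats::rnorm(nrow(trees), 0, sim_growth_sigma(rates)), 0)
      if (any(!is.finite(incr)))
        stop("non-finite growth prediction at time ", state$time)
      trees$dbh <- trees$dbh + incr
    }
  }

  # recruitment on undisturbed plots, covariates at step start
  und <- which(!disturbed)
  if (length(und)) {
    new_list <- vector("list", 2)
    for (i in 1:2) {
      ph <- c("EV", "DE")[i]
      lam <- rates[[ph]]$recruitment(und,
               plot_ba = cov0$plot_ba[und],
               stem_density = cov0$stem_density[und],
               con_ba = if (ph == "EV") cov0$ba_ev[und] else cov0$ba_de[und],
               relev = relev_now[und])
      if (any(!is.finite(lam)))
        stop("non-finite recruitment prediction at time ", state$time)
      k <- stats::rpois(length(und), lam)
      if (sum(k))
        new_list[[i]] <- data.frame(plot = rep(und, k), is_ev = ph == "EV",
                                    dbh = config$dbh_init)
    }
    trees <- rbind(trees, do.call(rbind, new_list))
  }

  # disturbed plots regenerate from their pre-disturbance composition
  if (any(disturbed)) {
    dplots <- which(disturbed)
    m <- length(dplots) * config$trees_init
    regen <- data.frame(
      plot = rep(dplots, each = config$trees_init),
      is_ev = stats::runif(m) < rep(relev_now[dplots], each = config$trees_init),
      dbh = config$dbh_init)
    trees <- rbind(trees, regen)
  }

  state$trees <- trees[order(trees$plot), , drop = FALSE]
  rownames(state$trees) <- NULL
  state$time <- state$time + step
  new_relev <- plot_relev(state)
  state$last_relev <- ifelse(is.na(new_relev), relev_now, new_relev)
  state
}

#' Run a succession simulation
#'
#' @param config a [sim_config()].
#' @param models fitted or true vital-rate models.
#' @param env_reference plot table to sample environments from.
#' @param env_rows optional fixed environment rows (see [init_sim_state()]).
#' @return list with \code{final_relev} (per-plot relEV after the horizon;
#'   last defined value for empty plots), \code{trajectory} (matrix steps x
#'   plots when \code{record_every} is set), \code{state}, and \code{summary}
#'   (mean tree count and relEV).
#' @export
run_simulation <- function(config, models, env_reference, env_rows = NULL) {
  state <- init_sim_state(config, env_reference, env_rows)
  if (!inherits(models, "compiled_rates")) models <- compile_rates(models, state$env)
  n_steps <- config$horizon_years / config$step_years
  rec <- config$record_every
  traj <- if (!is.null(rec)) matrix(NA_real_, floor(n_steps / rec) + 1, config$n_plots)
  if (!is.null(rec)) traj[1, ] <- state$last_relev
  for (s in seq_len(n_steps)) {
    state <- sim_step(state, models, config)
    if (!is.null(rec) && s %% rec == 0) traj[s / rec + 1, ] <- state$last_relev
  }
  list(final_relev = state$last_relev,
       trajectory = traj,
       state = state,
       summary = data.frame(mean_trees = nrow(state$trees) / config$n_plots,
                            mean_relev = mean(state$last_relev, na.rm = TRUE)))
}

#' Hysteresis experiment along the temperature gradient
#'
#' Splits the MAT range into equal sections; for each section, simulates
#' plots whose environments are drawn from the reference plots falling in
#' that section, under both initializations (evergreen-dominated 800:200 and
#' deciduous-dominated) and both model variants, then reports the mean final
#' relEV per section with a 95\% band and the initialization gap
#' (EV-init minus DE-init).
#'
#' @param config a [sim_config()] (its \code{init} field is overridden).
#' @param models_feedback feedback-variant models (with a MAT term when
#'   fitted).
#' @param models_null null-variant models, or NULL to skip.
#' @param env_reference reference plot table with \code{mat_c}.
#' @param mat_range MAT gradient range (default -2..23 C).
#' @param n_sections number of gradient sections (default 12).
#' @return data.frame: variant, section, mat_mid, mean relEV and 95\% bands
#'   per initialization, gap, gap_lo95, gap_hi95.
#' @export
hysteresis_experiment <- function(config, models_feedback, models_null,
                                  env_reference, mat_range = c(-2, 23),
                                  n_sections = 12) {
  edges <- seq(mat_range[1], mat_range[2], length.out = n_sections + 1)
  sec_of <- cut(env_reference$mat_c, edges, include.lowest = TRUE, labels = FALSE)
  variants <- list(feedback = models_feedback)
  if (!is.null(models_null)) variants$null <- models_null
  rows <- list()
  for (vn in names(variants)) {
    for (s in seq_len(n_sections)) {
      idx <- which(sec_of == s)
      if (!length(idx)) stop("no reference plots in MAT section ", s)
      res <- list()
      for (init in c("hysteresis_ev", "hysteresis_de")) {
        cfg <- config
        cfg$init <- init
        cfg$seed <- config$seed + s * 100 + (init == "hysteresis_de") * 7 +
          match(vn, names(variants)) * 13
        set.seed(cfg$seed)
        rowsample <- sample(idx, cfg$n_plots, replace = TRUE)
        sim <- run_simulation(cfg, variants[[vn]], env_reference, env_rows = rowsample)
        x <- sim$final_relev
        res[[init]] <- c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
      }
      gap <- res$hysteresis_ev["mean"] - res$hysteresis_de["mean"]
      gse <- sqrt(res$hysteresis_ev["se"]^2 + res$hysteresis_de["se"]^2)
      rows[[length(rows) + 1]] <- data.frame(
        variant = vn, section = s, mat_mid = (edges[s] + edges[s + 1]) / 2,
        relev_ev_init = res$hysteresis_ev["mean"],
        relev_ev_lo = res$hysteresis_ev["mean"] - 1.96 * res$hysteresis_ev["se"],
        relev_ev_hi = res$hysteresis_ev["mean"] + 1.96 * res$hysteresis_ev["se"],
        relev_de_init = res$hysteresis_de["mean"],
        relev_de_lo = res$hysteresis_de["mean"] - 1.96 * res$hysteresis_de["se"],
        relev_de_hi = res$hysteresis_de["mean"] + 1.96 * res$hysteresis_de["se"],
        gap = gap, gap_lo95 = gap - 1.96 * gse, gap_hi95 = gap + 1.96 * gse,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
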