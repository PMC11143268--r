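# ---------------------------------------------------------------------------
# Growth, survival and recruitment response models per leaf phenology, with
# or without the con-phenological feedback predictor (plot relEV), and the
# headline contrast predictions. Fitting uses mgcv penalized thin-plate
# splines with basis dimension 5 per continuous predictor.
# ---------------------------------------------------------------------------

#' Assemble model frames for demographic fitting
#'
#' Plot covariates are the start-of-interval state: basal area and stem
#' density over first-census trees, basal-area relEV (the feedback
#' predictor), and con-phenological basal area per leaf type. The tree frame
#' (for growth/survival) joins these to every first-census tree; the plot
#' frame (for recruitment) adds recruit counts per phenology.
#'
#' @param trees tree table.
#' @param plots plot table with env_pc1..env_pc10 and mat_c.
#' @return list with \code{tree_frame} and \code{plot_frame}.
#' @export
build_demography_data <- function(trees, plots) {
  validate_trees(trees)
  first <- trees[trees$fate != "recruit", , drop = FALSE]
  pid <- factor(first$plot_id, levels = plots$plot_id)
  ba <- basal_area_m2(first$dbh_prev_cm)
  agg <- function(v) as.numeric(tapply(v, pid, sum, default = 0))
  plot_ba <- agg(ba)
  ba_ev <- agg(ba * (first$phenology == "EV"))
  ba_de <- agg(ba * (first$phenology == "DE"))
  stem_density <- agg(rep(1, nrow(first)))
  relev <- ifelse(ba_ev + ba_de > 0, ba_ev / (ba_ev + ba_de), NA_real_)
  envc <- c(paste0("env_pc", 1:10), "mat_c", "interval_yr")
  plot_frame <- data.frame(plot_id = plots$plot_id,
                           plot_ba = plot_ba, stem_density = stem_density,
                           ba_ev = ba_ev, ba_de = ba_de, relev = relev,
                           plots[, envc], stringsAsFactors = FALSE)
  names(plot_frame)[names(plot_frame) == "mat_c"] <- "mat"
  rec <- trees[trees$fate == "recruit", , drop = FALSE]
  rpid <- factor(rec$plot_id, levels = plots$plot_id)
  plot_frame$recruits_ev <- as.numeric(tapply(rec$phenology == "EV", rpid, sum, default = 0))
  plot_frame$recruits_de <- as.numeric(tapply(rec$phenology == "DE", rpid, sum, default = 0))
  idx <- match(first$plot_id, plot_frame$plot_id)
  tree_frame <- cbind(first[, c("tree_id", "plot_id", "phenology",
                                "dbh_prev_cm", "dbh_curr_cm", "fate")],
                      plot_frame[idx, setdiff(names(plot_frame),
                                              c("plot_id", "recruits_ev", "recruits_de"))])
  names(tree_frame)[names(tree_frame) == "dbh_prev_cm"] <- "dbh_prev"
  names(tree_frame)[names(tree_frame) == "dbh_curr_cm"] <- "dbh_curr"
  tree_frame$survive <- as.numeric(tree_frame$fate == "survivor")
  rownames(tree_frame) <- NULL
  list(tree_frame = tree_frame, plot_frame = plot_frame)
}

demog_formula <- function(rate, feedback, mat_term, k) {
  sm <- function(v) sprintf("s(%s, k = %d)", v, k)
  # conBA is itself a con-phenological quantity: the null variant excludes
  # every feedback predictor (relEV and conBA), otherwise the additive conBA
  # smooth reconstructs the relEV effect (conBA/plotBA = relEV exactly) and
  # the "null" keeps the recruitment feedback
  covs <- c(if (rate %in% c("survival", "growth")) "dbh_prev",
            "plot_ba", "stem_density",
            if (rate == "recruitment" && feedback) "con_ba",
            paste0("env_pc", 1:10),
            if (mat_term) "mat")
  resp <- switch(rate, survival = "survive", growth = "dbh_curr",
                 recruitment = "recruits")
  # the feedback predictor enters linearly: con-phenological frequency
  # dependence is monotone, and the relEV = 0/1 contrasts sit at the sparse
  # ends of the gradient where a free smooth extrapolates unstably
  stats::as.formula(paste(resp, "~",
                          paste(c(vapply(covs, sm, ""),
                                  if (feedback) "relev"), collapse = " + ")))
}

fit_one_rate <- function(rate, data, phenology, feedback, mat_term, k, min_n) {
  fam <- switch(rate, survival = stats::binomial(), growth = stats::gaussian(),
                recruitment = stats::poisson())
  if (nrow(data) < min_n)
    stop("too few observations (", nrow(data), " < ", min_n, ") to fit the ",
         phenology, " ", rate, " model")
  form <- demog_formula(rate, feedback, mat_term, k)
  # gamma = 1.4: standard REML overfit guard; keeps the smooth terms from
  # chasing noise near the sparse ends of the relEV gradient
  m <- mgcv::bam(form, data = data, family = fam, method = "fREML",
                 discrete = TRUE, gamma = 1.4)
  preds <- all.vars(form)[-1]
  structure(list(fit = m, rate = rate, phenology = phenology,
                 feedback = feedback, mat_term = mat_term,
                 predictors = preds,
                 means = vapply(preds, function(v) mean(data[[v]]), 0),
                 ranges = lapply(preds, function(v) range(data[[v]])) |>
                   stats::setNames(preds),
                 sigma = if (rate == "growth") stats::sd(stats::residuals(m)) else NULL,
                 interval_yr = data$interval_yr[1],
                 n = nrow(data)),
            class = "vital_rate_fit")
}

#' Fit a survival model for one leaf phenology
#'
#' Binomial GAM (logit link) of per-interval survival of first-census trees
#' as a smooth function of previous diameter, plot basal area, stem density,
#' the ten environmental PCs and, in the feedback variant, plot relEV.
#'
#' @param demog result of [build_demography_data()].
#' @param phenology "EV" or "DE".
#' @param feedback include the relEV feedback predictor?
#' @param mat_term include mean annual temperature (hysteresis variant)?
#' @param k spline basis dimension (default 5).
#' @param min_n minimum number of trees (default 500).
#' @export
fit_survival <- function(demog, phenology, feedback = TRUE, mat_term = FALSE,
                         k = 5, min_n = 500) {
  d <- demog$tree_frame
  d <- d[d$phenology == phenology & !is.na(d$relev), , drop = FALSE]
  fit_one_rate("survival", d, phenology, feedback, mat_term, k, min_n)
}

#' Fit a growth model for one leaf phenology
#'
#' Gaussian GAM of current diameter of surviving trees given previous
#' diameter, stand structure, environment and (feedback variant) relEV.
#' Growth is reported downstream as the predicted diameter increment per
#' year.
#'
#' @inheritParams fit_survival
#' @export
fit_growth <- function(demog, phenology, feedback = TRUE, mat_term = FALSE,
                       k = 5, min_n = 500) {
  d <- demog$tree_frame
  d <- d[d$phenology == phenology & d$fate == "survivor" & !is.na(d$relev), , drop = FALSE]
  if (any(d$interval_yr <= 0)) stop("census interval must be positive")
  fit_one_rate("growth", d, phenology, feedback, mat_term, k, min_n)
}

#' Fit a recruitment model for one leaf phenology
#'
#' Poisson GAM (log link) of per-plot recruit counts over the census interval
#' given plot basal area, stem density, con-phenological basal area (kept in
#' both variants), environment and (feedback variant) relEV.
#'
#' @inheritParams fit_survival
#' @param min_n minimum number of plots (default 200).
#' @export
fit_recruitment <- function(demog, phenology, feedback = TRUE, mat_term = FALSE,
                            k = 5, min_n = 200) {
  d <- demog$plot_frame
  d <- d[!is.na(d$relev), , drop = FALSE]
  d$recruits <- if (phenology == "EV") d$recruits_ev else d$recruits_de
  d$con_ba <- if (phenology == "EV") d$ba_ev else d$ba_de
  if (all(d$recruits == 0)) stop("all recruit counts are zero for ", phenology)
  fit_one_rate("recruitment", d, phenology, feedback, mat_term, k, min_n)
}

#' Fit the full set of vital-rate models
#'
#' All six models (growth, survival, recruitment for each leaf phenology) in
#' one variant (feedback or null).
#'
#' @param trees,plots inventory tables.
#' @param feedback include the relEV feedback predictor?
#' @param mat_term include mean annual temperature?
#' @param k spline basis dimension.
#' @return object of class \code{vital_rate_models}.
#' @export
fit_vital_rates <- function(trees, plots, feedback = TRUE, mat_term = FALSE, k = 5) {
  demog <- build_demography_data(trees, plots)
  out <- list(feedback = feedback, mat_term = mat_term)
  for (ph in c("EV", "DE")) {
    out[[ph]] <- list(
      survival = fit_survival(demog, ph, feedback, mat_term, k),
      growth = fit_growth(demog, ph, feedback, mat_term, k),
      recruitment = fit_recruitment(demog, ph, feedback, mat_term, k))
  }
  out$interval_yr <- out$EV$survival$interval_yr
  class(out) <- "vital_rate_models"
  out
}

clamp_to_range <- function(newdata, ranges) {
  for (v in names(ranges)) {
    if (!is.null(newdata[[v]]))
      newdata[[v]] <- pmin(pmax(newdata[[v]], ranges[[v]][1]), ranges[[v]][2])
  }
  newdata
}

#' Predict from one fitted vital-rate model
#'
#' Response-scale predictions (survival probability, expected current
#' diameter, expected recruit count per interval). Covariates are clamped to
#' the training range by default, which keeps long simulations from
#' extrapolating the spline tails.
#'
#' @param object a \code{vital_rate_fit}.
#' @param newdata data.frame with the model's predictors.
#' @param clamp clamp covariates to the training range?
#' @param ... unused.
#' @export
predict.vital_rate_fit <- function(object, newdata, clamp = TRUE, ...) {
  if (clamp) newdata <- clamp_to_range(newdata, object$ranges)
  as.numeric(stats::predict(object$fit, newdata = newdata, type = "response",
                               discrete = FALSE, newdata.guaranteed = TRUE))
}

means_newdata <- function(vfit, relev, overrides = list()) {
  nd <- as.data.frame(as.list(vfit$means))
  if (!is.null(relev)) nd$relev <- relev
  for (v in names(overrides)) nd[[v]] <- overrides[[v]]
  nd
}

draw_predictions <- function(vfit, newdata, n_draws, invlink) {
  Xp <- stats::predict(vfit$fit, newdata = newdata, type = "lpmatrix",
                          discrete = FALSE, newdata.guaranteed = TRUE)
  beta <- stats::coef(vfit$fit)
  draws <- mgcv::rmvn(n_draws, beta, stats::vcov(vfit$fit))
  list(point = invlink(drop(Xp %*% beta)),
       draws = invlink(Xp %*% t(draws)))  # rows = newdata, cols = draws
}

#' Con- vs hetero-phenological survival or growth contrast
#'
#' Predicts the rate for both phenologies at the requested stand compositions
#' (relEV = 0, a fully deciduous stand, and relEV = 1, fully evergreen) with
#' every other predictor held at its training mean, and reports the relative
#' difference (con - hetero)/hetero x 100 between the resident ("con") and
#' the minority ("hetero") phenology. Growth is compared on diameter
#' increments per year. Uncertainty comes from \code{n_draws} multivariate
#' normal coefficient draws from each model's posterior covariance.
#'
#' @param models a feedback-variant [fit_vital_rates()] set.
#' @param rate "survival" or "growth".
#' @param relev_points stand compositions to evaluate (default 0 and 1).
#' @param n_draws number of coefficient draws (default 100).
#' @param seed integer seed for the draws.
#' @return data.frame with one row per relEV point: con/hetero phenology,
#'   point values, relative difference (\%) and its 95\% draw interval.
#' @export
predict_survival_growth_contrast <- function(models, rate = "survival",
                                             relev_points = c(0, 1),
                                             n_draws = 100, seed = 1) {
  stopifnot(inherits(models, "vital_rate_models"), rate %in% c("survival", "growth"))
  if (!models$feedback)
    stop("contrast undefined for null-variant models (no relEV term)")
  set.seed(seed)
  out <- do.call(rbind, lapply(relev_points, function(r) {
    pv <- lapply(c(EV = "EV", DE = "DE"), function(ph) {
      vfit <- models[[ph]][[rate]]
      nd <- means_newdata(vfit, relev = r)
      inv <- if (rate == "survival") stats::plogis else identity
      pr <- draw_predictions(vfit, nd, n_draws, inv)
      if (rate == "growth") {
        iv <- vfit$interval_yr
        pr$point <- (pr$point - nd$dbh_prev) / iv
        pr$draws <- (drop(pr$draws) - nd$dbh_prev) / iv
      } else pr$draws <- drop(pr$draws)
      pr
    })
    con <- if (r >= 0.5) "EV" else "DE"
    het <- setdiff(c("EV", "DE"), con)
    rel <- function(c_, h_) (c_ - h_) / h_ * 100
    est <- rel(pv[[con]]$point, pv[[het]]$point)
    dr <- rel(pv[[con]]$draws, pv[[het]]$draws)
    ci <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    data.frame(rate = rate, relev = r, con = con, hetero = het,
               con_value = pv[[con]]$point, hetero_value = pv[[het]]$point,
               rel_diff_pct = est, lo95 = ci[1], hi95 = ci[2],
               n_draws = n_draws, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Con- vs hetero-phenological recruitment ratio
#'
#' Predicted recruitment-rate ratio of the resident over the minority
#' phenology at relEV 0.9 (evergreen-dominated) and 0.1
#' (deciduous-dominated), other predictors at training means (including each
#' model's own con-phenological basal area).
#'
#' @inheritParams predict_survival_growth_contrast
#' @param relev_points default \code{c(0.1, 0.9)}.
#' @param hetero_floor ratios whose denominator rate falls below this are
#'   flagged unstable.
#' @return data.frame with one row per relEV point: rates, ratio, 95\%
#'   interval, \code{unstable} flag.
#' @export
predict_recruitment_ratio <- function(models, relev_points = c(0.1, 0.9),
                                      n_draws = 100, seed = 1,
                                      hetero_floor = 1e-8) {
  stopifnot(inherits(models, "vital_rate_models"))
  if (!models$feedback)
    stop("ratio undefined for null-variant models (no relEV term)")
  set.seed(seed)
  out <- do.call(rbind, lapply(relev_points, function(r) {
    pv <- lapply(c(EV = "EV", DE = "DE"), function(ph) {
      vfit <- models[[ph]]$recruitment
      nd <- means_newdata(vfit, relev = r)
      pr <- draw_predictions(vfit, nd, n_draws, exp)
      pr$draws <- drop(pr$draws)
      pr
    })
    con <- if (r >= 0.5) "EV" else "DE"
    het <- setdiff(c("EV", "DE"), con)
    ratio <- pv[[con]]$point / pv[[het]]$point
    dr <- pv[[con]]$draws / pv[[het]]$draws
    ci <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    data.frame(relev = r, con = con, hetero = het,
               con_rate = pv[[con]]$point, hetero_rate = pv[[het]]$point,
               ratio = ratio, lo95 = ci[1], hi95 = ci[2],
               unstable = pv[[het]]$point < hetero_floor,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
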