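# ---------------------------------------------------------------------------
# Environmental-filtering null model: if only the environment (through the
# plot-specific hurdle parameters) drives evergreen and deciduous abundances,
# simulated relEV histograms bracket what the observed one should look like.
# Observed mass piling up in the outer bins (0-0.05 and 0.95-1) beyond the
# 97.5% envelope, and an observed EV-DE rank correlation more negative than
# every null draw, point to feedbacks beyond environmental filtering.
# ---------------------------------------------------------------------------

#' Null ensemble of relative evergreen abundance distributions
#'
#' Fits are taken as given (one [fit_zap()] model per leaf type on the same
#' plots). Each replicate draws independent evergreen and deciduous counts
#' per plot from the plot-specific hurdle parameters, keeps plots with at
#' least \code{min_trees} trees (re-applied per replicate), computes the
#' stem-count relEV, and bins it at width 0.05 on \[0, 1\]. Per-bin 2.5% and
#' 97.5% quantiles over the replicates form the envelope.
#'
#' @param fit_ev,fit_de fitted \code{zap_model}s for the two leaf types.
#' @param env_pcs environmental PCs of the same plots the models were fit on.
#' @param observed optional data.frame/list with \code{ev_count},
#'   \code{de_count}: observed abundances to overlay and dip-test.
#' @param n_rep number of null replicates (default 1000).
#' @param min_trees per-replicate minimum stem count for a plot to enter the
#'   relEV distribution (default 10).
#' @param bin_width histogram bin width (default 0.05).
#' @param seed integer seed.
#' @param dip_p_value if TRUE and \code{observed} given, attach a Monte-Carlo
#'   dip p-value for the observed relEV distribution.
#' @return list with \code{bins} (data.frame: lower, upper, observed, q025,
#'   q975, exceeds_upper, below_lower), \code{outer_exceedance} (logical for
#'   the two outer bins), \code{n_rep_used}, and when observed data are given
#'   \code{observed_relev} plus optionally \code{dip} (data.frame D, p).
#' @export
null_relev_ensemble <- function(fit_ev, fit_de, env_pcs, observed = NULL,
                                n_rep = 1000, min_trees = 10,
                                bin_width = 0.05, seed = 1,
                                dip_p_value = FALSE) {
  par_ev <- predict(fit_ev, env_pcs)
  par_de <- predict(fit_de, env_pcs)
  n <- nrow(par_ev)
  breaks <- seq(0, 1, by = bin_width)
  nb <- length(breaks) - 1
  hist_freq <- function(ev, de) {
    keep <- (ev + de) >= min_trees
    if (!any(keep)) return(NULL)
    relev <- ev[keep] / (ev[keep] + de[keep])
    b <- pmin(floor(relev / bin_width) + 1L, nb)  # right-closed last bin
    tabulate(b, nbins = nb) / sum(keep)
  }
  set.seed(seed)
  reps <- matrix(NA_real_, n_rep, nb)
  dropped <- 0L
  for (r in seq_len(n_rep)) {
    h <- hist_freq(rzap(n, par_ev$pi0, par_ev$mu), rzap(n, par_de$pi0, par_de$mu))
    if (is.null(h)) dropped <- dropped + 1L else reps[r, ] <- h
  }
  if (dropped > 0) warning(dropped, " replicates had no qualifying plots and were dropped")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (nrow(reps) == 0) stop("every replicate had zero qualifying plots")
  q <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975))
  bins <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                     q025 = q[1, ], q975 = q[2, ], null_median = apply(reps, 2, stats::median))
  out <- list(bins = bins, reps = reps, n_rep_used = nrow(reps), min_trees = min_trees)
  if (!is.null(observed)) {
    h_obs <- hist_freq(observed$ev_count, observed$de_count)
    bins$observed <- h_obs
    bins$exceeds_upper <- h_obs > bins$q975
    bins$below_lower <- h_obs < bins$q025
    out$bins <- bins
    out$outer_exceedance <- bins$exceeds_upper[c(1, nb)]
    keep <- (observed$ev_count + observed$de_count) >= min_trees
    out$observed_relev <- observed$ev_count[keep] /
      (observed$ev_count[keep] + observed$de_count[keep])
    if (dip_p_value) {
      d <- dip_statistic(out$observed_relev)
      out$dip <- data.frame(D = d,
                            p = dip_pvalue_mc(d, length(out$observed_relev),
                                              n_null = 999, seed = seed + 1L))
    }
  }
  out
}

#' Spearman coupling test of evergreen vs deciduous abundance
#'
#' Compares the observed Spearman rank correlation (midranks for ties)
#' between plot-level evergreen and deciduous counts with its null
#' distribution under environment-only hurdle draws. The one-sided p-value is
#' the fraction of null replicates at least as negative as the observation
#' (the alternative being "more anticorrelated than environmental filtering
#' explains").
#'
#' @param ev_count,de_count observed counts per plot.
#' @param fit_ev,fit_de fitted \code{zap_model}s.
#' @param env_pcs environmental PCs of the same plots.
#' @param n_rep number of null replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{rho_obs}, \code{rho_null} (vector), \code{p}.
#' @export
spearman_coupling_test <- function(ev_count, de_count, fit_ev, fit_de,
                                   env_pcs, n_rep = 1000, seed = 1) {
  if (stats::sd(ev_count) == 0 || stats::sd(de_count) == 0)
    stop("Spearman correlation undefined for a constant abundance vector")
  rho_obs <- stats::cor(ev_count, de_count, method = "spearman")
  par_ev <- predict(fit_ev, env_pcs)
  par_de <- predict(fit_de, env_pcs)
  n <- nrow(par_ev)
  set.seed(seed)
  rho_null <- vapply(seq_len(n_rep), function(r) {
    stats::cor(rzap(n, par_ev$pi0, par_ev$mu),
               rzap(n, par_de$pi0, par_de$mu), method = "spearman")
  }, 0)
  list(rho_obs = rho_obs, rho_null = rho_null, p = mean(rho_null <= rho_obs))
}
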