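#' Hartigan's dip statistic
#'
#' The dip of a sample is the maximum distance between its empirical CDF and
#' the closest unimodal CDF (convex up to some mode, concave after it). It is
#' the basis of the dip test of unimodality: large values indicate
#' multimodality. The statistic is invariant under affine transforms of the
#' sample and satisfies \eqn{1/(2n) \le D \le 1/4} for samples with at least
#' two distinct values.
#'
#' The implementation performs an exact bisection on the sup-distance: a
#' distance \eqn{\epsilon} is achievable if and only if, for some candidate
#' mode (an observed value, where the unimodal CDF may place an atom), a
#' convex CDF piece fits the \eqn{\pm\epsilon} bands to the left and a concave
#' piece fits them to the right; each one-sided check reduces to a convex-hull
#' comparison of the band limits.
#'
#' @param x numeric vector, at least 4 observations.
#' @return the dip statistic \eqn{D} (a single number).
#' @examples
#' dip_statistic(c(rep(0, 15), rep(1, 15))) # 0.25, the largest possible dip
#' dip_statistic(runif(100))
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("dip_statistic() needs at least 4 finite observations")
  .dip_cpp(x)
}

#' Monte-Carlo p-value for the dip test
#'
#' The null distribution of the dip is simulated from uniform samples of the
#' same size (the uniform is the classical least-favourable unimodal null).
#' The p-value is the fraction of null samples whose dip is at least as large
#' as the observed one.
#'
#' @param d observed dip statistic.
#' @param n sample size of the observed sample.
#' @param n_null number of null samples.
#' @param seed optional integer seed for the null draws.
#' @return p-value in \[0, 1\].
#' @export
dip_pvalue_mc <- function(d, n, n_null = 2000, seed = NULL) {
  stopifnot(is.finite(d), d >= 0, n >= 4)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  null_d <- vapply(seq_len(n_null), function(i) .dip_cpp(stats::runif(n)), 0)
  mean(null_d >= d)
}

#' Sample-size adapted dip statistic
#'
#' \eqn{D' = \sqrt{n}\,D}. The rescaling makes the statistic comparable across
#' clusters of different size: under a unimodal null the dip shrinks like
#' \eqn{1/\sqrt{n}}, so \eqn{D'} is roughly size-free.
#'
#' @param d dip statistic.
#' @param n sample size.
#' @export
adapted_dip <- function(d, n) {
  stopifnot(all(d >= 0), all(n >= 1))
  sqrt(n) * d
}

#' Skewness-signed bimodality index
#'
#' \eqn{BI = -e^{-a D'^b} \mathrm{sign}(S)} where \eqn{D'} is the adapted dip
#' and \eqn{S} the sample skewness of the relative evergreen abundance. BI is
#' close to 0 for clearly bimodal samples and approaches \eqn{\pm 1} for
#' unimodal ones: negative for deciduous dominance (\eqn{S > 0}, mass piled at
#' low relEV) and positive for evergreen dominance (\eqn{S < 0}). With the
#' defaults \eqn{a = 6}, \eqn{b = 2}, the dip threshold \eqn{D' = 0.5} maps to
#' \eqn{|BI| = e^{-1.5} \approx 0.22}, the classification cutoff.
#'
#' The grouping is \eqn{-\exp(-a (D')^b)}: only this reading reproduces the
#' 0.22 cutoff (\eqn{\exp(-6 \cdot 0.25) = 0.2231}).
#'
#' @param d_prime adapted dip statistic(s), non-negative.
#' @param s sample skewness (only its sign is used; \code{sign(0) = 0} gives
#'   \code{BI = 0}).
#' @param a,b shape parameters controlling the range of BI.
#' @return BI in \[-1, 1\].
#' @export
bimodality_index <- function(d_prime, s, a = 6, b = 2) {
  stopifnot(all(d_prime >= 0))
  -exp(-a * d_prime^b) * sign(s)
}

#' Classify a bimodality index into the four forest-state labels
#'
#' Cutoffs at \eqn{\pm 0.22} (from the \eqn{D' = 0.5} dip threshold):
#' BI < -0.22 deciduous-dominated; -0.22 <= BI < 0 bistable deciduous;
#' 0 <= BI <= 0.22 bistable evergreen (BI = 0 falls here by convention);
#' BI > 0.22 evergreen-dominated.
#'
#' @param bi bimodality index value(s) in \[-1, 1\].
#' @param cutoff classification cutoff, default 0.22.
#' @return factor with levels \code{deciduous_dominated}, \code{bistable_deciduous},
#'   \code{bistable_evergreen}, \code{evergreen_dominated}.
#' @export
classify_bi <- function(bi, cutoff = 0.22) {
  if (any(abs(bi) > 1 + 1e-12, na.rm = TRUE)) stop("|BI| must be <= 1")
  lab <- ifelse(bi < -cutoff, "deciduous_dominated",
         ifelse(bi < 0,       "bistable_deciduous",
         ifelse(bi <= cutoff, "bistable_evergreen", "evergreen_dominated")))
  factor(lab, levels = c("deciduous_dominated", "bistable_deciduous",
                         "bistable_evergreen", "evergreen_dominated"))
}

#' Bias-adjusted sample skewness
#'
#' Fisher-Pearson adjusted skewness (e1071 type 2). For relative evergreen
#' abundance, \eqn{S < 0} means mass concentrated at high relEV (evergreen
#' dominance) and \eqn{S > 0} deciduous dominance.
#'
#' @param x numeric vector, at least 3 values with non-zero variance.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("skewness needs at least 3 observations")
  if (stats::var(x) == 0) stop("skewness undefined for zero-variance sample")
  e1071::skewness(x, type = 2)
}

#' Full bimodality summary of a relEV sample
#'
#' Computes the dip, the adapted dip, the skewness, the bimodality index and
#' its class label for one sample of relative evergreen abundances, optionally
#' with a Monte-Carlo dip p-value.
#'
#' @param x sample of relEV values in \[0, 1\].
#' @param a,b BI shape parameters.
#' @param p_value if TRUE, add a Monte-Carlo dip p-value.
#' @param n_null,seed passed to [dip_pvalue_mc()].
#' @return one-row data.frame with n, D, D_prime, S, BI, label (and p_dip).
#' @export
bimodality_result <- function(x, a = 6, b = 2, p_value = FALSE,
                              n_null = 2000, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  d <- dip_statistic(x)
  s <- if (stats::var(x) == 0) 0 else sample_skewness(x)
  dp <- adapted_dip(d, n)
  bi <- bimodality_index(dp, s, a = a, b = b)
  out <- data.frame(n = n, D = d, D_prime = dp, S = s, BI = bi,
                    label = classify_bi(bi), stringsAsFactors = FALSE)
  if (p_value) out$p_dip <- dip_pvalue_mc(d, n, n_null = n_null, seed = seed)
  out
}
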