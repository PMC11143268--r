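# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

toy_inventory <- function() {
  utils::read.csv(system.file("extdata", "toy_inventory.csv", package = "phenostate"),
                  stringsAsFactors = FALSE)
}

# full-scale synthetic inventory with the headline effect sizes planted,
# plus feedback and null model fits (the expensive shared fixture)
acceptance_fixture <- function() {
  cached("acc", {
    p <- generator_params(n_plots = 3000, seed = 20240531)
    env <- generate_environment(p)
    inv <- generate_two_census_inventory(env, p)
    list(params = p, env = env, inv = inv,
         models_fb = fit_vital_rates(inv$trees, inv$plots, feedback = TRUE),
         models_null = fit_vital_rates(inv$trees, inv$plots, feedback = FALSE))
  })
}

# temperature-asymmetric variant for the hysteresis experiment
hysteresis_fixture <- function() {
  cached("hyst", {
    p <- generator_params(n_plots = 3000, seed = 20240531,
                          mat_survival_asym = 0.6, mat_recruit_asym = 0.6)
    env <- generate_environment(p)
    inv <- generate_two_census_inventory(env, p)
    list(params = p, env = env,
         models_fb = fit_vital_rates(inv$trees, inv$plots, feedback = TRUE,
                                     mat_term = TRUE),
         models_null = fit_vital_rates(inv$trees, inv$plots, feedback = FALSE,
                                       mat_term = TRUE))
  })
}

# small inventory for cheaper structural tests
small_inventory <- function() {
  cached("small", {
    p <- generator_params(n_plots = 800, seed = 3)
    env <- generate_environment(p)
    inv <- generate_two_census_inventory(env, p)
    list(params = p, env = env, inv = inv)
  })
}

# independent brute-force dip oracle: direct band-feasibility bisection with
# chord-defined hulls (O(m^3) per mode sweep; small n only). The greatest
# convex minorant value at a knot is computed from its definition as the
# minimum over all bracketing chords of the upper band points, independent of
# the incremental-hull implementation in the package.
dip_brute <- function(x, tol = 1e-9) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  cc <- cumsum(as.numeric(table(factor(x, levels = ux))))
  m <- length(ux)
  if (m == 1) return(0)
  cprev <- c(0, cc[-m])
  chord_min <- function(xs, ys, j) {
    # value at xs[j] of the lower hull of (xs, ys)
    v <- ys[j]
    for (i1 in seq_len(j)) for (i2 in j:length(xs)) {
      if (i1 == i2) next
      lam <- (xs[j] - xs[i1]) / (xs[i2] - xs[i1])
      v <- min(v, (1 - lam) * ys[i1] + lam * ys[i2])
    }
    v
  }
  feasible <- function(eps) {
    lo <- cc / n - eps
    hi <- cprev / n + eps
    left_ok <- function(k) {
      if (k == 1) return(TRUE)
      xs <- ux[1:k]; ys <- hi[1:k]
      all(vapply(seq_len(k - 1),
                 function(j) chord_min(xs, ys, j) >= lo[j] - 1e-12, TRUE))
    }
    right_ok <- function(k) {
      if (k == m) return(TRUE)
      xs <- ux[k:m]; ys <- lo[k:m]
      # upper hull via reflection
      vals <- vapply(seq_along(xs), function(j) -chord_min(xs, -ys, j), 0)
      all(vals[-1] <= hi[(k + 1):m] + 1e-12)
    }
    any(vapply(seq_len(m), function(k) left_ok(k) && right_ok(k), TRUE))
  }
  lo_e <- 0; hi_e <- 0.2500001
  while (hi_e - lo_e > tol) {
    mid <- (lo_e + hi_e) / 2
    if (feasible(mid)) hi_e <- mid else lo_e <- mid
  }
  hi_e
}
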