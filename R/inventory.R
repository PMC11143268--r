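#' @useDynLib phenostate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Two-census inventory data model.
#
# Tree table (one row per tree across a census interval):
#   tree_id, plot_id, species_id, phenology {EV, DE, UNKNOWN},
#   dbh_prev_cm (NA for recruits), dbh_curr_cm (NA for dead), fate
#   {survivor, died, recruit}.
# Plot table: plot_id, lon, lat, area_ha, interval_yr, env_pc1..env_pc10,
#   mat_c, det_* (seven key determinant covariates).
# ---------------------------------------------------------------------------

#' Basal area of a stem
#'
#' @param dbh_cm diameter at breast height in cm.
#' @return basal area in m^2 (\eqn{\pi (dbh/2)^2}).
#' @export
basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

tree_cols <- c("tree_id", "plot_id", "species_id", "phenology",
               "dbh_prev_cm", "dbh_curr_cm", "fate")

validate_trees <- function(trees) {
  miss <- setdiff(tree_cols, names(trees))
  if (length(miss)) stop("tree table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(trees$phenology %in% c("EV", "DE", "UNKNOWN")))
    stop("phenology must be EV, DE or UNKNOWN")
  if (!all(trees$fate %in% c("survivor", "died", "recruit")))
    stop("fate must be survivor, died or recruit")
  bad <- (trees$fate == "recruit" & (!is.na(trees$dbh_prev_cm) | is.na(trees$dbh_curr_cm))) |
         (trees$fate == "died" & !is.na(trees$dbh_curr_cm)) |
         (trees$fate == "survivor" & (is.na(trees$dbh_prev_cm) | is.na(trees$dbh_curr_cm)))
  if (any(bad)) stop(sum(bad), " tree records violate the fate/diameter invariants")
  invisible(trees)
}

#' Plot-level summaries of a two-census tree table
#'
#' For each plot, stem counts and basal areas per leaf-phenology type and the
#' two flavours of relative evergreen abundance:
#' \deqn{relEV_{area} = BA_{EV} / (BA_{EV} + BA_{DE})}
#' \deqn{relEV_{density} = n_{EV} / (n_{EV} + n_{DE})}
#' Basal area uses the first-census diameter where available (state at the
#' start of the exposure interval); recruits contribute via their current
#' diameter. Trees of unknown phenology never enter the relEV numerator or
#' denominator but are tracked as a basal-area fraction. When a plot has no
#' tree of known phenology both relEV fields are NA (undefined, not 0).
#'
#' @param trees tree table (see package overview for the schema).
#' @return data.frame with one row per plot: n_trees, n_first_census, n_ev,
#'   n_de, ba_ev, ba_de, ba_total, relev_area, relev_density, n_species,
#'   unknown_ba_frac, mortality_frac, n_recruits.
#' @export
plot_summaries <- function(trees) {
  validate_trees(trees)
  dbh <- ifelse(is.na(trees$dbh_prev_cm), trees$dbh_curr_cm, trees$dbh_prev_cm)
  ba <- basal_area_m2(dbh)
  pid <- factor(trees$plot_id, levels = unique(trees$plot_id))
  agg <- function(v, f = sum) as.numeric(tapply(v, pid, f, default = 0))
  is_ev <- trees$phenology == "EV"
  is_de <- trees$phenology == "DE"
  first <- trees$fate != "recruit"
  out <- data.frame(
    plot_id = levels(pid),
    n_trees = agg(rep(1, nrow(trees))),
    n_first_census = agg(as.numeric(first)),
    n_ev = agg(as.numeric(is_ev)),
    n_de = agg(as.numeric(is_de)),
    ba_ev = agg(ba * is_ev),
    ba_de = agg(ba * is_de),
    ba_total = agg(ba),
    n_species = as.numeric(tapply(trees$species_id, pid,
                                  function(s) length(unique(s)), default = 0)),
    n_recruits = agg(as.numeric(trees$fate == "recruit")),
    stringsAsFactors = FALSE
  )
  out$unknown_ba_frac <- ifelse(out$ba_total > 0,
                                1 - (out$ba_ev + out$ba_de) / out$ba_total, 0)
  died <- agg(as.numeric(trees$fate == "died"))
  out$mortality_frac <- ifelse(out$n_first_census > 0, died / out$n_first_census, NA_real_)
  denom_a <- out$ba_ev + out$ba_de
  denom_d <- out$n_ev + out$n_de
  out$relev_area <- ifelse(denom_a > 0, out$ba_ev / denom_a, NA_real_)
  out$relev_density <- ifelse(denom_d > 0, out$n_ev / denom_d, NA_real_)
  # single-species dominance (largest species share of total basal area)
  sp_ba <- tapply(ba, list(pid, factor(trees$species_id)), sum, default = 0)
  out$max_species_ba_frac <- ifelse(out$ba_total > 0,
                                    apply(sp_ba, 1, max) / out$ba_total, NA_real_)
  rownames(out) <- NULL
  out
}

#' Summary for a single plot
#'
#' Convenience wrapper around [plot_summaries()] for one plot's trees.
#'
#' @param trees tree table restricted to one plot.
#' @return one-row summary data.frame.
#' @export
compute_plot_summary <- function(trees) {
  if (length(unique(trees$plot_id)) != 1) stop("expected trees of a single plot")
  plot_summaries(trees)
}

#' Inclusion filter criteria for inventory plots
#'
#' Mirrors the inventory preprocessing rules: at least \code{min_trees}
#' individuals, at most \code{max_unknown_ba_frac} of basal area with unknown
#' phenology, at most \code{max_mortality_frac} of first-census trees dead
#' (guards against stand-replacing outbreaks), at least \code{min_species}
#' species and no single species holding more than
#' \code{max_single_species_ba_frac} of basal area (guards against
#' plantations). Each rule can be toggled per dataset dialect.
#'
#' @param min_trees minimum tree count (default 10).
#' @param max_unknown_ba_frac maximum unknown-phenology basal-area fraction
#'   (default 0.10, i.e. >90\% of basal area must have a known leaf type).
#' @param max_mortality_frac maximum dead fraction of first-census trees
#'   (default 0.50).
#' @param min_species minimum species count (default 2).
#' @param max_single_species_ba_frac maximum basal-area share of any single
#'   species (default 0.90).
#' @param enable named logical vector switching individual rules on or off;
#'   names among \code{min_trees, unknown_ba, mortality, min_species,
#'   single_species_ba}.
#' @export
filter_criteria <- function(min_trees = 10, max_unknown_ba_frac = 0.10,
                            max_mortality_frac = 0.50, min_species = 2,
                            max_single_species_ba_frac = 0.90,
                            enable = NULL) {
  fr <- c(max_unknown_ba_frac, max_mortality_frac, max_single_species_ba_frac)
  if (any(fr < 0 | fr > 1)) stop("filter fractions must lie in [0, 1]")
  en <- c(min_trees = TRUE, unknown_ba = TRUE, mortality = TRUE,
          min_species = TRUE, single_species_ba = TRUE)
  if (!is.null(enable)) {
    bad <- setdiff(names(enable), names(en))
    if (length(bad)) stop("unknown filter toggles: ", paste(bad, collapse = ", "))
    en[names(enable)] <- enable
  }
  structure(list(min_trees = min_trees,
                 max_unknown_ba_frac = max_unknown_ba_frac,
                 max_mortality_frac = max_mortality_frac,
                 min_species = min_species,
                 max_single_species_ba_frac = max_single_species_ba_frac,
                 enable = en),
            class = "filter_criteria")
}

#' Apply the plot inclusion filters
#'
#' A plot is kept iff it passes every enabled rule. The audit table counts
#' each excluded plot once, under the first rule it fails, in the fixed order
#' min_trees, unknown_ba, mortality, min_species, single_species_ba (so the
#' audit is reproducible even though the kept set does not depend on order).
#'
#' @param trees tree table.
#' @param plots plot table (may be NULL; then only summaries are filtered).
#' @param criteria a [filter_criteria()] object.
#' @return list with \code{summaries} (kept plots' summaries), \code{plots}
#'   (kept rows of \code{plots}, if given), \code{trees} (kept trees),
#'   \code{kept_ids}, and \code{audit} (data.frame rule / n_excluded).
#' @export
apply_inclusion_filters <- function(trees, plots = NULL,
                                    criteria = filter_criteria()) {
  rules <- c("min_trees", "unknown_ba", "mortality", "min_species",
             "single_species_ba")
  if (nrow(trees) == 0) {
    return(list(summaries = plot_summaries(trees[0, , drop = FALSE]),
                plots = if (!is.null(plots)) plots[0, , drop = FALSE],
                trees = trees, kept_ids = character(0),
                audit = data.frame(rule = rules, n_excluded = 0L)))
  }
  s <- plot_summaries(trees)
  en <- criteria$enable
  fails <- cbind(
    min_trees = en["min_trees"] & s$n_trees < criteria$min_trees,
    unknown_ba = en["unknown_ba"] & s$unknown_ba_frac > criteria$max_unknown_ba_frac,
    mortality = en["mortality"] & !is.na(s$mortality_frac) &
      s$mortality_frac > criteria$max_mortality_frac,
    min_species = en["min_species"] & s$n_species < criteria$min_species,
    single_species_ba = en["single_species_ba"] & !is.na(s$max_species_ba_frac) &
      s$max_species_ba_frac > criteria$max_single_species_ba_frac
  )
  first_fail <- apply(fails, 1, function(z) if (any(z)) rules[which(z)[1]] else NA)
  keep <- is.na(first_fail)
  audit <- data.frame(rule = rules,
                      n_excluded = as.integer(table(factor(first_fail, levels = rules))))
  kept_ids <- s$plot_id[keep]
  list(summaries = s[keep, , drop = FALSE],
       plots = if (!is.null(plots)) plots[plots$plot_id %in% kept_ids, , drop = FALSE],
       trees = trees[trees$plot_id %in% kept_ids, , drop = FALSE],
       kept_ids = kept_ids,
       audit = audit)
}

#' Principal components of an environmental covariate table
#'
#' Standardizes the covariates (zero mean, unit variance), drops constant
#' columns with a warning, and returns the leading principal-component scores
#' with their explained-variance fractions. Used to reduce a large covariate
#' panel to the ten orthogonal predictors entering all demographic models.
#'
#' @param covariates numeric matrix or data.frame, plots x covariates.
#' @param n_components number of leading components to return.
#' @return list with \code{scores} (plots x n_components), \code{explained}
#'   (fraction of variance per returned component), \code{cumulative}
#'   (cumulative fraction), \code{rotation}, \code{dropped} (names of constant
#'   columns removed).
#' @export
env_pca <- function(covariates, n_components = 10) {
  x <- as.matrix(covariates)
  if (!is.numeric(x)) stop("covariates must be numeric")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant covariate columns: ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (n_components > min(dim(x))) stop("n_components exceeds the rank bound")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained = ev[seq_len(n_components)],
       cumulative = cumsum(ev)[seq_len(n_components)],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       dropped = dropped)
}

#' Read a two-census inventory from CSV files
#'
#' @param tree_csv path to the tree table (columns tree_id, plot_id,
#'   species_id, phenology, dbh_prev_cm, dbh_curr_cm, fate; empty fields are
#'   missing values).
#' @param plot_csv optional path to the plot table.
#' @return list with \code{trees} and (if given) \code{plots}.
#' @export
read_inventory <- function(tree_csv, plot_csv = NULL) {
  trees <- utils::read.csv(tree_csv, stringsAsFactors = FALSE)
  validate_trees(trees)
  out <- list(trees = trees)
  if (!is.null(plot_csv)) out$plots <- utils::read.csv(plot_csv, stringsAsFactors = FALSE)
  out
}

# normalize longitudes to [-180, 180)
normalize_lon <- function(lon) ((lon + 180) %% 360) - 180
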