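# ---------------------------------------------------------------------------
# Spatial (fishing-net) and environmental (k-means) clustering of plots, the
# per-cluster bimodality table, and bootstrap permutation importance of the
# seven key determinants.
# ---------------------------------------------------------------------------

#' Fishing-net (regular lon/lat grid) clusters
#'
#' Cells are half-open squares of \code{cell_arcmin} arc-minutes:
#' cell id = (floor(lon/delta), floor(lat/delta)) with delta = cell_arcmin/60
#' degrees. Longitude is normalized to \[-180, 180). Clusters with fewer than
#' \code{min_plots} plots are dropped.
#'
#' @param plots plot table with lon and lat in decimal degrees (WGS84).
#' @param cell_arcmin grid size in arc-minutes (default 10, roughly 20 km).
#' @param min_plots minimum plots per retained cluster (default 10).
#' @return object of class \code{cluster_set}: method, cell size, and a
#'   \code{membership} data.frame (plot_id, cluster_id; dropped plots absent).
#' @export
fishing_net_clusters <- function(plots, cell_arcmin = 10, min_plots = 10) {
  if (any(abs(plots$lat) > 90)) stop("latitude outside [-90, 90]")
  delta <- cell_arcmin / 60
  lon <- normalize_lon(plots$lon)
  cell <- paste0(floor(lon / delta), "_", floor(plots$lat / delta))
  tab <- table(cell)
  keep <- cell %in% names(tab)[tab >= min_plots]
  structure(list(method = "fishing_net", cell_arcmin = cell_arcmin,
                 min_plots = min_plots,
                 membership = data.frame(plot_id = plots$plot_id[keep],
                                         cluster_id = cell[keep],
                                         stringsAsFactors = FALSE)),
            class = "cluster_set")
}

#' Environmental k-means clusters
#'
#' Standard k-means on the leading three environmental principal components,
#' with seeded determinism. Small clusters are dropped, and their plots are
#' excluded from downstream bimodality summaries.
#'
#' @param plots plot table with env_pc1..env_pc3.
#' @param k number of clusters.
#' @param n_pcs number of leading components used (default 3).
#' @param seed integer seed.
#' @param min_plots minimum plots per retained cluster (default 10).
#' @param nstart k-means restarts (default 5).
#' @export
kmeans_env_clusters <- function(plots, k, n_pcs = 3, seed = 1, min_plots = 10,
                                nstart = 5) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(plots)) stop("k exceeds the number of plots")
  x <- as.matrix(plots[, paste0("env_pc", seq_len(n_pcs)), drop = FALSE])
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50)
  cl <- paste0("k", km$cluster)
  tab <- table(cl)
  keep <- cl %in% names(tab)[tab >= min_plots]
  structure(list(method = "kmeans_env", k = k, n_pcs = n_pcs,
                 min_plots = min_plots,
                 membership = data.frame(plot_id = plots$plot_id[keep],
                                         cluster_id = cl[keep],
                                         stringsAsFactors = FALSE)),
            class = "cluster_set")
}

#' Bimodality summary per cluster
#'
#' Dip statistic, adapted dip, skewness, bimodality index and class label of
#' the relEV distribution within each retained cluster.
#'
#' @param clusters a \code{cluster_set}.
#' @param relev named vector of plot relEV values (names = plot ids), or a
#'   data.frame with plot_id and relev columns.
#' @param a,b BI shape parameters.
#' @return data.frame with one row per cluster (cluster_id, n, D, D_prime, S,
#'   BI, label).
#' @export
cluster_bimodality <- function(clusters, relev, a = 6, b = 2) {
  if (is.data.frame(relev)) relev <- stats::setNames(relev$relev, relev$plot_id)
  m <- clusters$membership
  m$relev <- relev[m$plot_id]
  m <- m[!is.na(m$relev), , drop = FALSE]
  res <- lapply(split(m$relev, m$cluster_id), function(x) {
    if (length(x) < max(4, clusters$min_plots)) return(NULL)
    r <- bimodality_result(x, a = a, b = b)
    r
  })
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {
    return(data.frame(cluster_id = character(0), n = integer(0), D = numeric(0),
                      D_prime = numeric(0), S = numeric(0), BI = numeric(0),
                      label = factor(character(0),
                                     levels = levels(classify_bi(0)))))
  }
  out <- do.call(rbind, res[ok])
  out <- cbind(cluster_id = names(res)[ok], out)
  rownames(out) <- NULL
  out
}

#' Bootstrap permutation importance of the key determinants
#'
#' Fits a random-forest regressor on \code{n_boot} bootstrap subsamples of
#' proportion \code{frac}, evaluates on the out-of-sample rows, and measures
#' each feature's importance as the increase in mean squared prediction
#' error when that feature's values are permuted. Returns the bootstrap mean
#' and standard deviation per feature.
#'
#' @param features data.frame/matrix of predictors (e.g. the seven key
#'   determinants).
#' @param response numeric response (BI per cluster, or plot relEV).
#' @param n_boot number of bootstrap fits (default 100).
#' @param frac sampling proportion per fit (default 1/3).
#' @param seed integer seed.
#' @param num_trees trees per forest (default 100).
#' @return data.frame feature / importance_mean / importance_sd, ordered by
#'   decreasing mean importance.
#' @export
permutation_importance <- function(features, response, n_boot = 100,
                                   frac = 1/3, seed = 1, num_trees = 100) {
  x <- as.data.frame(features)
  y <- as.numeric(response)
  if (stats::sd(y) == 0) stop("constant response: importance undefined")
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  p <- ncol(x)
  imp <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, names(x)))
  n <- nrow(x)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, max(2, round(frac * n)))
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) < 2) oob <- seq_len(n)
    d <- cbind(y = y[idx], x[idx, , drop = FALSE])
    rf <- ranger::ranger(y ~ ., data = d, num.trees = num_trees,
                         seed = seed + b, num.threads = 1)
    xo <- x[oob, , drop = FALSE]
    base_mse <- mean((stats::predict(rf, xo, num.threads = 1)$predictions - y[oob])^2)
    for (j in seq_len(p)) {
      xp <- xo
      xp[[j]] <- xp[[j]][sample.int(nrow(xp))]
      mse_j <- mean((stats::predict(rf, xp, num.threads = 1)$predictions - y[oob])^2)
      imp[b, j] <- mse_j - base_mse
    }
  }
  out <- data.frame(feature = colnames(imp),
                    importance_mean = colMeans(imp),
                    importance_sd = apply(imp, 2, stats::sd))
  out <- out[order(-out$importance_mean), ]
  rownames(out) <- NULL
  out
}
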