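mk_trees <- function(plot, phen, dbh, fate = "survivor", species = "sp") {
  n <- length(phen)
  data.frame(tree_id = paste0(plot, seq_len(n)), plot_id = plot,
             species_id = rep_len(species, n), phenology = phen,
             dbh_prev_cm = ifelse(fate == "recruit", NA, dbh),
             dbh_curr_cm = ifelse(fate == "died", NA, dbh),
             fate = rep_len(fate, n), stringsAsFactors = FALSE)
}

test_that("relEV follows the basal-area and stem-density definitions", {
  s <- compute_plot_summary(mk_trees("a", rep(c("EV", "DE"), c(9, 1)), 20))
  expect_equal(s$relev_density, 0.9)
  expect_equal(s$relev_area, 0.9)  # equal diameters
  # equal basal areas per type -> 0.5 by symmetry
  s2 <- compute_plot_summary(mk_trees("b", c("EV", "DE"), c(30, 30)))
  expect_equal(s2$relev_area, 0.5)
  expect_equal(s2$ba_ev, basal_area_m2(30))
  # no evergreens -> 0 (not NA)
  s3 <- compute_plot_summary(mk_trees("c", rep("DE", 5), 20))
  expect_equal(s3$relev_area, 0)
  expect_equal(s3$relev_density, 0)
  # all UNKNOWN -> undefined, not 0
  s4 <- compute_plot_summary(mk_trees("d", rep("UNKNOWN", 5), 20))
  expect_true(is.na(s4$relev_area) && is.na(s4$relev_density))
  expect_equal(s4$unknown_ba_frac, 1)
})

test_that("relEV is invariant to ordering and duplication; flavours agree", {
  inv <- small_inventory()
  tr <- inv$inv$trees
  s1 <- plot_summaries(tr)
  s2 <- plot_summaries(tr[sample.int(nrow(tr)), ])
  expect_equal(s1$relev_area, s2$relev_area[match(s1$plot_id, s2$plot_id)])
  one <- tr[tr$plot_id == tr$plot_id[1], ]
  dup <- rbind(one, transform(one, tree_id = paste0(tree_id, "x")))
  expect_equal(compute_plot_summary(dup)$relev_area,
               compute_plot_summary(one)$relev_area)
  # area- and density-based relEV are close and strongly rank-correlated
  ok <- !is.na(s1$relev_area) & !is.na(s1$relev_density)
  expect_lt(max(abs(s1$relev_area[ok] - s1$relev_density[ok])), 0.25)
  expect_gt(cor(s1$relev_area[ok], s1$relev_density[ok], method = "spearman"), 0.9)
})

test_that("inclusion filters keep the right plots and audit the first failure", {
  toy <- toy_inventory()
  f <- apply_inclusion_filters(toy)
  expect_setequal(f$kept_ids, c("keep12", "keep11", "keep14"))
  expect_equal(sum(f$audit$n_excluded), 5)
  expect_true(all(f$audit$n_excluded == 1))
  # named single-rule cases
  expect_equal(f$audit$n_excluded[f$audit$rule == "min_trees"], 1)       # 9 trees
  expect_equal(f$audit$n_excluded[f$audit$rule == "mortality"], 1)       # 60% dead
  # filters are idempotent
  f2 <- apply_inclusion_filters(f$trees)
  expect_setequal(f2$kept_ids, f$kept_ids)
  expect_equal(sum(f2$audit$n_excluded), 0)
  # empty input: empty output plus empty audit, no failure
  f0 <- apply_inclusion_filters(toy[0, ])
  expect_equal(length(f0$kept_ids), 0)
  expect_equal(sum(f0$audit$n_excluded), 0)
  # toggles disable individual rules
  crit <- filter_criteria(enable = c(min_species = FALSE, single_species_ba = FALSE))
  f3 <- apply_inclusion_filters(toy, criteria = crit)
  expect_true(all(c("mono20", "dom30") %in% f3$kept_ids))
})

test_that("environmental PCA standardizes, orders and reports variance", {
  set.seed(11)
  # isotropic case: 10 of 53 components capture about 10/53 (sample
  # eigenvalue spread shrinks as rows >> columns)
  x <- matrix(rnorm(4000 * 53), 4000, 53)
  p <- env_pca(x, 10)
  expect_lt(abs(p$cumulative[10] - 10 / 53), 0.04)
  expect_true(all(diff(p$explained) <= 1e-12))
  # exact low-rank data: 3 components capture everything
  b <- matrix(rnorm(300 * 3), 300, 3)
  y <- b %*% matrix(rnorm(3 * 8), 3, 8)
  expect_equal(env_pca(y, 3)$cumulative[3], 1, tolerance = 1e-8)
  # planted covariance spectrum matches the eigenvalue oracle
  ev <- c(6, 3, 1)
  z <- matrix(rnorm(60000 * 3), ncol = 3) %*% diag(sqrt(ev))
  z <- scale(z)  # PCA standardizes anyway; oracle on the correlation scale
  r <- eigen(cor(z))$values
  expect_equal(env_pca(z, 3)$explained, r / sum(r), tolerance = 1e-8)
  # constant column dropped with a warning
  xc <- cbind(x[, 1:5], const = 1)
  expect_warning(pc <- env_pca(xc, 3), "constant")
  expect_equal(pc$dropped, "const")
})

test_that("inventory round-trips through CSV with missing-value fields", {
  toy <- toy_inventory()
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(toy, tmp, row.names = FALSE, na = "")
  back <- read_inventory(tmp)$trees
  expect_equal(nrow(back), nrow(toy))
  expect_equal(sum(is.na(back$dbh_curr_cm)), sum(is.na(toy$dbh_curr_cm)))
})
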