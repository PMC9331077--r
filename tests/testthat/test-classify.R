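test_that("binomial distance matches the formula, a loop oracle and vegan", {
  expect_equal(binomial_distance(c(2, 0), c(0, 2)), 2 * log(2))
  expect_equal(binomial_distance(c(5, 3), c(5, 3)), 0)

  # independent oracle: naive per-channel loop
  loop_oracle <- function(x, y) {
    d <- 0
    for (i in seq_along(x)) {
      n <- x[i] + y[i]
      if (n == 0) next
      m <- n / 2
      tx <- if (x[i] > 0) x[i] * log(x[i] / m) else 0
      ty <- if (y[i] > 0) y[i] * log(y[i] / m) else 0
      d <- d + (tx + ty) / n
    }
    d
  }
  set.seed(5)
  for (i in 1:100) {
    x <- rpois(20, 3)
    y <- rpois(20, 3)
    if (all(x + y == 0)) x[1] <- 1
    expect_equal(binomial_distance(x, y), loop_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(binomial_distance(x, y), binomial_distance(y, x))
    expect_gte(binomial_distance(x, y), 0)
  }
  expect_error(binomial_distance(c(-1, 2), c(1, 2)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(6)
  m <- matrix(rpois(5 * 12, 4), 5, 12)
  ours <- binomial_dist_matrix(m)
  theirs <- as.matrix(vegan::vegdist(m, method = "binomial"))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("NMDS reaches zero stress on exact configurations", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(X))
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  fit <- nmds(d, k = 2, n_restarts = 3, seed = 1)
  expect_lt(fit$stress, 1e-4)
  # fitted == observed case: disparities equal configuration distances
  expect_equal(length(fit$fitted), length(fit$observed))
})

test_that("NMDS stress is non-increasing and the best restart is kept", {
  cfg <- small_config(depth_mean = 3e7, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 53)
  dd <- deduplicate(coh$mutations)$unique
  sp <- sample_spectra(dd, coh$metadata)
  d <- binomial_dist_matrix(sp)
  fit <- nmds(d, k = 2, n_restarts = 4, max_iter = 100, seed = 2)
  expect_true(all(diff(fit$stress_trace) <= 1e-8))
  expect_gte(fit$stress, 0)
  # determinism given the seed
  fit2 <- nmds(d, k = 2, n_restarts = 4, max_iter = 100, seed = 2)
  expect_identical(fit$coords, fit2$coords)
  expect_identical(fit$stress, fit2$stress)
})

test_that("NMDS separates control from high-dose samples", {
  hits <- vapply(1:3, function(s) {
    cfg <- small_config(depth_mean = 1e8, n_per_dose = 3L)
    coh <- generate_cohort(cfg, seed = 300 + s)
    dd <- deduplicate(coh$mutations)$unique
    meta <- coh$metadata
    keep <- meta$dose %in% c(0, 50)
    sp <- sample_spectra(dd, meta, samples = meta$sample_id[keep])
    fit <- nmds(binomial_dist_matrix(sp), k = 2, n_restarts = 5, seed = s)
    grp <- meta$dose[match(rownames(fit$coords), meta$sample_id)]
    cd <- as.matrix(dist(fit$coords))
    same <- outer(grp, grp, "==") & upper.tri(cd)
    diff_ <- !outer(grp, grp, "==") & upper.tri(cd)
    mean(cd[diff_]) > mean(cd[same])
  }, logical(1))
  expect_true(all(hits))
})

test_that("Mantel test is exact on identical matrices and calibrated on nulls", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  d1 <- as.matrix(dist(X))
  r <- mantel_test(d1, d1, n_perm = 199, seed = 3)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 200)

  # null calibration: independent matrices, type-I error near alpha
  rejections <- vapply(1:200, function(i) {
    a <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    b <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    mantel_test(a, b, n_perm = 99, seed = i)$p <= 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.10)

  expect_error(mantel_test(matrix(0, 4, 4), d1[1:4, 1:4]), "constant")

  skip_if_not_installed("vegan")
  b <- as.matrix(dist(matrix(rnorm(20), 10, 2))) + 0.5 * d1
  expect_equal(mantel_test(d1, b, n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(d1, b, permutations = 9)$statistic),
               tolerance = 1e-10)
})

test_that("genic and intergenic spectra of one exposure process correlate", {
  cfg <- small_config(depth_mean = 2e8, n_per_dose = 3L)
  coh <- generate_cohort(cfg, seed = 61)
  dd <- deduplicate(coh$mutations)$unique
  rc <- cfg$panel$region_class[match(dd$target, cfg$panel$name)]
  sp_g <- sample_spectra(dd[rc == "genic", ], coh$metadata)
  sp_i <- sample_spectra(dd[rc == "intergenic", ], coh$metadata)
  r <- mantel_test(binomial_dist_matrix(sp_g), binomial_dist_matrix(sp_i),
                   n_perm = 199, seed = 4)
  expect_gt(r$r, 0)
  expect_lt(r$p, 0.05)
})

test_that("NSC at delta 0 reproduces plain nearest-centroid assignment", {
  set.seed(10)
  x <- matrix(rnorm(20 * 8), 20, 8)
  colnames(x) <- paste0("f", 1:8)
  labels <- rep(c("a", "b"), each = 10)
  x[labels == "b", 1:2] <- x[labels == "b", 1:2] + 1.5
  model <- nsc_train(x, labels, delta_grid = 0, cv_folds = 2, seed = 1)
  expect_equal(model$delta, 0)
  expect_equal(model$shrunk_centroids, model$centroids, tolerance = 1e-12)

  pred <- predict(model, x)$class
  # oracle: explicit standardized nearest-centroid loop
  scale_ <- model$pooled_sd + model$s0
  oracle <- apply(x, 1, function(row) {
    d2 <- vapply(model$classes, function(k) {
      sum(((row - model$centroids[k, ]) / scale_)^2)
    }, numeric(1))
    model$classes[which.min(d2)]
  })
  expect_identical(pred, unname(oracle))
})

test_that("total shrinkage leaves no active channels and prior-only calls", {
  set.seed(11)
  x <- matrix(rnorm(12 * 6), 12, 6)
  colnames(x) <- paste0("f", 1:6)
  labels <- rep(c("a", "b"), each = 6)
  big <- 1e6
  model <- suppressWarnings(
    nsc_train(x, labels, delta_grid = big, cv_folds = 2, seed = 1)
  )
  expect_length(model$active_channels, 0)
  pr <- predict(model, x)
  expect_true(all(abs(pr$a - 0.5) < 1e-9)) # equal priors, no signal
})

test_that("cross-validation recovers the channels carrying the signal", {
  # exposure excess concentrated on exactly three channels
  chs <- sbs_channels()
  three <- c("C[C>A]A", "C[C>A]C", "G[C>A]C")
  base <- rep(1 / 96, 96)
  names(base) <- chs
  boosted <- base
  boosted[three] <- boosted[three] + c(0.08, 0.16, 0.08)
  boosted <- boosted / sum(boosted)
  hits <- vapply(1:5, function(s) {
    set.seed(400 + s)
    n_mut <- 600
    draw <- function(p) as.numeric(stats::rmultinom(1, n_mut, p))
    x <- rbind(
      t(vapply(1:6, function(i) draw(base), numeric(96))),
      t(vapply(1:6, function(i) draw(boosted), numeric(96)))
    )
    colnames(x) <- chs
    pct <- 100 * x / n_mut
    labels <- rep(c("control", "exposed"), each = 6)
    model <- nsc_train(pct, labels, cv_folds = 6, seed = s)
    length(model$active_channels) > 0 &&
      all(model$active_channels %in% three)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the Gaussian discriminant reproduces its closed form", {
  params <- discriminant_params(
    exposed_mean = c(4.23, 10.3, 4.00),
    control_mean = c(1.38, 1.64, 0.80),
    scale = c(1.81, 4.11, 1.93)
  )
  # independent hand evaluation of the printed equations
  B <- ((4.23 - 1.38) / 1.81)^2 + ((10.3 - 1.64) / 4.11)^2 +
    ((4.00 - 0.80) / 1.93)^2
  expected <- exp(0) / (exp(0) + exp(-B / 2))
  p_exposed <- prob_exposed(c(4.23, 10.3, 4.00), params)
  expect_equal(p_exposed, expected, tolerance = 1e-12)
  expect_equal(p_exposed, 0.9921, tolerance = 1e-3)

  p_ctrl_point <- prob_exposed(c(1.38, 1.64, 0.80), params)
  expect_equal(p_ctrl_point, 1 - expected, tolerance = 1e-12)
  expect_equal(p_ctrl_point, 0.0079, tolerance = 2e-3)

  # complement identity and the equidistant point
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(3, 3, 2)
    expect_equal(prob_exposed(x, params) + prob_control(x, params), 1,
                 tolerance = 1e-12)
  }
  mid <- (params$exposed_mean + params$control_mean) / 2
  expect_equal(prob_exposed(mid, params), 0.5, tolerance = 1e-12)
  expect_error(prob_exposed(c(1, 2), params), "3 value")
})
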