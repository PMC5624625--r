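test_that("climate PCA compresses a low-rank climate field", {
  md <- toy_metadata(40, seed = 2)
  cp <- climate_pca(md)
  expect_equal(nrow(cp$scores), 40L)
  expect_equal(sum(cp$explained_fraction), 1, tolerance = 1e-9)

  # climate built from 2 latent factors + small noise: 2 axes retain > 95%
  set.seed(8)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  md2 <- md[rep(1, n), ]
  md2$plot_id <- sprintf("q%02d", 1:n)
  md2$t_ann <- 10 + 2 * f1 + rnorm(n, 0, 0.1)
  md2$t_jan <- -3 + 2 * f1 + rnorm(n, 0, 0.1)
  md2$t_aug <- 22 + 2 * f1 + rnorm(n, 0, 0.1)
  md2$t_grow <- 17 + 2 * f1 + rnorm(n, 0, 0.1)
  md2$t_diff <- 25 + 2 * f2 + rnorm(n, 0, 0.1)
  md2$p_ann <- exp(7 + 0.3 * f2 + rnorm(n, 0, 0.01))
  md2$p_grow <- exp(6.5 + 0.3 * f2 + rnorm(n, 0, 0.01))
  cp2 <- climate_pca(md2)
  expect_gt(cp2$cumulative[2], 0.95)

  md$t_ann <- 5
  expect_error(climate_pca(md), "constant")
})

test_that("habitat transforms hit their closed-form endpoints", {
  h <- transform_habitat(c(10, 20), c(0, 1))
  expect_equal(h$rar_t, c(0, pi / 2))
  expect_equal(transform_habitat(5, 0.5)$rar_t, pi / 4)
  # automatic offset: zero slopes switch the offset to 1
  expect_equal(transform_habitat(0, 0.2)$slope_t, 0)
  expect_equal(transform_habitat(c(10), c(0.3))$slope_t, log(10))
  expect_error(transform_habitat(5, 1.2), "rar")
})

test_that("simple OLS reports R2, slope sign and p", {
  x <- 1:20
  f <- suppressWarnings(simple_ols(2 * x, x))  # exact fit warns in summary.lm
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$sign, "+")
  set.seed(3)
  g <- simple_ols(-x + rnorm(20, 0, 0.5), x)
  expect_equal(g$sign, "-")
  expect_lt(g$p, 1e-6)
  expect_error(simple_ols(rnorm(10), rep(1, 10)), "zero-variance")
})

test_that("geographic distance matches the closed forms and haversine", {
  md <- data.frame(plot_id = c("a", "b"), latitude = c(38, 39),
                   longitude = c(128, 128))
  g <- geographic_distance(md)
  expect_equal(g["a", "b"], 6371000 * pi / 180, tolerance = 1e-6)

  md2 <- data.frame(plot_id = c("a", "b"), latitude = c(38, 38),
                    longitude = c(128, 129))
  g2 <- geographic_distance(md2)
  expect_equal(g2["a", "b"], 6371000 * pi / 180 * cos(38 * pi / 180),
               tolerance = 1e-6)

  md3 <- data.frame(plot_id = c("a", "b"), latitude = c(38.1, 38.1),
                    longitude = c(128.2, 128.2))
  expect_equal(geographic_distance(md3)["a", "b"], 0)

  skip_if_not_installed("geosphere")
  set.seed(4)
  for (i in 1:10) {
    lat <- 38 + runif(2, 0, 0.3)   # pairs < ~50 km apart
    lon <- 128 + runif(2, 0, 0.3)
    mdi <- data.frame(plot_id = c("a", "b"), latitude = lat,
                      longitude = lon)
    mine <- geographic_distance(mdi)["a", "b"]
    ref <- geosphere::distHaversine(c(lon[1], lat[1]), c(lon[2], lat[2]))
    expect_lt(abs(mine - ref) / ref, 0.01)
  }
})

test_that("environmental distances satisfy the Pythagorean identity", {
  md <- toy_metadata(12, seed = 5)
  env <- env_table(md)
  ed <- env_distances(env)
  expect_equal(ed$env^2, ed$clim^2 + ed$habit^2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # identical rows: zero everywhere
  env2 <- env[c(1, 1), ]; env2$plot_id <- c("a", "b")
  ed2 <- env_distances(env2)
  expect_true(all(sapply(ed2, max) == 0))

  # hand case: plots differing only in pc1 by 3
  env3 <- data.frame(plot_id = c("a", "b"), pc1_clim = c(0, 3),
                     pc2_clim = 0, slope_t = 1, rar_t = 0.5)
  ed3 <- env_distances(env3)
  expect_equal(ed3$clim["a", "b"], 3)
  expect_equal(ed3$env["a", "b"], 3)
  expect_equal(ed3$habit["a", "b"], 0)
})

test_that("Mantel r equals the triangle-vector correlation, p reproducible", {
  a <- random_dist(12, seed = 6)
  b <- random_dist(12, seed = 7)
  rownames(b) <- colnames(b) <- rownames(a)
  m <- mantel(a, b, n_perm = 99, seed = 1)
  expect_equal(m$r, pearson_stream(lower_triangle(a), lower_triangle(b)),
               tolerance = 1e-12)
  expect_equal(m$r, cor(lower_triangle(a), lower_triangle(b)),
               tolerance = 1e-12)

  expect_equal(mantel(a, a, n_perm = 9, seed = 1)$r, 1)
  expect_equal(mantel(a, 2 * a + 5 * (1 - diag(12)), n_perm = 9,
                      seed = 1)$r, 1, tolerance = 1e-12)

  expect_identical(mantel(a, b, n_perm = 99, seed = 3)$p,
                   mantel(a, b, n_perm = 99, seed = 3)$p)
  cc <- matrix(1, 12, 12, dimnames = dimnames(a)); diag(cc) <- 0
  expect_error(mantel(a, cc), "constant")

  skip_if_not_installed("vegan")
  vm <- vegan::mantel(as.dist(a), as.dist(b), permutations = 9)
  expect_equal(m$r, unname(vm$statistic), tolerance = 1e-10)
})

test_that("all-subsets AICc enumerates 2^k - 1 models with unit weights", {
  set.seed(10)
  n <- 50
  x <- replicate(4, rnorm(n))
  colnames(x) <- paste0("v", 1:4)
  y <- x[, 1] * 2 + rnorm(n, 0, 0.1)
  preds4 <- as.list(as.data.frame(x))
  ms4 <- all_subsets_aicc(y, preds4)
  expect_equal(nrow(ms4$models), 15L)
  ms3 <- all_subsets_aicc(y, preds4[1:3])
  expect_equal(nrow(ms3$models), 7L)
  expect_equal(sum(ms4$models$weight), 1, tolerance = 1e-9)
  expect_equal(ms4$models$delta[1], 0)
  expect_true(all(ms4$models$delta >= 0))

  # a (near-)exact predictor among noise: best model is that singleton
  y_exact <- 3 * x[, 2] + rnorm(n, 0, 0.01)
  ms_e <- all_subsets_aicc(y_exact, preds4)
  expect_equal(ms_e$best, "v2")

  # ranking invariant to adding a constant to the response
  ms_shift <- all_subsets_aicc(y + 100, preds4)
  expect_equal(ms_shift$models$model, ms4$models$model)
  expect_equal(ms_shift$models$weight, ms4$models$weight, tolerance = 1e-9)

  expect_warning(all_subsets_aicc(y, list(a = x[, 1], b = x[, 1])),
                 "collinear")
})

test_that("Akaike-weight importances behave as constructed", {
  set.seed(11)
  n <- 200
  strong <- rnorm(n); noise <- rnorm(n)
  y <- strong + rnorm(n, 0, 0.5)
  ms1 <- all_subsets_aicc(y, list(strong = strong))
  expect_equal(unname(importance_values(ms1)), 1)

  expect_warning(ms2 <- all_subsets_aicc(y, list(a = strong, b = strong)),
                 "collinear")
  iv2 <- importance_values(ms2)
  expect_equal(unname(iv2["a"]), unname(iv2["b"]), tolerance = 1e-9)

  ms3 <- all_subsets_aicc(y, list(strong = strong, noise = noise))
  iv3 <- importance_values(ms3)
  expect_gt(iv3["strong"], iv3["noise"])
  expect_gt(iv3["strong"], 0.99)
})

test_that("alpha variation partitioning decomposes R2 consistently", {
  set.seed(12)
  n <- 300
  a1 <- rnorm(n); b1 <- rnorm(n)
  y <- a1 + 0.5 * b1 + rnorm(n, 0, 0.7)
  vp <- variation_partition_alpha(y, list(a1 = a1), list(b1 = b1))
  expect_equal(vp$pure_a + vp$shared + vp$pure_b, vp$r2_full,
               tolerance = 1e-9)
  expect_equal(vp$pure_a + vp$shared + vp$pure_b + vp$unexplained, 1,
               tolerance = 1e-9)
  expect_lt(abs(vp$shared), 0.05)          # orthogonal blocks share ~0

  noise <- rnorm(n)
  vp2 <- variation_partition_alpha(y, list(a1 = a1), list(nz = noise))
  expect_lt(vp2$pure_b, 0.03)

  vp3 <- variation_partition_alpha(y, list(a1 = a1), list(a2 = a1 + 0))
  expect_lt(abs(vp3$pure_a), 1e-9)
  expect_lt(abs(vp3$pure_b), 1e-9)
  expect_error(variation_partition_alpha(y, list(a1 = a1),
                                         list(a1 = a1)), "disjoint")
})

test_that("MRM recovers exact structure and is reproducible", {
  g <- random_dist(14, seed = 13)
  e <- random_dist(14, seed = 14)
  rownames(e) <- colnames(e) <- rownames(g)
  fit <- mrm(g, list(geo = g, env = e), n_perm = 99, seed = 2)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["geo"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$p_coef["geo"]), 1 / 100)
  expect_true(is.na(fit$p_coef["(Intercept)"]))
  expect_identical(fit$p_coef,
                   mrm(g, list(geo = g, env = e), n_perm = 99,
                       seed = 2)$p_coef)
})

test_that("beta variation partitioning mirrors the alpha algebra", {
  g <- random_dist(13, seed = 15)
  e <- random_dist(13, seed = 16)
  rownames(e) <- colnames(e) <- rownames(g)
  yv <- 0.7 * g + 0.3 * e
  vp <- suppressWarnings(               # exact linear combination: lm warns
    variation_partition_beta(yv, list(geo = g), list(env = e)))
  expect_equal(vp$pure_a + vp$shared + vp$pure_b + vp$unexplained, 1,
               tolerance = 1e-9)
  expect_equal(vp$r2_full, 1, tolerance = 1e-9)
  expect_lt(vp$unexplained, 1e-9)

  vp_same <- suppressWarnings(
    variation_partition_beta(g, list(geo = g), list(env = e)))
  expect_lt(abs(vp_same$pure_b), 1e-9)
})
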