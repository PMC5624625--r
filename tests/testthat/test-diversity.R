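test_that("richness counts species with positive abundance", {
  comm <- rbind(p1 = c(0, 0, 0.5), p2 = c(1, 2, 3), p3 = c(2, 0, 0))
  colnames(comm) <- c("a", "b", "c")
  expect_equal(unname(richness(comm)), c(1L, 3L, 1L))
  expect_equal(unname(richness(comm, "p2")), 3L)
})

test_that("Bray-Curtis similarity matches hand values and vegan", {
  expect_equal(bray_curtis_similarity(c(2, 0, 1), c(2, 0, 1)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(bray_curtis_similarity(c(2, 0, 1), c(1, 1, 0)), 0.4)
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")

  skip_if_not_installed("vegan")
  comm <- random_comm(6, sprintf("sp%d", 1:9), seed = 4)
  ref <- 1 - as.matrix(vegan::vegdist(comm, method = "bray"))
  expect_equal(bray_curtis_matrix(comm), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("alpha MPD matches hand arithmetic and the double-loop oracle", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(mpd_alpha(d, c(A = 1, B = 1, C = 1)), 4)

  # equal pairwise distances: MPD = d regardless of the weights
  de <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  expect_equal(mpd_alpha(de, setNames(c(5, 1, 2, 9), letters[1:4])), 3)

  single <- mpd_alpha(d, c(A = 2, B = 0, C = 0))
  expect_true(is.na(single))
  expect_match(attr(single, "degenerate"), "fewer than 2")

  for (s in 1:5) {
    dd <- random_dist(15, seed = s)
    ab <- setNames(rpois(15, 2), rownames(dd))
    if (sum(ab > 0) < 2) ab[1:2] <- 1
    expect_equal(mpd_alpha(dd, ab), mpd_alpha_brute(dd, ab),
                 tolerance = 1e-12)
  }
})

test_that("beta MPD matches closed forms, symmetry and the oracle", {
  # identical plots on a star tree with tip-pair distance d: only
  # conspecific pairs are at 0, so the value is d * (1 - sum(f^2))
  n <- 5
  ds <- matrix(2, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(ds) <- 0
  ab <- setNames(c(4, 3, 2, 1, 0), letters[1:n])
  f <- ab / sum(ab)
  expect_equal(mpd_beta(ds, ab, ab), 2 * (1 - sum(f^2)), tolerance = 1e-12)

  # monodominant plots: the single cross pair
  d <- random_dist(4, seed = 2)
  ax <- setNames(c(3, 0, 0, 0), rownames(d))
  ay <- setNames(c(0, 5, 0, 0), rownames(d))
  expect_equal(mpd_beta(d, ax, ay), d[1, 2])

  for (s in 1:5) {
    dd <- random_dist(12, seed = 10 + s)
    a1 <- setNames(rpois(12, 2), rownames(dd)); a1[1] <- a1[1] + 1
    a2 <- setNames(rpois(12, 2), rownames(dd)); a2[2] <- a2[2] + 1
    expect_equal(mpd_beta(dd, a1, a2), mpd_beta(dd, a2, a1),
                 tolerance = 1e-12)
    expect_equal(mpd_beta(dd, a1, a2), mpd_beta_brute(dd, a1, a2),
                 tolerance = 1e-12)
  }
  expect_error(mpd_beta(d, ax * 0, ay), "empty")
})

test_that("MPD conventions are consistent with picante", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(12, 6)
  d <- patristic_distance(tr)
  comm <- random_comm(5, tr$tip.label, seed = 6)
  # picante's abundance-weighted MPD keeps conspecific pairs in the
  # denominator; ours excludes them, so they differ by (1 - sum(f^2))
  pm <- picante::mpd(comm, as.matrix(d), abundance.weighted = TRUE)
  for (i in 1:5) {
    f <- comm[i, ] / sum(comm[i, ])
    expect_equal(mpd_alpha(d, comm[i, ]) * (1 - sum(f^2)), pm[i],
                 tolerance = 1e-10)
  }
  cd <- as.matrix(picante::comdist(comm, as.matrix(d),
                                   abundance.weighted = TRUE))
  expect_equal(mpd_beta(d, comm[1, ], comm[3, ]), cd[1, 3],
               tolerance = 1e-10)
})

test_that("tip-shuffle null preserves the community and matches theory", {
  # pool = exactly the species in the unit, star distances: every
  # permutation leaves MPD unchanged
  ds <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(ds) <- 0
  comm <- rbind(p1 = c(1, 2, 3, 4))
  colnames(comm) <- letters[1:4]
  null <- tip_shuffle_null(ds, comm, "p1", n_null = 25, seed = 3)
  expect_true(all(null == mpd_alpha(ds, comm["p1", ])))

  expect_identical(tip_shuffle_null(ds, comm, "p1", 10, seed = 7),
                   tip_shuffle_null(ds, comm, "p1", 10, seed = 7))

  # analytic expectation under uniform label permutation: mean off-diagonal
  d <- random_dist(14, seed = 5)
  comm2 <- random_comm(3, rownames(d), seed = 5)
  null2 <- tip_shuffle_null(d, comm2, "p01", n_null = 1000, seed = 9)
  expected <- mean(d[row(d) != col(d)])
  se <- sd(null2) / sqrt(length(null2))
  expect_lt(abs(mean(null2) - expected), 3 * se)
})

test_that("NRI follows its defining formula and flags degenerate nulls", {
  null <- c(3, 4, 5, 6, 7)
  expect_equal(nri(mean(null), null), 0)
  expect_equal(nri(mean(null) - 2 * sd(null), null), 2)
  expect_warning(out <- nri(1, c(2, 2, 2)), "degenerate")
  expect_equal(as.numeric(out), 0)

  # scale invariance: multiplying all distances by c > 0 leaves NRI fixed
  d <- random_dist(10, seed = 11)
  comm <- random_comm(4, rownames(d), seed = 11)
  p1 <- dispersion_profiles(d, comm, "alpha", n_null = 199, seed = 2)
  p2 <- dispersion_profiles(7.3 * d, comm, "alpha", n_null = 199, seed = 2)
  expect_equal(p1$nri, p2$nri, tolerance = 1e-9)
})

test_that("dispersion profiles cover all units and drop thin plots", {
  d <- random_dist(10, seed = 12)
  comm <- random_comm(6, rownames(d), seed = 12)
  comm["p01", ] <- 0; comm["p01", 1] <- 5      # richness-1 plot
  expect_message(
    prof <- dispersion_profiles(d, comm, "alpha", n_null = 99, seed = 1),
    "richness < 2")
  expect_equal(nrow(prof), 5L)
  expect_false("p01" %in% prof$unit_id)

  beta <- dispersion_profiles(d, comm, "beta", n_null = 99, seed = 1)
  expect_equal(nrow(beta), choose(6, 2))

  # observed MPD column equals the direct per-unit computation
  for (u in prof$unit_id)
    expect_equal(prof$mpd_obs[prof$unit_id == u],
                 as.numeric(mpd_alpha(d, comm[u, ])), tolerance = 1e-12)
  b1 <- beta[1, ]
  expect_equal(b1$mpd_obs,
               mpd_beta(d, comm[b1$plot_a, ], comm[b1$plot_b, ]),
               tolerance = 1e-12)

  # null summaries agree with the standalone tip-shuffle engine
  null <- tip_shuffle_null(d, comm, "p02", n_null = 2000, seed = 5)
  row <- prof[prof$unit_id == "p02", ]
  expect_lt(abs(row$null_mean - mean(null)), 4 * sd(null) / sqrt(99))
  expect_lt(abs(row$null_sd - sd(null)) / sd(null), 0.15)
})
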