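# Synthetic data with known ground truth: Yule phylogenies, lambda-structured
# Brownian traits, and gradient communities assembled by environmental
# filtering, limiting-similarity competition or neutral placement.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults mirror a single temperate mountain transect: ~120 woody species,
#' plots spread over a 300-1700 m elevational gradient (the sampled domain of
#' the motivating surveys), Gaussian elevational niches of 250 m breadth, and
#' fully Brownian traits (`lambda_true = 1`, unit rate on a depth-1 tree).
#'
#' @param n_species number of species in the pool (>= 3).
#' @param n_plots number of plots along the transect (>= 2).
#' @param elevation_range numeric length-2, min/max plot elevation in m.
#' @param scenario assembly process: `"filtering"` (species optima follow a
#'   conserved trait, so co-occurring species are related), `"competition"`
#'   (sequential entry rejecting species within `comp_radius` of a resident
#'   in trait space) or `"neutral"` (optima uniform at random).
#' @param lambda_true Pagel's lambda used to simulate traits, in `[0, 1]`.
#' @param sigma2 Brownian rate of trait evolution (trait variance per unit
#'   tree depth; the tree is depth-normalised to 1).
#' @param niche_breadth Gaussian niche SD in m.
#' @param n_traits number of independent traits to simulate.
#' @param abundance_scale Poisson mean at a species' optimum.
#' @param comp_radius limiting-similarity radius in (conserved) trait units.
#' @param elev_bias exponent >= 1 biasing species optima toward low
#'   elevations; values > 1 shrink the high-elevation species pool so that
#'   richness declines with elevation. 1 = uniform coverage.
#' @param rar_elev_weight weight in `[0, 1]` coupling the rocky-area ratio
#'   to elevation (0 = independent noise).
#' @param seed integer RNG seed (required; the generator is deterministic).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 120, n_plots = 50,
                            elevation_range = c(300, 1700),
                            scenario = c("filtering", "competition",
                                         "neutral"),
                            lambda_true = 1, sigma2 = 1,
                            niche_breadth = 250, n_traits = 5,
                            abundance_scale = 8, comp_radius = 0.25,
                            elev_bias = 1, rar_elev_weight = 0,
                            seed) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  stopifnot(n_species >= 3, n_plots >= 2, niche_breadth > 0,
            lambda_true >= 0, lambda_true <= 1, sigma2 >= 0,
            length(elevation_range) == 2,
            elevation_range[2] > elevation_range[1],
            elev_bias >= 1, rar_elev_weight >= 0, rar_elev_weight <= 1)
  structure(list(n_species = as.integer(n_species),
                 n_plots = as.integer(n_plots),
                 elevation_range = as.numeric(elevation_range),
                 scenario = scenario, lambda_true = lambda_true,
                 sigma2 = sigma2, niche_breadth = niche_breadth,
                 n_traits = as.integer(n_traits),
                 abundance_scale = abundance_scale,
                 comp_radius = comp_radius, elev_bias = elev_bias,
                 rar_elev_weight = rar_elev_weight,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Topology and waiting times from [ape::rphylo()] with death rate 0; the
#' tree is ultrametric and rescaled so every root-to-tip distance equals 1,
#' which makes the Brownian rate `sigma2` directly interpretable as trait
#' variance accumulated root-to-tip.
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer RNG seed.
#' @return an ultrametric `phylo` with tips `s001 ...`.
#' @export
simulate_tree <- function(n_species, seed) {
  if (n_species < 3) stop("n_species must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("s%03d", seq_len(n_species))
  tree
}

#' Simulate traits under a lambda-transformed Brownian model
#'
#' Each trait is one draw from a zero-mean multivariate normal with
#' covariance `sigma2 * C(lambda)`, where `C` is the tree's shared
#' branch-length (phylogenetic variance-covariance) matrix and `C(lambda)`
#' multiplies its off-diagonal entries by `lambda`. `lambda = 1` is plain
#' Brownian motion; `lambda = 0` gives independent tips.
#'
#' @param tree a `phylo` with branch lengths.
#' @param lambda_true lambda in `[0, 1]`.
#' @param sigma2 Brownian rate (> 0; 0 returns the root value everywhere).
#' @param seed integer RNG seed.
#' @param n_traits number of independent traits.
#' @return numeric matrix, species in rows (tree tip order), traits in
#'   columns `trait1 ...`.
#' @export
simulate_traits <- function(tree, lambda_true, sigma2, seed, n_traits = 5) {
  stopifnot(lambda_true >= 0, lambda_true <= 1, sigma2 >= 0)
  C <- phylo_vcv(tree)
  if (!is_ultrametric_vcv(C))
    warning("tree is not ultrametric; C(lambda) is still well defined")
  n <- nrow(C)
  Cl <- lambda_transform(C, lambda_true)
  set.seed(seed)
  if (sigma2 == 0) {
    X <- matrix(0, n, n_traits)
  } else {
    L <- chol(sigma2 * Cl + diag(1e-12, n))
    Z <- matrix(rnorm(n * n_traits), n, n_traits)
    X <- crossprod(L, Z)
  }
  dimnames(X) <- list(rownames(C), paste0("trait", seq_len(n_traits)))
  X
}

# lambda transform: scale off-diagonal of C by lambda
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

is_ultrametric_vcv <- function(C) {
  d <- diag(C)
  max(d) - min(d) < 1e-8 * max(d)
}

#' Simulate a gradient-structured community and its plot metadata
#'
#' Plots are placed evenly over the configured elevation range along a
#' straight transect line in lon/lat (with small jitter), each species gets
#' an elevational optimum according to the assembly scenario, and abundance
#' of species `i` at plot `j` is a Poisson draw with mean
#' `abundance_scale * exp(-0.5 ((e_j - opt_i) / niche_breadth)^2)`
#' (competition additionally masks species within `comp_radius` of an
#' already-admitted resident in conserved-trait space, per plot). Metadata
#' includes five temperature variables decreasing linearly with elevation
#' plus noise, two precipitation variables increasing with elevation plus
#' noise, and slope / rocky-area ratio as habitat noise (RAR optionally
#' elevation-coupled via `rar_elev_weight`).
#'
#' @param tree phylogeny from [simulate_tree()].
#' @param traits trait matrix from [simulate_traits()] (rows = tips).
#' @param cfg a [scenario_config()].
#' @return list with elements `community` (plots x species matrix),
#'   `metadata` (data.frame as in [read_metadata()]) and `optima` (the
#'   true species optima, for ground-truth checks).
#' @export
simulate_gradient_community <- function(tree, traits, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  sp <- tree$tip.label
  if (!all(sp %in% rownames(traits)))
    stop("traits must be indexed by the tree's tips")
  traits <- traits[sp, , drop = FALSE]
  n_sp <- length(sp)
  n_plot <- cfg$n_plots
  set.seed(cfg$seed + 1L)

  elev <- seq(cfg$elevation_range[1], cfg$elevation_range[2],
              length.out = n_plot)
  erange <- cfg$elevation_range[2] - cfg$elevation_range[1]

  # species optima by scenario; conserved trait = trait1
  z1 <- traits[, 1]
  u <- switch(cfg$scenario,
    filtering = pnorm(z1, mean = mean(z1), sd = max(sd(z1), 1e-12)),
    competition = runif(n_sp),
    neutral = runif(n_sp))
  u <- u^cfg$elev_bias
  optima <- cfg$elevation_range[1] + u * erange

  lambda_mat <- cfg$abundance_scale *
    exp(-0.5 * outer(elev, optima, "-")^2 / cfg$niche_breadth^2)

  if (cfg$scenario == "competition") {
    # per-plot sequential assembly: random entry order, reject entrants
    # within comp_radius of any admitted resident in conserved-trait space
    mask <- matrix(FALSE, n_plot, n_sp)
    for (j in seq_len(n_plot)) {
      ord <- sample.int(n_sp)
      res <- numeric(0)
      for (i in ord) {
        if (lambda_mat[j, i] < 1e-6) next
        if (!length(res) || min(abs(z1[i] - res)) > cfg$comp_radius) {
          mask[j, i] <- TRUE
          res <- c(res, z1[i])
        }
      }
    }
    lambda_mat[!mask] <- 0
  }

  comm <- draw_community(lambda_mat, retry_cap = 100L)
  dimnames(comm) <- list(sprintf("p%03d", seq_len(n_plot)), sp)

  # transect geometry: straight line, ~5 km, mid-latitude; 20 m jitter
  lat0 <- 38.0; lon0 <- 128.4
  frac <- (elev - cfg$elevation_range[1]) / erange
  m_per_deg <- 6371000 * pi / 180
  lat <- lat0 + frac * 5000 / m_per_deg + rnorm(n_plot, 0, 20 / m_per_deg)
  lon <- lon0 + rnorm(n_plot, 0, 20 / m_per_deg)

  # climate: temperature lapse ~6.5 K/km, precip increasing with elevation
  ez <- (elev - mean(elev)) / 1000
  t_ann <- 11 - 6.5 * ez + rnorm(n_plot, 0, 0.3)
  t_jan <- t_ann - 13 + rnorm(n_plot, 0, 0.4)
  t_aug <- t_ann + 12 + rnorm(n_plot, 0, 0.4)
  t_grow <- t_ann + 7 + rnorm(n_plot, 0, 0.3)
  t_diff <- t_aug - t_jan + rnorm(n_plot, 0, 0.2)
  p_ann <- 1230 + 250 * ez + rnorm(n_plot, 0, 40)
  p_grow <- 0.6 * p_ann + rnorm(n_plot, 0, 25)

  slope <- exp(rnorm(n_plot, log(20), 0.35))
  ezs <- (elev - mean(elev)) / max(sd(elev), 1e-12)
  rar <- plogis(-1.2 + cfg$rar_elev_weight * ezs +
                  0.8 * rnorm(n_plot))

  metadata <- data.frame(
    plot_id = rownames(comm), transect_id = "T1", elevation = elev,
    latitude = lat, longitude = lon, slope = slope, rar = rar,
    t_ann = t_ann, t_jan = t_jan, t_aug = t_aug, t_grow = t_grow,
    t_diff = t_diff, p_ann = p_ann, p_grow = p_grow,
    stringsAsFactors = FALSE)

  list(community = comm, metadata = metadata,
       optima = setNames(optima, sp))
}

# Poisson draws per plot; all-zero plots redrawn up to retry_cap
draw_community <- function(lambda_mat, retry_cap = 100L) {
  n_plot <- nrow(lambda_mat); n_sp <- ncol(lambda_mat)
  comm <- matrix(rpois(n_plot * n_sp, lambda_mat), n_plot, n_sp)
  empty <- which(rowSums(comm) == 0)
  for (j in empty) {
    ok <- FALSE
    for (k in seq_len(retry_cap)) {
      row <- rpois(n_sp, lambda_mat[j, ])
      if (sum(row) > 0) { comm[j, ] <- row; ok <- TRUE; break }
    }
    if (!ok) stop("plot ", j, " empty after ", retry_cap,
                  " redraws; increase abundance_scale or niche_breadth")
  }
  comm
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing tree, traits, community and metadata from a
#' single [scenario_config()]; deterministic given the config.
#'
#' @param cfg a [scenario_config()].
#' @return list with `tree`, `traits`, `community`, `metadata`, `optima`
#'   and the `config` itself.
#' @export
simulate_scenario <- function(cfg) {
  tree <- simulate_tree(cfg$n_species, cfg$seed)
  traits <- simulate_traits(tree, cfg$lambda_true, cfg$sigma2,
                            seed = cfg$seed + 2L, n_traits = cfg$n_traits)
  com <- simulate_gradient_community(tree, traits, cfg)
  c(list(tree = tree, traits = traits, config = cfg), com)
}
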