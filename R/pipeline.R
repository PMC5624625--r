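# End-to-end orchestration: simulate (or load) the inputs, run signal,
# dendrogram, alpha/beta dispersion and driver attribution, and write every
# stage's table with provenance (config hash + stage seed) to an output
# directory.

#' Convert a simulated (z-scale) trait matrix to a positive trait table
#'
#' Simulated traits live on an unbounded Brownian scale; mapping them
#' through `exp(location + scale * z)` yields strictly positive, lognormal
#' trait values with field-realistic magnitudes (heights in m, leaf
#' dimensions in cm, flowering months, seed masses in mg), i.e. a table
#' that [read_traits()] would accept. Flowering onset is additionally
#' clamped to 1-12.
#'
#' @param traits z-scale matrix from [simulate_traits()] (>= 5 columns are
#'   mapped onto the five canonical traits; extras are dropped).
#' @return data.frame in [trait_vars()] layout, rownames = species.
#' @export
traits_to_table <- function(traits) {
  traits <- as.matrix(traits)
  if (ncol(traits) < 5) stop("need at least 5 simulated traits")
  z <- scale(traits[, 1:5])
  out <- data.frame(
    max_height = exp(log(8) + 0.9 * z[, 1]),
    leaf_length = exp(log(7) + 0.6 * z[, 2]),
    leaf_width = exp(log(4) + 0.6 * z[, 3]),
    flowering_onset = pmin(12, pmax(1, round(exp(log(5.5) + 0.25 * z[, 4])))),
    seed_mass = exp(log(20) + 1.2 * z[, 5]),
    row.names = rownames(traits))
  out
}

# short deterministic config hash (polynomial rolling hash, mod 2^31 - 1)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage <- function(x, path, hash, seed, id_col = "id") {
  con <- file(path, "w")
  writeLines(sprintf("# gradiv config_hash=%s seed=%s", hash, seed), con)
  close(con)
  if (inherits(x, "phylo")) {
    cat(ape::write.tree(x), "\n", sep = "", file = path, append = TRUE)
  } else {
    x <- as.data.frame(x, check.names = FALSE)
    suppressWarnings(write.table(x, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  invisible(path)
}

#' Run the full gradient-diversity analysis
#'
#' Orchestrates simulate -> signal -> dendrogram -> alpha/beta dispersion
#' -> drivers from one configuration list. Deterministic given the config;
#' every output table carries a header comment with the config hash and
#' the stage seed.
#'
#' @param config list with either `scenario` (a [scenario_config()]) or
#'   paths `tree`, `community`, `traits`, `metadata`; optional `n_null`
#'   (default 999), `n_perm` (default 999), `n_perm_signal` (default 199),
#'   `n_components` (default 4), `seed` (required), `out_dir` (optional:
#'   write stage tables there).
#' @return list with all stage results, invisibly.
#' @export
run_all <- function(config) {
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  seed <- as.integer(config$seed)
  n_null <- config$n_null %||% 999
  n_perm <- config$n_perm %||% 999
  n_perm_signal <- config$n_perm_signal %||% 199
  n_components <- config$n_components %||% 4
  # the hash identifies the analysis, not where it is written
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf("[gradiv %s] ", hash), ...)

  if (!is.null(config$scenario)) {
    log_msg("simulating scenario '", config$scenario$scenario, "'")
    sim <- simulate_scenario(config$scenario)
    tree <- sim$tree
    comm <- sim$community
    metadata <- sim$metadata
    trait_table <- traits_to_table(sim$traits)
  } else {
    for (p in c("tree", "community", "traits", "metadata"))
      if (is.null(config[[p]]) || !file.exists(config[[p]]))
        stop("config input missing or not found: ", p)
    tree <- read_newick(config$tree)
    comm <- read_community(config$community)
    trait_table <- read_traits(config$traits)
    metadata <- read_metadata(config$metadata)
  }
  comm <- match_species(comm, tree = tree, traits = trait_table,
                        drop_unmatched = isTRUE(config$drop_unmatched))

  log_msg("phylogenetic signal (", n_perm_signal, " permutations)")
  z <- prepare_traits(trait_table[, intersect(trait_vars(),
                                              names(trait_table))])
  sig <- signal_table(tree, z, n_perm = n_perm_signal, seed = seed + 10L)

  log_msg("functional dendrogram (", n_components, " components)")
  fd <- functional_dendrogram(
    trait_table[, intersect(trait_vars(), names(trait_table))],
    n_components = n_components)

  dp <- patristic_distance(tree)
  dp <- dp[colnames(comm), colnames(comm)]
  df <- fd$cophenetic[colnames(comm), colnames(comm)]

  log_msg("alpha/beta dispersion (", n_null, " null replicates)")
  alpha_phylo <- dispersion_profiles(dp, comm, "alpha",
                                     n_null = n_null, seed = seed + 20L)
  alpha_func <- dispersion_profiles(df, comm, "alpha",
                                    n_null = n_null, seed = seed + 21L)
  beta_phylo <- dispersion_profiles(dp, comm, "beta",
                                    n_null = n_null, seed = seed + 22L)
  beta_func <- dispersion_profiles(df, comm, "beta",
                                   n_null = n_null, seed = seed + 23L)
  rich <- richness(comm)
  bc <- bray_curtis_matrix(comm)

  log_msg("driver attribution (", n_perm, " permutations)")
  env <- env_table(metadata)
  dists <- env_distances(env)
  dgeo <- geographic_distance(metadata)
  preds <- list(pc1_clim = env$pc1_clim, pc2_clim = env$pc2_clim,
                slope_t = env$slope_t, rar_t = env$rar_t)
  ids <- metadata$plot_id

  alpha_resp <- list(
    TAD = setNames(as.numeric(rich[ids]), ids),
    PAD = setNames(alpha_phylo$nri[match(ids, alpha_phylo$unit_id)], ids),
    FAD = setNames(alpha_func$nri[match(ids, alpha_func$unit_id)], ids))

  ols <- do.call(rbind, lapply(names(alpha_resp), function(ix) {
    yv <- alpha_resp[[ix]]
    ok <- !is.na(yv)
    do.call(rbind, lapply(names(preds), function(v) {
      f <- simple_ols(yv[ok], preds[[v]][ok])
      data.frame(index = ix, variable = v, r2 = f$r2, sign = f$sign,
                 p = f$p, stringsAsFactors = FALSE)
    }))
  }))

  imp_alpha <- do.call(rbind, lapply(names(alpha_resp), function(ix) {
    yv <- alpha_resp[[ix]]
    ok <- !is.na(yv)
    ms <- all_subsets_aicc(yv[ok], lapply(preds, function(p) p[ok]))
    iv <- importance_values(ms)
    data.frame(index = ix, variable = names(iv), importance = iv,
               best = ms$best, stringsAsFactors = FALSE, row.names = NULL)
  }))

  vp_alpha <- lapply(alpha_resp, function(yv) {
    ok <- !is.na(yv)
    variation_partition_alpha(
      yv[ok],
      list(pc1_clim = preds$pc1_clim[ok], pc2_clim = preds$pc2_clim[ok]),
      list(slope_t = preds$slope_t[ok], rar_t = preds$rar_t[ok]))
  })

  nri_to_dist <- function(prof) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(prof$plot_a, prof$plot_b)] <- prof$nri
    m[cbind(prof$plot_b, prof$plot_a)] <- prof$nri
    m
  }
  beta_resp <- list(
    TBD = bc[ids, ids],          # Bray-Curtis similarity (distance-decay
                                 # then shows up as a negative Mantel r)
    PBD = nri_to_dist(beta_phylo),
    FBD = nri_to_dist(beta_func))
  dmats <- list(dist_geo = dgeo[ids, ids],
                dist_clim = as.matrix(dists$clim)[ids, ids],
                dist_habit = as.matrix(dists$habit)[ids, ids])

  mantel_tab <- do.call(rbind, lapply(names(beta_resp), function(ix) {
    do.call(rbind, lapply(names(dmats), function(v) {
      mt <- mantel(beta_resp[[ix]], dmats[[v]],
                   n_perm = n_perm, seed = seed + 30L)
      data.frame(index = ix, matrix = v, r = mt$r, p = mt$p,
                 stringsAsFactors = FALSE)
    }))
  }))

  imp_beta <- do.call(rbind, lapply(names(beta_resp), function(ix) {
    ms <- all_subsets_aicc(beta_resp[[ix]], dmats,
                           response_is_distance = TRUE)
    iv <- importance_values(ms)
    data.frame(index = ix, variable = names(iv), importance = iv,
               best = ms$best, stringsAsFactors = FALSE, row.names = NULL)
  }))

  denv <- as.matrix(dists$env)[ids, ids]
  mrm_res <- lapply(beta_resp, function(Y)
    mrm(Y, list(dist_geo = dmats$dist_geo, dist_env = denv),
        n_perm = n_perm, seed = seed + 31L))
  vp_beta <- lapply(beta_resp, function(Y)
    variation_partition_beta(Y, list(dist_geo = dmats$dist_geo),
                             list(dist_env = denv)))

  res <- list(config = config, hash = hash, tree = tree, community = comm,
              traits = trait_table, metadata = metadata, signal = sig,
              dendrogram = fd, richness = rich, bray_curtis = bc,
              alpha_phylo = alpha_phylo, alpha_func = alpha_func,
              beta_phylo = beta_phylo, beta_func = beta_func,
              env = env, ols = ols, mantel = mantel_tab,
              importance_alpha = imp_alpha, importance_beta = imp_beta,
              vp_alpha = vp_alpha, vp_beta = vp_beta, mrm = mrm_res)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name, s) write_stage(x, file.path(config$out_dir, name),
                                          hash, s)
    w(tree, "tree.nwk", seed)
    w(cbind(plot_id = rownames(comm), as.data.frame(comm)),
      "community.tsv", seed)
    w(cbind(species_id = rownames(trait_table), trait_table),
      "traits.tsv", seed)
    w(metadata, "metadata.tsv", seed)
    w(sig, "signal.tsv", seed + 10L)
    w(dendro_to_phylo(fd$dendrogram), "dendro.nwk", seed)
    w(alpha_phylo, "alpha_phylo.tsv", seed + 20L)
    w(alpha_func, "alpha_func.tsv", seed + 21L)
    w(beta_phylo, "beta_phylo.tsv", seed + 22L)
    w(beta_func, "beta_func.tsv", seed + 23L)
    w(ols, "ols.tsv", seed)
    w(mantel_tab, "mantel.tsv", seed + 30L)
    w(rbind(cbind(component = "alpha", imp_alpha),
            cbind(component = "beta", imp_beta)), "importance.tsv", seed)
    part <- do.call(rbind, lapply(names(vp_alpha), function(ix)
      data.frame(component = "alpha", index = ix,
                 as.data.frame(vp_alpha[[ix]][1:4]))))
    partb <- do.call(rbind, lapply(names(vp_beta), function(ix)
      data.frame(component = "beta", index = ix,
                 as.data.frame(vp_beta[[ix]][1:4]))))
    w(rbind(part, partb), "partition.tsv", seed)
    log_msg("wrote outputs to ", config$out_dir)
  }
  log_msg(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, "secs")))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
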