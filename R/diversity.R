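# Taxonomic, phylogenetic and functional alpha/beta diversity: richness,
# Bray-Curtis similarity, abundance-weighted MPD, the tip-shuffle null model
# and the net relatedness index (NRI).
#
# With f the within-plot relative abundances and D a zero-diagonal distance
# matrix, the abundance-weighted alpha MPD reduces to
#   f' D f / (1 - sum(f^2))
# (conspecific pairs contribute 0 to the numerator and sum(f^2) to the
# excluded weight), and the between-plot MPD to f' D g (the pair weights sum
# to 1, conspecific cross-pairs included at distance 0). These closed forms
# are what the vectorised null-model engine uses; the tests check them
# against an explicit double loop.

#' Species richness of each plot
#'
#' @param comm plots-by-species abundance matrix.
#' @param plot optional plot id(s); default all.
#' @return named integer vector of counts of species with abundance > 0.
#' @export
richness <- function(comm, plot = rownames(comm)) {
  comm <- comm[plot, , drop = FALSE]
  setNames(as.integer(rowSums(comm > 0)), rownames(comm))
}

#' Bray-Curtis similarity between two abundance vectors
#'
#' `1 - sum|x - y| / sum(x + y)`; 1 for identical non-empty vectors, 0 for
#' disjoint supports.
#'
#' @param x,y non-negative abundance vectors over the same species order.
#' @return similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must share species order")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both abundance vectors are all-zero")
  1 - sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis similarity for all plot pairs
#'
#' @param comm plots-by-species abundance matrix.
#' @return a symmetric plots-by-plots similarity matrix (diagonal 1).
#' @export
bray_curtis_matrix <- function(comm) {
  n <- nrow(comm)
  s <- matrix(1, n, n, dimnames = list(rownames(comm), rownames(comm)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s[i, j] <- s[j, i] <- bray_curtis_similarity(comm[i, ], comm[j, ])
  }
  s
}

#' Abundance-weighted mean pairwise distance within a plot
#'
#' `sum_{i != j} f_i f_j d_ij / sum_{i != j} f_i f_j` over the species
#' present, with f the within-plot relative abundances. Weights are
#' scale-invariant, so raw covers are accepted.
#'
#' @param d species distance matrix (labels = species).
#' @param abund named (or d-ordered) abundance vector for one plot.
#' @return MPD, or `NA` with attribute `degenerate` if fewer than two
#'   species are present.
#' @export
mpd_alpha <- function(d, abund) {
  d <- as.matrix(d)
  abund <- align_abund(abund, rownames(d))
  pres <- which(abund > 0)
  if (length(pres) < 2) {
    out <- NA_real_
    attr(out, "degenerate") <- "fewer than 2 species present"
    return(out)
  }
  f <- abund[pres] / sum(abund[pres])
  dd <- d[pres, pres]
  sum(f * (dd %*% f)) / (1 - sum(f^2))
}

#' Abundance-weighted mean pairwise distance between two plots
#'
#' `sum_{k,l} f_k g_l d_kl` over species k present in plot x and l present
#' in plot y, with f, g the per-plot relative abundances (the weights sum
#' to 1; shared species contribute conspecific pairs at distance 0).
#'
#' @param d species distance matrix.
#' @param abund_x,abund_y abundance vectors for the two plots.
#' @return between-plot MPD (symmetric in the argument order).
#' @export
mpd_beta <- function(d, abund_x, abund_y) {
  d <- as.matrix(d)
  x <- align_abund(abund_x, rownames(d))
  y <- align_abund(abund_y, rownames(d))
  if (sum(x) == 0 || sum(y) == 0) stop("empty plot in mpd_beta")
  f <- x / sum(x)
  g <- y / sum(y)
  as.numeric(f %*% d %*% g)
}

#' Tip-shuffle null distribution of MPD
#'
#' Each replicate permutes the species labels of the distance matrix across
#' the whole species pool (equivalent to shuffling the tip names of the
#' tree or dendrogram) and recomputes the observed unit's MPD; the
#' community matrix is untouched, so observed richness, abundance and
#' occupancy are all preserved.
#'
#' @param d species distance matrix over the pool.
#' @param comm plots-by-species matrix (columns must match `d`'s labels).
#' @param unit a plot id (alpha) or a character vector of two plot ids
#'   (beta; the same permutation is applied jointly to both plots).
#' @param n_null number of permutations.
#' @param seed integer RNG seed.
#' @return numeric vector of `n_null` null MPD values.
#' @export
tip_shuffle_null <- function(d, comm, unit, n_null = 1000, seed = 1L) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("species pool must contain at least 2 species")
  if (!all(colnames(comm) %in% rownames(d)))
    stop("community species missing from the distance matrix")
  d <- d[colnames(comm), colnames(comm)]
  n_sp <- ncol(comm)
  set.seed(seed)
  if (length(unit) == 1) {
    ab <- comm[unit, ]
    vapply(seq_len(n_null), function(r) {
      p <- sample.int(n_sp)
      mpd_alpha(d[p, p, drop = FALSE], unname(ab))
    }, numeric(1))
  } else if (length(unit) == 2) {
    ax <- comm[unit[1], ]; ay <- comm[unit[2], ]
    vapply(seq_len(n_null), function(r) {
      p <- sample.int(n_sp)
      mpd_beta(d[p, p, drop = FALSE], unname(ax), unname(ay))
    }, numeric(1))
  } else stop("unit must be one plot id or a pair of plot ids")
}

#' Net relatedness index from an observed MPD and its null sample
#'
#' `NRI = -1 * (mpd_obs - mean(null)) / sd(null)` (sample SD, n-1
#' denominator). Positive NRI = observed MPD below the null mean =
#' clustering; negative = overdispersion. A degenerate null (SD 0) is
#' reported as 0 with a warning and flagged.
#'
#' @param mpd_obs observed MPD.
#' @param null numeric vector of null MPD values (length >= 2).
#' @return NRI scalar; attribute `degenerate` set when sd(null) == 0.
#' @export
nri <- function(mpd_obs, null) {
  if (length(null) < 2) stop("null sample must have length >= 2")
  s <- sd(null)
  if (s == 0) {
    warning("degenerate null distribution (sd = 0); NRI reported as 0")
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  -1 * (mpd_obs - mean(null)) / s
}

#' Alpha or beta dispersion profiles (NRI tables)
#'
#' Runs the full observed-MPD + tip-shuffle-null + NRI engine for every
#' plot (alpha) or every unordered plot pair (beta). The same engine serves
#' phylogenetic diversity (patristic distances from the tree) and
#' functional diversity (cophenetic distances from the trait dendrogram).
#' The species pool is the set of species with a positive abundance
#' anywhere in `comm` — pass a transect-scoped community matrix for a
#' transect-scoped pool, or the full matrix for a global pool. One label
#' permutation is drawn per null replicate and applied to every unit (for
#' beta, jointly to both plots of a pair, preserving shared-species
#' structure). Alpha units with richness < 2 are excluded with a message.
#'
#' @param d species distance matrix (patristic or cophenetic).
#' @param comm plots-by-species abundance matrix.
#' @param mode `"alpha"` or `"beta"`.
#' @param n_null null replicates (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame with columns `unit_id` (plot, or "p1|p2"), `mpd_obs`,
#'   `null_mean`, `null_sd`, `nri`, `n_null`, `seed` (beta rows also carry
#'   `plot_a`, `plot_b`).
#' @export
dispersion_profiles <- function(d, comm, mode = c("alpha", "beta"),
                                n_null = 1000, seed = 1L) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  pool <- colnames(comm)[colSums(comm) > 0]
  if (!all(pool %in% rownames(d)))
    stop("community species missing from the distance matrix")
  comm <- comm[, pool, drop = FALSE]
  d <- d[pool, pool]
  n_sp <- length(pool)
  if (n_sp < 2) stop("species pool must contain at least 2 species")
  RA <- t(comm / rowSums(comm))             # species x plots rel. abundance

  set.seed(seed)
  perms <- replicate(n_null, sample.int(n_sp))

  if (mode == "alpha") {
    keep <- colSums(RA > 0) >= 2
    if (any(!keep))
      message("excluding ", sum(!keep), " plot(s) with richness < 2")
    Fa <- RA[, keep, drop = FALSE]
    self_w <- 1 - colSums(Fa^2)
    obs <- colSums(Fa * (d %*% Fa)) / self_w
    null <- matrix(NA_real_, n_null, ncol(Fa))
    for (r in seq_len(n_null)) {
      dp <- d[perms[, r], perms[, r]]
      null[r, ] <- colSums(Fa * (dp %*% Fa)) / self_w
    }
    nm <- colMeans(null)
    nsd <- apply(null, 2, sd)
    out <- data.frame(unit_id = colnames(Fa), mpd_obs = obs,
                      null_mean = nm, null_sd = nsd,
                      nri = ifelse(nsd > 0, -1 * (obs - nm) / nsd, 0),
                      n_null = n_null, seed = seed,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (any(nsd == 0))
      warning("degenerate null (sd = 0) for ",
              sum(nsd == 0), " plot(s); NRI set to 0")
    return(out)
  }

  plots <- rownames(comm)
  pairs <- t(combn(plots, 2))
  pairM <- function(M) M[cbind(match(pairs[, 1], plots),
                               match(pairs[, 2], plots))]
  obs <- pairM(crossprod(RA, d %*% RA))
  nsum <- numeric(length(obs)); nsq <- numeric(length(obs))
  for (r in seq_len(n_null)) {
    dp <- d[perms[, r], perms[, r]]
    v <- pairM(crossprod(RA, dp %*% RA))
    nsum <- nsum + v
    nsq <- nsq + v^2
  }
  nm <- nsum / n_null
  nsd <- sqrt(pmax(0, (nsq - n_null * nm^2) / (n_null - 1)))
  data.frame(unit_id = paste(pairs[, 1], pairs[, 2], sep = "|"),
             plot_a = pairs[, 1], plot_b = pairs[, 2],
             mpd_obs = obs, null_mean = nm, null_sd = nsd,
             nri = ifelse(nsd > 0, -1 * (obs - nm) / nsd, 0),
             n_null = n_null, seed = seed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between each pair of tips
#' ([ape::cophenetic.phylo()]).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return a [distance_matrix()] over the tips.
#' @export
patristic_distance <- function(tree) {
  distance_matrix(ape::cophenetic.phylo(tree))
}

# internal: align an abundance vector with species labels
align_abund <- function(abund, species) {
  if (!is.null(names(abund))) {
    miss <- setdiff(species, names(abund))
    if (length(miss)) stop("abundances missing for species: ",
                           paste(miss, collapse = ", "))
    abund <- abund[species]
  } else if (length(abund) != length(species)) {
    stop("unnamed abundance vector of wrong length")
  }
  if (any(abund < 0)) stop("negative abundance")
  abund
}
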