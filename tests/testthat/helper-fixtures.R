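# Shared fixture builders: everything is generated in code at test time.

# small hand-checkable tree: ((A:1,B:1):1,C:2);
hand_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# star phylogeny with n tips of branch length t
star_tree <- function(n = 6, t = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(t, nrow(tr$edge))
  tr$tip.label <- LETTERS[seq_len(n)]
  tr
}

# random labelled distance matrix (Euclidean, so valid & generically tie-free)
random_dist <- function(n, seed = 1, dim = 3) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n, dim)
  rownames(pts) <- sprintf("t%02d", seq_len(n))
  as.matrix(dist(pts))
}

# random community over given species labels (no empty plots)
random_comm <- function(n_plot, species, seed = 1, lambda = 1.5) {
  set.seed(seed)
  m <- matrix(rpois(n_plot * length(species), lambda), n_plot,
              length(species),
              dimnames = list(sprintf("p%02d", seq_len(n_plot)), species))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}

# brute-force abundance-weighted alpha MPD (explicit double loop)
mpd_alpha_brute <- function(d, abund) {
  d <- as.matrix(d)
  abund <- abund[rownames(d)]
  pres <- which(abund > 0)
  f <- abund[pres] / sum(abund[pres])
  num <- 0; den <- 0
  for (i in seq_along(pres)) for (j in seq_along(pres)) {
    if (i == j) next
    w <- f[i] * f[j]
    num <- num + w * d[pres[i], pres[j]]
    den <- den + w
  }
  unname(num / den)
}

# brute-force between-plot MPD
mpd_beta_brute <- function(d, ax, ay) {
  d <- as.matrix(d)
  ax <- ax[rownames(d)]; ay <- ay[rownames(d)]
  f <- ax / sum(ax); g <- ay / sum(ay)
  num <- 0; den <- 0
  for (i in seq_along(f)) for (j in seq_along(g)) {
    w <- f[i] * g[j]
    if (w == 0) next
    num <- num + w * d[i, j]
    den <- den + w
  }
  unname(num / den)
}

# Blomberg's K by explicit matrix inversion (oracle for small trees)
blomberg_k_brute <- function(tree, x) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  dev <- x - a
  mse0 <- sum(dev^2)
  mse <- as.numeric(t(dev) %*% Ci %*% dev)
  expect <- (sum(diag(C)) - n / as.numeric(t(one) %*% Ci %*% one)) / (n - 1)
  (mse0 / mse) / expect
}

# streaming Pearson correlation (independent of stats::cor)
pearson_stream <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# write a small delimited file and return its path
tmp_tsv <- function(df, sep = "\t") {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = sep, quote = FALSE, row.names = FALSE)
  p
}

# minimal valid metadata for n plots
toy_metadata <- function(n = 6, seed = 1) {
  set.seed(seed)
  elev <- seq(300, 1500, length.out = n)
  data.frame(plot_id = sprintf("p%02d", 1:n), transect_id = "T1",
             elevation = elev,
             latitude = 38 + seq(0, 0.04, length.out = n),
             longitude = 128.4 + rnorm(n, 0, 1e-4),
             slope = runif(n, 5, 40), rar = runif(n, 0, 0.8),
             t_ann = 11 - elev / 200 + rnorm(n, 0, 0.1),
             t_jan = -2 - elev / 200 + rnorm(n, 0, 0.1),
             t_aug = 23 - elev / 200 + rnorm(n, 0, 0.1),
             t_grow = 18 - elev / 200 + rnorm(n, 0, 0.1),
             t_diff = 25 + rnorm(n, 0, 0.1),
             p_ann = 1200 + elev / 10 + rnorm(n, 0, 5),
             p_grow = 700 + elev / 20 + rnorm(n, 0, 5),
             stringsAsFactors = FALSE)
}
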