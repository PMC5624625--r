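# Phylogenetic signal: Blomberg's K and Pagel's lambda, with tip-permutation
# significance. Linear solves use Cholesky factorisations; the explicit
# matrix-inverse route exists only as a brute-force oracle in the tests.

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` = branch length shared between the root and the most recent
#' common ancestor of tips i and j; `C[i, i]` = root-to-tip distance.
#' Computed with [ape::vcv.phylo()].
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix, tips in tip-label order.
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("tree has zero total depth")
  C
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Ratio of the observed mean squared error of the trait about its
#' generalized-least-squares (GLS) mean to the phylogenetically corrected
#' mean squared error, scaled by its Brownian-motion expectation so that
#' K = 1 under Brownian evolution, K < 1 for weaker-than-Brownian and
#' K > 1 for stronger-than-Brownian resemblance of relatives:
#' \deqn{K = \frac{(x-\hat a 1)'(x-\hat a 1)}{(x-\hat a 1)' C^{-1}
#'   (x-\hat a 1)} \Big/ \frac{\mathrm{tr}(C) - n/(1'C^{-1}1)}{n-1}}
#' with \eqn{\hat a = (1'C^{-1}x)/(1'C^{-1}1)}.
#'
#' @param tree rooted `phylo`.
#' @param x named numeric vector of trait values covering every tip.
#' @param C optional precomputed [phylo_vcv()] matrix.
#' @return K (non-negative scalar).
#' @export
blomberg_k <- function(tree, x, C = phylo_vcv(tree)) {
  x <- align_trait(x, rownames(C))
  if (var(x) == 0)
    stop("constant trait: zero phylogenetically corrected variance")
  n <- length(x)
  R <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  Ci1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  Cix <- backsolve(R, forwardsolve(t(R), x))
  one_Ci_one <- sum(Ci1)
  a_hat <- sum(Ci1 * x) / one_Ci_one
  dev <- x - a_hat
  mse0 <- sum(dev * dev)
  mse <- sum(dev * (Cix - a_hat * Ci1))
  expected <- (sum(diag(C)) - n / one_Ci_one) / (n - 1)
  (mse0 / mse) / expected
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the Gaussian likelihood of the trait under mean `mu * 1` and
#' covariance `sigma2 * C(lambda)` (off-diagonal of C scaled by lambda);
#' `mu` is the GLS mean and `sigma2` the residual quadratic form divided by
#' n, both analytic, leaving a 1-D bounded search for lambda on `[0, 1]`
#' (tolerance 1e-6). Lambda slightly above 1 can be likelihood-optimal on
#' some trees; the search is nonetheless bounded at 1, the interpretable
#' Brownian limit. On a star phylogeny the likelihood is flat in lambda and
#' the result is flagged unidentifiable.
#'
#' @inheritParams blomberg_k
#' @return list with `lambda_hat`, `loglik`, and logical `identifiable`.
#' @export
pagel_lambda <- function(tree, x, C = phylo_vcv(tree)) {
  x <- align_trait(x, rownames(C))
  if (var(x) == 0) stop("constant trait")
  offdiag <- C[upper.tri(C)]
  if (all(offdiag == 0)) {
    ll <- lambda_loglik(0, C, x)
    return(list(lambda_hat = NA_real_, loglik = ll, identifiable = FALSE))
  }
  opt <- optimize(function(l) lambda_loglik(l, C, x),
                  interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  # the optimum can sit on a boundary; compare against both endpoints
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, lambda_loglik(0, C, x), lambda_loglik(1, C, x))
  best <- which.max(lls)
  list(lambda_hat = cand[best], loglik = lls[best], identifiable = TRUE)
}

#' Profile log-likelihood of lambda
#'
#' @inheritParams pagel_lambda
#' @param lambda value in `[0, 1]`.
#' @return log-likelihood at the profiled GLS mean and variance.
#' @export
lambda_loglik <- function(lambda, C, x) {
  n <- length(x)
  Cl <- lambda_transform(C, lambda)
  R <- chol(Cl)
  Ci1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  Cix <- backsolve(R, forwardsolve(t(R), x))
  mu <- sum(Ci1 * x) / sum(Ci1)
  dev <- x - mu
  quad <- sum(dev * (Cix - mu * Ci1))
  sigma2 <- quad / n
  logdet <- 2 * sum(log(diag(R)))
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdet / 2 - n / 2
}

#' Permutation p-value for a phylogenetic signal statistic
#'
#' Trait values are randomly re-arrayed across the tips `n_perm` times and
#' the statistic recomputed each time; the reported p is the one-tailed
#' upper probability with the add-one correction,
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so p is never exactly 0.
#'
#' @inheritParams blomberg_k
#' @param statistic `"K"` or `"lambda"`.
#' @param n_perm number of permutations (values below 99 warn).
#' @param seed integer RNG seed.
#' @return list with `observed`, `p`, `null` (the permuted statistics),
#'   `n_perm` and `seed`.
#' @export
signal_pvalue <- function(tree, x, statistic = c("K", "lambda"),
                          n_perm = 1000, seed = 1L) {
  statistic <- match.arg(statistic)
  C <- phylo_vcv(tree)
  x <- align_trait(x, rownames(C))
  if (n_perm < 99) warning("n_perm < 99 gives an unstable p-value")
  stat_fun <- if (statistic == "K") {
    function(v) blomberg_k(tree, setNames(v, names(x)), C = C)
  } else {
    function(v) pagel_lambda(tree, setNames(v, names(x)), C = C)$lambda_hat
  }
  obs <- stat_fun(x)
  set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(i) stat_fun(sample(unname(x))), numeric(1))
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  list(observed = obs, p = p, null = null, n_perm = n_perm, seed = seed)
}

#' Phylogenetic signal table for a trait matrix
#'
#' Runs [blomberg_k()], [pagel_lambda()] and their permutation tests for
#' every trait column, mirroring the layout of a per-trait signal table.
#'
#' @param tree rooted `phylo`.
#' @param traits numeric matrix or data.frame, species in rows (names must
#'   cover the tips), traits in columns.
#' @param n_perm permutations for both tests.
#' @param seed integer RNG seed.
#' @return data.frame with one row per trait: `trait`, `K`, `p_K`,
#'   `lambda_hat`, `loglik`, `p_lambda`, `n_perm`, `seed`.
#' @export
signal_table <- function(tree, traits, n_perm = 1000, seed = 1L) {
  traits <- as.matrix(traits)
  out <- lapply(seq_len(ncol(traits)), function(j) {
    x <- setNames(traits[, j], rownames(traits))
    pk <- signal_pvalue(tree, x, "K", n_perm = n_perm, seed = seed + j)
    pl <- signal_pvalue(tree, x, "lambda", n_perm = n_perm,
                        seed = seed + 1000L + j)
    lam <- pagel_lambda(tree, x)
    data.frame(trait = colnames(traits)[j], K = pk$observed, p_K = pk$p,
               lambda_hat = lam$lambda_hat, loglik = lam$loglik,
               p_lambda = pl$p, n_perm = n_perm, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# internal: align a named trait vector with the tip order of C
align_trait <- function(x, tips) {
  if (is.null(names(x))) {
    if (length(x) != length(tips))
      stop("unnamed trait vector of wrong length")
    names(x) <- tips
    return(x)
  }
  miss <- setdiff(tips, names(x))
  if (length(miss)) stop("trait values missing for tips: ",
                         paste(miss, collapse = ", "))
  x[tips]
}
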