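# Driver attribution: climate PCA, habitat transforms, geographic /
# climatic / habitat / environmental distance matrices, simple OLS, simple
# Mantel tests, all-subsets AICc multimodel inference with Akaike-weight
# importances, variation partitioning and multiple regression on distance
# matrices (MRM).

#' Climate PCA: reduce the seven climate variables to two axes
#'
#' The two precipitation variables are log-transformed, all seven variables
#' are z-standardized, and a PCA (eigendecomposition of the correlation
#' matrix, deterministic sign convention) yields the scores of the first
#' two axes, named `pc1_clim` and `pc2_clim`.
#'
#' @param metadata plot metadata with the [climate_vars()] columns.
#' @return list: `scores` (data.frame `plot_id`, `pc1_clim`, `pc2_clim`),
#'   `explained_fraction` (all 7 axes), `cumulative`, `loadings`.
#' @export
climate_pca <- function(metadata) {
  cv <- climate_vars()
  miss <- setdiff(cv, names(metadata))
  if (length(miss)) stop("missing climate columns: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(metadata[, cv])
  X[, c("p_ann", "p_grow")] <- log(X[, c("p_ann", "p_grow")])
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant climate column(s): ",
         paste(cv[sds == 0], collapse = ", "))
  Z <- scale(X)
  eig <- eigen(cor(Z), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(cv, paste0("PC", seq_len(ncol(vecs))))
  sc <- Z %*% vecs[, 1:2]
  ef <- vals / sum(vals)
  list(scores = data.frame(plot_id = metadata$plot_id,
                           pc1_clim = sc[, 1], pc2_clim = sc[, 2],
                           stringsAsFactors = FALSE),
       explained_fraction = ef, cumulative = cumsum(ef), loadings = vecs)
}

#' Transform the habitat variables
#'
#' Slope (degrees) is log-transformed — with offset `c = 0` when all slopes
#' are positive, else `c = 1` — and the rocky-area ratio is arcsine
#' square-root transformed (`asin(sqrt(rar))`, so 0 maps to 0 and 1 to
#' pi/2).
#'
#' @param slope slope in degrees (>= 0).
#' @param rar rocky-area ratio in `[0, 1]`.
#' @param offset log offset; default picks 0 or 1 automatically.
#' @return list with `slope_t` and `rar_t`.
#' @export
transform_habitat <- function(slope, rar, offset = NULL) {
  if (any(rar < 0 | rar > 1)) stop("rar outside [0, 1]")
  if (any(slope < 0)) stop("negative slope")
  if (is.null(offset)) offset <- if (all(slope > 0)) 0 else 1
  list(slope_t = log(slope + offset), rar_t = asin(sqrt(rar)))
}

#' Build the plot-level environment table
#'
#' Combines [climate_pca()] scores with [transform_habitat()] values into
#' the four predictors used throughout the driver analyses.
#'
#' @param metadata full plot metadata ([read_metadata()] layout).
#' @return data.frame: `plot_id`, `pc1_clim`, `pc2_clim`, `slope_t`,
#'   `rar_t`; attribute `climate_pca` holds the full PCA result.
#' @export
env_table <- function(metadata) {
  cp <- climate_pca(metadata)
  hb <- transform_habitat(metadata$slope, metadata$rar)
  out <- data.frame(cp$scores, slope_t = hb$slope_t, rar_t = hb$rar_t,
                    stringsAsFactors = FALSE)
  attr(out, "climate_pca") <- cp
  out
}

#' Simple OLS regression of a diversity index on one predictor
#'
#' Univariate ordinary least squares with intercept; reports R-squared, the
#' sign of the slope and the two-sided t-test p-value of the slope.
#'
#' @param y response vector.
#' @param x predictor vector (non-constant).
#' @return list: `r2`, `sign` (`"+"` or `"-"`), `slope`, `p`, `n`.
#' @export
simple_ols <- function(y, x) {
  if (length(y) != length(x) || length(y) < 3)
    stop("need n >= 3 paired observations")
  if (var(x) == 0) stop("zero-variance predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  b <- coef(fit)[2]
  list(r2 = sm$r.squared, sign = if (b >= 0) "+" else "-",
       slope = unname(b), p = sm$coefficients[2, 4], n = length(y))
}

#' Geographic distance matrix under an equidistant cylindrical projection
#'
#' Plots are projected to `x = R * lon_rad * cos(lat0)`,
#' `y = R * lat_rad` with `lat0` the mean plot latitude as standard
#' parallel and `R = 6,371,000` m, then Euclidean distances are taken.
#' Accurate to well under 1% of the great-circle distance for the few-km
#' extents of a single transect.
#'
#' @param metadata data.frame with `plot_id`, `latitude`, `longitude`.
#' @return a [distance_matrix()] in meters.
#' @export
geographic_distance <- function(metadata) {
  R_earth <- 6371000
  lat0 <- mean(metadata$latitude) * pi / 180
  x <- R_earth * metadata$longitude * pi / 180 * cos(lat0)
  y <- R_earth * metadata$latitude * pi / 180
  xy <- cbind(x, y)
  rownames(xy) <- metadata$plot_id
  distance_matrix(as.matrix(dist(xy)))
}

#' Climatic, habitat and integrated environmental distance matrices
#'
#' Euclidean distance over (`pc1_clim`, `pc2_clim`) for the climatic
#' distance, over (`slope_t`, `rar_t`) for the habitat distance, and over
#' all four columns for the environmental distance, so that
#' `Dist_env^2 = Dist_clim^2 + Dist_habit^2` holds exactly.
#'
#' @param env an [env_table()].
#' @return list of [distance_matrix()] objects: `clim`, `habit`, `env`.
#' @export
env_distances <- function(env) {
  m <- as.matrix(env[, c("pc1_clim", "pc2_clim", "slope_t", "rar_t")])
  rownames(m) <- env$plot_id
  list(clim = distance_matrix(as.matrix(dist(m[, 1:2]))),
       habit = distance_matrix(as.matrix(dist(m[, 3:4]))),
       env = distance_matrix(as.matrix(dist(m))))
}

#' Simple Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the strictly-lower-triangle entries;
#' significance comes from simultaneously permuting the rows and columns of
#' `b`, two-tailed on |r| with the add-one correction.
#'
#' @param a,b distance matrices sharing labels in the same order.
#' @param n_perm number of matrix permutations.
#' @param seed integer RNG seed.
#' @return list: `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(a, b, n_perm = 999, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  check_same_labels(a, b)
  va <- lower_triangle(a)
  vb <- lower_triangle(b)
  if (var(va) == 0 || var(vb) == 0)
    stop("constant distance matrix in mantel test")
  r_obs <- cor(va, vb)
  n <- nrow(b)
  set.seed(seed)
  r_null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(va, lower_triangle(b[p, p]))
  }, numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm, seed = seed)
}

# internal: design matrix/response from vectors or distance matrices
as_model_data <- function(y, predictors, response_is_distance) {
  if (response_is_distance) {
    yv <- lower_triangle(y)
    Xv <- lapply(predictors, lower_triangle)
  } else {
    yv <- as.numeric(y)
    Xv <- lapply(predictors, as.numeric)
  }
  X <- do.call(cbind, Xv)
  colnames(X) <- names(predictors)
  list(y = yv, X = X)
}

#' All-subsets OLS with AICc, Akaike weights and model ranking
#'
#' Fits every non-empty subset of the candidate predictors (2^k - 1
#' models; the intercept-only model is excluded from the enumeration) by
#' OLS — on strictly-lower-triangle vectors when the response and
#' predictors are distance matrices — and ranks them by the corrected
#' Akaike information criterion
#' `AICc = n log(RSS/n) + 2p + 2p(p+1)/(n-p-1)` with `p` = number of
#' predictors + 2 (intercept and variance). Akaike weights are
#' `exp(-dAICc/2)` normalized over the set.
#'
#' @param y response vector, or distance matrix when
#'   `response_is_distance = TRUE`.
#' @param predictors named list of predictor vectors (or distance
#'   matrices), 1 to 10 of them.
#' @param response_is_distance treat inputs as distance matrices and model
#'   their lower triangles.
#' @return list of class `model_set`: `models` data.frame (one row per
#'   subset: `model`, `k`, `r2`, `aicc`, `delta`, `weight`), `best`
#'   (formula string of the AICc-best model), `coefficients` (list),
#'   `n`.
#' @export
all_subsets_aicc <- function(y, predictors, response_is_distance = FALSE) {
  k <- length(predictors)
  if (k < 1 || k > 10) stop("need 1 to 10 candidate predictors")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop("predictors must be named")
  md <- as_model_data(y, predictors, response_is_distance)
  n <- length(md$y)
  if (n <= k + 2) stop("too few observations for the full model")
  kappa_full <- kappa(cbind(1, scale(md$X)), exact = TRUE)
  if (kappa_full > 1e10)
    warning("near-collinear predictors (condition number > 1e10)")
  subsets <- unlist(lapply(seq_len(k), function(m)
    combn(k, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    Xs <- md$X[, s, drop = FALSE]
    fit <- lm(md$y ~ Xs)
    rss <- sum(fit$residuals^2)
    p <- length(s) + 2
    aicc <- n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    data.frame(model = paste(names(predictors)[s], collapse = "+"),
               k = length(s), r2 = summary(fit)$r.squared, aicc = aicc,
               stringsAsFactors = FALSE)
  })
  models <- do.call(rbind, rows)
  models$delta <- models$aicc - min(models$aicc)
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  models <- models[order(models$aicc), ]
  rownames(models) <- NULL
  coefs <- lapply(subsets, function(s) {
    fit <- lm(md$y ~ md$X[, s, drop = FALSE])
    setNames(coef(fit), c("(Intercept)", names(predictors)[s]))
  })
  names(coefs) <- vapply(subsets, function(s)
    paste(names(predictors)[s], collapse = "+"), character(1))
  structure(list(models = models, best = models$model[1],
                 coefficients = coefs, n = n,
                 terms = names(predictors)),
            class = "model_set")
}

#' Akaike-weight importance of each variable
#'
#' The importance of a variable is the sum of the Akaike weights of every
#' model in the set that contains it.
#'
#' @param ms a `model_set` from [all_subsets_aicc()].
#' @return named numeric vector in `(0, 1]`.
#' @export
importance_values <- function(ms) {
  stopifnot(inherits(ms, "model_set"))
  terms <- strsplit(ms$models$model, "+", fixed = TRUE)
  vapply(setNames(ms$terms, ms$terms), function(v)
    sum(ms$models$weight[vapply(terms, function(t) v %in% t, logical(1))]),
    numeric(1))
}

#' Variation partitioning of alpha diversity between two predictor blocks
#'
#' Partial-regression decomposition of the full-model R-squared into the
#' pure fraction of block a, the fraction shared between the blocks and
#' the pure fraction of block b:
#' `pure_a = R2_ab - R2_b`, `pure_b = R2_ab - R2_a`,
#' `shared = R2_a + R2_b - R2_ab`, `unexplained = 1 - R2_ab`.
#' Unadjusted R-squared by default; with `adjusted = TRUE` the same
#' algebra is applied to adjusted R-squared (fractions may then be
#' negative).
#'
#' @param y response vector.
#' @param block_a,block_b named lists (or data.frames) of predictor
#'   vectors; the blocks must not share variables.
#' @param adjusted use adjusted R-squared.
#' @return list: `pure_a`, `shared`, `pure_b`, `unexplained`, `r2_full`,
#'   `r2_a`, `r2_b`.
#' @export
variation_partition_alpha <- function(y, block_a, block_b,
                                      adjusted = FALSE) {
  Xa <- as.matrix(as.data.frame(block_a))
  Xb <- as.matrix(as.data.frame(block_b))
  if (length(intersect(colnames(Xa), colnames(Xb))))
    stop("blocks must be disjoint")
  n <- length(y)
  if (n <= ncol(Xa) + ncol(Xb) + 1) stop("too few observations")
  r2 <- function(X) {
    sm <- summary(lm(y ~ X))
    if (adjusted) sm$adj.r.squared else sm$r.squared
  }
  r2a <- r2(Xa); r2b <- r2(Xb); r2ab <- r2(cbind(Xa, Xb))
  list(pure_a = r2ab - r2b, shared = r2a + r2b - r2ab,
       pure_b = r2ab - r2a, unexplained = 1 - r2ab,
       r2_full = r2ab, r2_a = r2a, r2_b = r2b)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response distance matrix on predictor distance matrices,
#' all unfolded to strictly-lower-triangle vectors. Coefficient
#' significance comes from permuting the rows and columns of the response
#' matrix, refitting, and comparing |t| of each coefficient against its
#' permutation distribution (two-tailed, add-one correction); the model
#' R-squared gets a p-value from the same permutations.
#'
#' @param dist_y response distance matrix.
#' @param predictors named list of predictor distance matrices with the
#'   same labels.
#' @param n_perm number of matrix permutations.
#' @param seed integer RNG seed.
#' @return list: `coefficients`, `r2`, `p_coef` (per predictor,
#'   intercept `NA`), `p_r2`, `n_perm`, `seed`.
#' @export
mrm <- function(dist_y, predictors, n_perm = 999, seed = 1L) {
  dist_y <- as.matrix(dist_y)
  do.call(check_same_labels, c(list(dist_y), lapply(predictors, as.matrix)))
  md <- as_model_data(dist_y, predictors, response_is_distance = TRUE)
  X <- cbind("(Intercept)" = 1, md$X)
  fit0 <- lm.fit(X, md$y)
  tstat <- function(fit, yv) {
    rss <- sum(fit$residuals^2)
    df <- length(yv) - fit$rank
    XtXi <- chol2inv(qr.R(fit$qr))
    se <- sqrt(diag(XtXi) * rss / df)
    fit$coefficients / se
  }
  t_obs <- tstat(fit0, md$y)
  r2_obs <- 1 - sum(fit0$residuals^2) /
    sum((md$y - mean(md$y))^2)
  n <- nrow(dist_y)
  set.seed(seed)
  exceed <- numeric(length(t_obs)); exceed_r2 <- 0
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- lower_triangle(dist_y[p, p])
    fitp <- lm.fit(X, yp)
    exceed <- exceed + (abs(tstat(fitp, yp)) >= abs(t_obs))
    r2p <- 1 - sum(fitp$residuals^2) / sum((yp - mean(yp))^2)
    exceed_r2 <- exceed_r2 + (r2p >= r2_obs)
  }
  p_coef <- (1 + exceed) / (n_perm + 1)
  p_coef[1] <- NA
  names(p_coef) <- colnames(X)
  list(coefficients = setNames(fit0$coefficients, colnames(X)),
       r2 = r2_obs, p_coef = p_coef,
       p_r2 = (1 + exceed_r2) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

#' Variation partitioning of beta diversity between distance-matrix blocks
#'
#' Same partial-regression algebra as [variation_partition_alpha()], with
#' the R-squared values taken from OLS fits on lower-triangle vectors
#' (blocks typically `{Dist_geo}` and `{Dist_env}`).
#'
#' @param dist_y response distance matrix.
#' @param block_a,block_b named lists of predictor distance matrices.
#' @param adjusted use adjusted R-squared.
#' @return as [variation_partition_alpha()].
#' @export
variation_partition_beta <- function(dist_y, block_a, block_b,
                                     adjusted = FALSE) {
  yv <- lower_triangle(as.matrix(dist_y))
  va <- lapply(block_a, lower_triangle)
  vb <- lapply(block_b, lower_triangle)
  variation_partition_alpha(yv, va, vb, adjusted = adjusted)
}
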