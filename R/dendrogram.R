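# Functional dendrogram pipeline: log-standardize traits, PCA to remove
# trait redundancy, Euclidean distance on the retained component scores,
# UPGMA clustering, cophenetic distances.

#' Log-transform and z-standardize a trait table
#'
#' Natural log (the base is immaterial: z-scores are identical under any
#' log base), then per-trait centring and scaling to mean 0, SD 1 across
#' species.
#'
#' @param traits data.frame or matrix of strictly positive trait values,
#'   species in rows. Non-numeric columns are dropped.
#' @return numeric matrix of z-scores with the same rownames.
#' @export
prepare_traits <- function(traits) {
  if (is.data.frame(traits)) {
    keep <- vapply(traits, is.numeric, logical(1))
    traits <- as.matrix(traits[, keep, drop = FALSE])
  }
  if (any(traits <= 0)) stop("trait values must be strictly positive")
  lx <- log(traits)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0))
    stop("zero-variance trait after log transform: ",
         paste(colnames(lx)[sds == 0], collapse = ", "))
  scale(lx)[, , drop = FALSE]
}

#' Principal components analysis of a standardized trait matrix
#'
#' Eigendecomposition of the correlation matrix of the (already
#' standardized) traits — equivalent to the covariance of the z-scores.
#' Eigenvector signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param z standardized trait matrix from [prepare_traits()].
#' @param n_components number of components to retain for the scores
#'   (default 4, the conventional choice for a five-trait table).
#' @return list of class `trait_pca`: `scores` (species x retained
#'   components), `loadings` (traits x all components),
#'   `explained_fraction` (all components, sums to 1), `cumulative`.
#' @export
trait_pca <- function(z, n_components = 4) {
  z <- as.matrix(z)
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > ncol(z))
    stop("n_components exceeds the number of traits")
  R <- cor(z)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(z), paste0("PC", seq_len(ncol(vecs))))
  scores <- z %*% vecs[, seq_len(n_components), drop = FALSE]
  ef <- vals / sum(vals)
  structure(list(scores = scores, loadings = vecs,
                 explained_fraction = ef, cumulative = cumsum(ef)),
            class = "trait_pca")
}

#' Euclidean distance matrix between score rows
#'
#' @param scores numeric matrix with rownames (e.g. PCA scores).
#' @return a [distance_matrix()].
#' @export
euclidean_distance <- function(scores) {
  d <- as.matrix(dist(scores, method = "euclidean"))
  distance_matrix(d)
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the inter-cluster
#' distance is the unweighted arithmetic mean of all member pairwise
#' distances, and the merge height is half that distance, so the resulting
#' dendrogram is ultrametric (cophenetic distance = 2 x merge height =
#' average distance at the merge). Ties are broken deterministically by the
#' lexicographically lowest pair of cluster representative labels, so the
#' output is reproducible across platforms.
#'
#' @param d a [distance_matrix()] (or plain labelled symmetric matrix) with
#'   at least 2 labels and no missing values.
#' @return list of class `upgma_dendrogram` with hclust-compatible fields
#'   `merge`, `height` (merge heights, = distance / 2), `order`, `labels`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("NaN/NA in distance matrix")
  labels <- rownames(d)
  if (is.null(labels) || length(labels) < 2)
    stop("need a labelled distance matrix with >= 2 labels")
  n <- length(labels)
  active <- as.list(seq_len(n))            # member tip indices per cluster
  rep_lab <- labels                        # representative (min) label
  idx <- -seq_len(n)                       # hclust merge coding
  size <- rep(1L, n)
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    best_d <- min(D)
    cand <- which(D - best_d <= 1e-12 & upper.tri(D), arr.ind = TRUE)
    # ties: lexicographically lowest (sorted) pair of representative labels
    keys <- apply(cand, 1, function(ij) {
      k <- sort(rep_lab[ij]); paste(k[1], k[2], sep = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    best_d <- D[i, j]
    merge[step, ] <- c(idx[i], idx[j])
    height[step] <- best_d / 2
    # Lance-Williams update for unweighted average linkage
    others <- which(alive); others <- others[others != i & others != j]
    if (length(others)) {
      upd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- D[others, i] <- upd
    }
    active[[i]] <- c(active[[i]], active[[j]])
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    idx[i] <- step
    alive[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
  }
  ord <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average"),
            class = c("upgma_dendrogram", "hclust"))
}

# tip ordering consistent with the merge history (for plotting)
dendro_order <- function(merge, n) {
  expand <- function(row) {
    unlist(lapply(merge[row, ], function(v)
      if (v < 0) -v else expand(v)))
  }
  expand(nrow(merge))
}

#' Cophenetic distance matrix of a dendrogram
#'
#' `d[i, j]` = 2 x the height of the merge first joining tips i and j;
#' ultrametric by construction.
#'
#' @param dendro an `upgma_dendrogram` (or any `hclust`).
#' @return a [distance_matrix()].
#' @export
cophenetic_distance <- function(dendro) {
  n <- length(dendro$labels)
  members <- vector("list", nrow(dendro$merge))
  cm <- matrix(0, n, n, dimnames = list(dendro$labels, dendro$labels))
  get_members <- function(v) if (v < 0) -v else members[[v]]
  for (s in seq_len(nrow(dendro$merge))) {
    a <- get_members(dendro$merge[s, 1])
    b <- get_members(dendro$merge[s, 2])
    cm[a, b] <- cm[b, a] <- 2 * dendro$height[s]
    members[[s]] <- c(a, b)
  }
  distance_matrix(cm)
}

#' Convert a dendrogram to an ultrametric phylo object
#'
#' Node heights are the merge heights, so patristic distances on the
#' returned tree equal the cophenetic distances of the dendrogram.
#'
#' @param dendro an `upgma_dendrogram`.
#' @return an [ape::phylo].
#' @export
dendro_to_phylo <- function(dendro) {
  h <- dendro
  # as.phylo.hclust places each node at height/2 (hclust heights are
  # cophenetic distances); our heights are already halved, so double them
  h$height <- 2 * h$height
  class(h) <- "hclust"
  ape::as.phylo(h)
}

#' Full functional-dendrogram pipeline
#'
#' [prepare_traits()] -> [trait_pca()] -> [euclidean_distance()] ->
#' [upgma()]; deterministic for a given trait table.
#'
#' @param traits positive trait table (species rows).
#' @param n_components retained components for the distance (default 4).
#' @return list with `z`, `pca`, `dist`, `dendrogram`, `cophenetic`.
#' @export
functional_dendrogram <- function(traits, n_components = 4) {
  z <- prepare_traits(traits)
  pca <- trait_pca(z, n_components = n_components)
  d <- euclidean_distance(pca$scores)
  den <- upgma(d)
  list(z = z, pca = pca, dist = d, dendrogram = den,
       cophenetic = cophenetic_distance(den))
}
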