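#' Construct a labelled distance matrix
#'
#' Thin validated wrapper around a square symmetric matrix with zero diagonal
#' and unique row/column labels. All distance-consuming functions in gradiv
#' (`mpd_alpha()`, `mantel()`, `mrm()`, ...) accept objects created here or
#' any plain matrix passing the same checks.
#'
#' @param d square numeric matrix of non-negative distances.
#' @param labels optional character vector of labels; defaults to the
#'   dimnames of `d`.
#' @return a numeric matrix of class `dist_matrix` with dimnames set.
#' @export
distance_matrix <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) stop("labels required (none found in dimnames)")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (length(labels) != nrow(d)) stop("label length does not match matrix")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  if (any(d < 0)) stop("negative entries in distance matrix")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d))))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  class(d) <- c("dist_matrix", "matrix", "array")
  d
}

#' Strictly-lower-triangle vector of a distance matrix
#'
#' @param d square matrix.
#' @return numeric vector of the n(n-1)/2 below-diagonal entries, column-major.
#' @export
lower_triangle <- function(d) {
  d <- as.matrix(d)
  d[lower.tri(d)]
}

# internal: check two (or more) distance matrices share labels in order
check_same_labels <- function(...) {
  mats <- list(...)
  lab <- rownames(as.matrix(mats[[1]]))
  for (m in mats[-1]) {
    if (!identical(rownames(as.matrix(m)), lab))
      stop("distance matrices must share identical labels in the same order")
  }
  invisible(lab)
}
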