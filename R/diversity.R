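#' Shannon diversity index
#'
#' `H = -sum p_i ln p_i` over taxa with nonzero abundance, natural
#' logarithm. Intended for rarefied counts (alpha diversity is sensitive
#' to uneven depth); a warning is issued for other kinds.
#'
#' @param table a [comm_table()] or abundance matrix (samples x taxa).
#' @return named numeric vector, one value per sample.
#' @export
shannon <- function(table) {
  k <- tab_kind(table)
  if (!is.na(k) && k != "rarefied")
    warning("Shannon index computed on kind '", k,
            "'; rarefied counts are recommended")
  m <- if (inherits(table, "comm_table")) as_comm_matrix(table) else
    as.matrix(table)
  if (any(rowSums(m) == 0)) stop("zero-sum sample")
  vegan::diversity(m, index = "shannon")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`, in `[0, 1]`.
#'
#' @param table a [comm_table()] or abundance matrix with nonzero rows.
#' @return a [stats::dist] object.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "comm_table")) as_comm_matrix(table) else
    as.matrix(table)
  if (any(rowSums(m) == 0)) stop("zero-sum sample")
  vegan::vegdist(m, method = "bray")
}

#' Euclidean distance, optionally on standardized columns
#'
#' With `standardize = TRUE` every column is z-scored (mean 0, sd 1)
#' before distances are taken, so each variable contributes on a common
#' scale; a zero-variance column is then an error.
#'
#' @param m numeric matrix (samples x variables).
#' @param standardize z-score columns first (default `FALSE`).
#' @return a [stats::dist] object.
#' @export
euclidean_dist <- function(m, standardize = FALSE) {
  m <- as.matrix(m)
  if (standardize) {
    s <- apply(m, 2, sd)
    if (any(s == 0))
      stop("zero-variance column(s): ",
           paste(colnames(m)[s == 0], collapse = ", "))
    m <- scale(m)
  }
  dist(m)
}

#' Principal coordinates analysis (PCoA)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns axes scaled
#' by the square root of their eigenvalues. Axes with negative eigenvalues
#' are dropped (not corrected); their summed magnitude is returned so the
#' distortion can be judged. Variance proportions are taken over the
#' positive eigenvalues.
#'
#' @param d a [stats::dist] object or symmetric distance matrix, `n >= 3`.
#' @return list of class `pcoa_ord`: `points` (n x k axis scores,
#'   decreasing eigenvalue order), `eig` (all eigenvalues), `prop_var`
#'   (share of positive-eigenvalue variance per retained axis),
#'   `negative_sum` (total magnitude of negative eigenvalues).
#' @export
pcoa_ord <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  pts <- sweep(e$vectors[, pos, drop = FALSE], 2,
               sqrt(e$values[pos]), "*")
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = pts, eig = e$values,
                 prop_var = e$values[pos] / sum(e$values[pos]),
                 negative_sum = sum(abs(e$values[e$values < -tol]))),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (first axis %.1f%%)\n",
              nrow(x$points), ncol(x$points), 100 * x$prop_var[1]))
  invisible(x)
}

# Gower double-centering of a squared distance matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n)
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}
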