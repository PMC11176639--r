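#' Distance-based Moran's eigenvector maps (dbMEM)
#'
#' Builds the classical truncated-distance spatial basis: Euclidean
#' distances among sample coordinates; truncation threshold `t` = longest
#' edge of the minimum spanning tree; entries greater than `t` replaced by
#' `4 t`; PCoA of the truncated matrix; eigenvectors with positive
#' eigenvalues retained, as orthonormal columns. The leading vectors
#' describe broad-scale spatial structure (monotone along a transect),
#' later ones progressively finer waves.
#'
#' @param coordinates numeric matrix/data.frame of sample coordinates in
#'   meters (n x 2, or n x k), `n >= 4`, not all identical.
#' @return list of class `mem_basis`: `vectors` (n x m orthonormal),
#'   `values` (positive eigenvalues), `threshold`, `selected` (indices of
#'   vectors retained by [select_mems()]; initially all).
#' @export
build_dbmem <- function(coordinates) {
  xy <- as.matrix(coordinates)
  if (nrow(xy) < 4) stop("need at least 4 samples")
  if (!all(is.finite(xy))) stop("non-finite coordinates")
  d <- dist(xy)
  if (max(d) == 0) stop("all coordinates identical")
  thr <- max(vegan::spantree(d)$dist)
  Dm <- as.matrix(d)
  Dm[Dm > thr] <- 4 * thr
  G <- gower_center(Dm)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  vec <- e$vectors[, pos, drop = FALSE]
  rownames(vec) <- rownames(xy)
  colnames(vec) <- paste0("MEM", seq_along(pos))
  structure(list(vectors = vec, values = e$values[pos], threshold = thr,
                 selected = seq_along(pos)),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("dbMEM basis: %d eigenvectors (truncation %.2f m), %d selected\n",
              ncol(x$vectors), x$threshold, length(x$selected)))
  invisible(x)
}

#' Select MEMs associated with a community distance matrix
#'
#' Tests every eigenvector marginally against the distance matrix with a
#' single-variable distance-based RDA pseudo-F and a free permutation
#' test, adjusts the p-values across MEMs by Benjamini-Hochberg, and
#' retains those with adjusted p below `alpha`. An empty selection is
#' allowed (variance partitioning then assigns no spatial fraction).
#'
#' @param basis a `mem_basis` from [build_dbmem()].
#' @param d [stats::dist] over the same samples.
#' @param n_perm permutations per MEM (default 999).
#' @param alpha significance level on the BH-adjusted p (default 0.05).
#' @param seed integer seed.
#' @return the basis with `selected` replaced, plus a `tests` data.frame
#'   (MEM, R2, F, p, p_adj).
#' @export
select_mems <- function(basis, d, n_perm = 999, alpha = 0.05, seed = NULL) {
  G <- gower_center(as.matrix(d))
  n <- nrow(G)
  ss_tot <- sum(diag(G))
  m <- ncol(basis$vectors)
  stat <- function(Gm, v) {
    ssm <- ma_ss(Gm, v)
    c(ssm / ss_tot, ssm / ((ss_tot - ssm) / (n - 2)))
  }
  res <- matrix(NA_real_, m, 3,
                dimnames = list(colnames(basis$vectors),
                                c("R2", "F", "p")))
  with_seed(seed, {
    for (j in seq_len(m)) {
      v <- basis$vectors[, j, drop = FALSE]
      s <- stat(G, v)
      ge <- 0
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        if (stat(G[idx, idx], v)[2] >= s[2]) ge <- ge + 1
      }
      res[j, ] <- c(s, (ge + 1) / (n_perm + 1))
    }
  })
  p_adj <- p.adjust(res[, "p"], "BH")
  basis$selected <- which(p_adj < alpha)
  basis$tests <- data.frame(MEM = rownames(res), res, p_adj = p_adj,
                            row.names = NULL)
  basis
}

#' Environment/space variance partitioning of a distance matrix
#'
#' Partitions distance-matrix variation between an environmental matrix E
#' (standardized chemistry) and a spatial matrix S (selected MEMs) using
#' distance-based RDA R2 (McArdle-Anderson sums of squares) and the
#' Ezekiel adjustment `R2adj = 1 - (1 - R2)(n - 1)/(n - p - 1)`:
#' `a = R2adj(E+S) - R2adj(S)` (environment alone),
#' `c = R2adj(E+S) - R2adj(E)` (space alone), `b = R2adj(E) - a`
#' (shared), `d = 1 - (a + b + c)` (residual). Adjusted fractions can be
#' slightly negative; values below -0.05 are flagged with a warning.
#'
#' @param d [stats::dist] over the samples.
#' @param chemistry numeric matrix of environmental covariates (z-scored
#'   internally).
#' @param mem a `mem_basis` (its `selected` vectors are used) or a
#'   numeric matrix of spatial predictors; may be empty/NULL, in which
#'   case `b = c = 0` and `a = R2adj(E)`.
#' @return list with `fractions` (named a, b, c, d), `R2` and `R2_adj`
#'   for models E, S, ES, and `n_env`, `n_space` predictor counts.
#' @export
varpart_env_space <- function(d, chemistry, mem) {
  E <- scale(as.matrix(chemistry))
  S <- if (is.null(mem)) NULL
  else if (inherits(mem, "mem_basis"))
    mem$vectors[, mem$selected, drop = FALSE]
  else as.matrix(mem)
  if (!is.null(S) && ncol(S) == 0) S <- NULL
  G <- gower_center(as.matrix(d))
  n <- nrow(G)
  ss_tot <- sum(diag(G))
  r2 <- function(X) ma_ss(G, X) / ss_tot
  adj <- function(R2, p) 1 - (1 - R2) * (n - 1) / (n - p - 1)
  p_e <- ma_rank(E)
  p_s <- if (is.null(S)) 0L else ma_rank(S)
  p_es <- if (is.null(S)) p_e else ma_rank(cbind(E, S))
  if (max(p_e, p_s, p_es) >= n - 1)
    stop("saturated model: predictors >= n - 1")
  R2_e <- r2(E)
  R2_s <- if (is.null(S)) 0 else r2(S)
  R2_es <- if (is.null(S)) R2_e else r2(cbind(E, S))
  A_e <- adj(R2_e, p_e)
  A_s <- if (is.null(S)) 0 else adj(R2_s, p_s)
  A_es <- if (is.null(S)) A_e else adj(R2_es, p_es)
  a <- A_es - A_s
  c_ <- A_es - A_e
  b <- A_e - a
  d_ <- 1 - (a + b + c_)
  fr <- c(a = a, b = b, c = c_, d = d_)
  if (any(fr[c("a", "c")] < -0.05))
    warning("strongly negative adjusted fraction: check model sizes")
  list(fractions = fr,
       R2 = c(E = R2_e, S = R2_s, ES = R2_es),
       R2_adj = c(E = A_e, S = A_s, ES = A_es),
       n_env = p_e, n_space = p_s)
}
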