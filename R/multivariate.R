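#' PERMANOVA (sequential terms)
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' delegating to [vegan::adonis2] with sequential (Type-I) terms in the
#' order given, free permutation of sample labels, and the
#' `(b + 1)/(m + 1)` p-value estimator. Typical usage fits `plot_type`
#' then `plot` so the nested factor absorbs variance after the coarse one.
#'
#' @param d [stats::dist] over the frame's samples (same order).
#' @param frame data.frame of sample covariates.
#' @param terms character vector of column names, fitted in this order.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param permutations optional explicit permutation matrix (rows =
#'   permutations of `1:n`), e.g. an exhaustive enumeration.
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   `term`, `df`, `SS`, `R2` (= SS/SS_total), `F`, `p`.
#' @export
permanova <- function(d, frame, terms, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  for (tm in terms)
    if (length(unique(frame[[tm]])) < 2)
      stop("term '", tm, "' has a single level")
  dat <- frame[, terms, drop = FALSE]
  for (tm in terms) dat[[tm]] <- factor(dat[[tm]])
  perm <- if (!is.null(permutations)) permutations else n_perm
  fml <- reformulate(terms, response = quote(d))
  res <- with_seed(seed,
    vegan::adonis2(fml, data = dat, permutations = perm, by = "terms"))
  data.frame(term = rownames(res), df = res$Df, SS = res$SumOfSqs,
             R2 = res$R2, F = res$F, p = res$`Pr(>F)`,
             row.names = NULL)
}

#' Mantel test
#'
#' Pearson correlation of the off-diagonal entries of two distance
#' matrices, with a one-tailed (greater) permutation test on rows/columns
#' of the second matrix and the `(b + 1)/(m + 1)` estimator; delegates to
#' [vegan::mantel].
#'
#' @param d_a,d_b [stats::dist] objects over the same samples in the same
#'   order.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param permutations optional explicit permutation matrix.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d_a, d_b, n_perm = 999, seed = NULL,
                        permutations = NULL) {
  va <- as.vector(as.dist(d_a)); vb <- as.vector(as.dist(d_b))
  if (sd(va) == 0 || sd(vb) == 0) stop("constant distance matrix")
  perm <- if (!is.null(permutations)) permutations else n_perm
  res <- with_seed(seed, vegan::mantel(d_a, d_b, permutations = perm))
  list(r = unname(res$statistic), p = res$signif,
       n_perm = if (is.matrix(perm)) nrow(perm) else perm)
}

#' Distance-decay of community similarity
#'
#' Tests whether Bray-Curtis similarity (`1 - BC`) declines with
#' geographic or environmental distance. The Mantel correlation is
#' computed between similarity and distance (negative under decay); the
#' one-tailed permutation p-value tests the decay direction. A
#' least-squares slope of similarity on distance is returned for
#' plotting.
#'
#' @param comm_dist community dissimilarity ([stats::dist], e.g.
#'   Bray-Curtis).
#' @param space_dist geographic or environmental distance over the same
#'   samples.
#' @inheritParams mantel_test
#' @return list with `r` (similarity vs distance), `p`, `slope`,
#'   `intercept`, `n_perm`.
#' @export
distance_decay <- function(comm_dist, space_dist, n_perm = 999,
                           seed = NULL, permutations = NULL) {
  # decay in similarity = positive association dissimilarity ~ distance,
  # which is the direction vegan's one-tailed test examines
  mt <- mantel_test(comm_dist, space_dist, n_perm = n_perm, seed = seed,
                    permutations = permutations)
  sim <- 1 - as.vector(as.dist(comm_dist))
  dis <- as.vector(as.dist(space_dist))
  fit <- stats::lm.fit(cbind(1, dis), sim)
  list(r = -mt$r, p = mt$p, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n_perm = mt$n_perm)
}

#' Procrustes congruence test (protest)
#'
#' Symmetric Procrustes analysis of two ordinations: both configurations
#' are centered and unit-normalized, `m12^2 = 1 - (sum of singular values
#' of X'Y)^2` is the residual after optimal rotation, and `r =
#' sqrt(1 - m12^2)` the correlation-like statistic, tested by permuting
#' rows of the second configuration ([vegan::protest], 999 permutations
#' by default).
#'
#' @param scores_x,scores_y numeric matrices (samples x axes, same sample
#'   order, >= 2 axes each).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `m12_squared`, `r`, `p`, `n_perm`.
#' @export
procrustes_test <- function(scores_x, scores_y, n_perm = 999, seed = NULL) {
  res <- with_seed(seed,
    vegan::protest(scores_x, scores_y, permutations = n_perm,
                   symmetric = TRUE))
  list(m12_squared = res$ss, r = res$t0, p = res$signif, n_perm = n_perm)
}

# tr(H G) with H the hat matrix of cbind(1, X); computed via the thin QR
# so rank-deficient model matrices are handled. McArdle-Anderson: this is
# the model sum of squares of the distance matrix itself.
ma_ss <- function(G, X) {
  Xm <- cbind(1, X)
  qr_ <- qr(Xm)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  sum(Q * (G %*% Q))
}

ma_rank <- function(X) qr(cbind(1, X))$rank - 1L

#' Distance-based forward selection of environmental predictors (DistLM)
#'
#' Multivariate multiple regression of a distance matrix on covariates
#' using McArdle-Anderson sums of squares computed on the Gower-centered
#' distance matrix directly (negative-eigenvalue structure is thereby
#' retained; no embedding truncation). At each step the variable adding
#' the most explained SS enters, its conditional pseudo-F is tested by
#' free permutation of the centered matrix, and selection stops when the
#' best candidate's p exceeds `alpha`. Marginal (single-variable) R2 is
#' reported for every variable. Covariates are z-scored internally.
#'
#' @param d [stats::dist] over the samples.
#' @param chemistry numeric matrix/data.frame of candidate predictors
#'   (samples x variables), ideally pre-pruned for collinearity.
#' @param n_perm permutations per test (default 999).
#' @param alpha stopping threshold on the permutation p (default 0.05).
#' @param seed integer seed.
#' @return list with `selected` (data.frame: variable, R2_added,
#'   R2_cum, F, p in selection order; zero rows if nothing enters) and
#'   `marginal` (data.frame: variable, R2 for every candidate).
#' @export
distlm_forward <- function(d, chemistry, n_perm = 999, alpha = 0.05,
                           seed = NULL) {
  X <- scale(as.matrix(chemistry))
  if (ncol(X) == 0) stop("no candidate variables")
  n <- nrow(X)
  G <- gower_center(as.matrix(d))
  ss_tot <- sum(diag(G))
  marginal <- data.frame(
    variable = colnames(X),
    R2 = vapply(seq_len(ncol(X)),
                function(j) ma_ss(G, X[, j, drop = FALSE]) / ss_tot,
                numeric(1)))
  sel <- character(0)
  rows <- list()
  with_seed(seed, {
    repeat {
      remaining <- setdiff(colnames(X), sel)
      if (length(remaining) == 0) break
      ss_red <- if (length(sel) == 0) 0 else
        ma_ss(G, X[, sel, drop = FALSE])
      cand_ss <- vapply(remaining, function(v)
        ma_ss(G, X[, c(sel, v), drop = FALSE]), numeric(1))
      best <- remaining[which.max(cand_ss)]
      ss_full <- max(cand_ss)
      p_full <- ma_rank(X[, c(sel, best), drop = FALSE])
      f_obs <- (ss_full - ss_red) /
        ((ss_tot - ss_full) / (n - p_full - 1))
      ge <- 0
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        Gp <- G[idx, idx]
        ssr <- if (length(sel) == 0) 0 else
          ma_ss(Gp, X[, sel, drop = FALSE])
        ssf <- ma_ss(Gp, X[, c(sel, best), drop = FALSE])
        f_p <- (ssf - ssr) / ((ss_tot - ssf) / (n - p_full - 1))
        if (f_p >= f_obs) ge <- ge + 1
      }
      p_val <- (ge + 1) / (n_perm + 1)
      if (p_val > alpha) break
      sel <- c(sel, best)
      rows[[length(rows) + 1]] <- data.frame(
        variable = best, R2_added = (ss_full - ss_red) / ss_tot,
        R2_cum = ss_full / ss_tot, F = f_obs, p = p_val)
    }
  })
  selected <- if (length(rows) == 0)
    data.frame(variable = character(0), R2_added = numeric(0),
               R2_cum = numeric(0), F = numeric(0), p = numeric(0))
  else do.call(rbind, rows)
  list(selected = selected, marginal = marginal)
}
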