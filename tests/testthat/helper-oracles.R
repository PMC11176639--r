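# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# betaMNTD by a literal double loop over taxa
brute_beta_mntd <- function(x, y, D, weighted = TRUE) {
  px <- x / sum(x); py <- y / sum(y)
  sx <- names(px)[px > 0]; sy <- names(py)[py > 0]
  if (!weighted) {
    px[] <- 0; px[sx] <- 1 / length(sx)
    py[] <- 0; py[sy] <- 1 / length(sy)
  }
  s1 <- 0
  for (i in sx) {
    best <- Inf
    for (j in sy) best <- min(best, D[i, j])
    s1 <- s1 + px[i] * best
  }
  s2 <- 0
  for (i in sy) {
    best <- Inf
    for (j in sx) best <- min(best, D[i, j])
    s2 <- s2 + py[i] * best
  }
  unname(0.5 * (s1 + s2))
}

# all permutations of 1:n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Pearson correlation of the lower triangles of two distance matrices
offdiag_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  cor(a[lower.tri(a)], b[lower.tri(b)])
}

# pseudo-F for a one-factor PERMANOVA computed from first principles
brute_pseudo_f <- function(D, groups) {
  D <- as.matrix(D); n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X), t(X))
  ss_tot <- sum(diag(G))
  ss_mod <- sum(diag(H %*% G))
  df1 <- length(unique(groups)) - 1
  (ss_mod / df1) / ((ss_tot - ss_mod) / (n - df1 - 1))
}

# small rooted test tree: ((A:1,B:1):1,C:2);
toy_tree <- function() read_phylogeny("((A:1,B:1):1,C:2);", text = TRUE)
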