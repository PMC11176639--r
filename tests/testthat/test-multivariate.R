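test_that("PERMANOVA recovers an obvious group split and decomposes variance", {
  pts <- rbind(matrix(rnorm(10, 0, 1e-3), 5, 2),
               matrix(rnorm(10, 50, 1e-3), 5, 2))
  rownames(pts) <- paste0("s", 1:10)
  frame <- data.frame(sample_id = rownames(pts),
                      grp = rep(c("a", "b"), each = 5))
  res <- permanova(dist(pts), frame, "grp", n_perm = 199, seed = 1)
  expect_gt(res$R2[res$term == "grp"], 0.999)
  # permutations that reproduce the partition tie the observed F, so the
  # attainable minimum is (1 + #ties)/(n_perm + 1)
  expect_lte(res$p[res$term == "grp"], 0.05)
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-9)
  expect_error(permanova(dist(pts), data.frame(g = rep("a", 10)), "g"),
               "single level")
})

test_that("PERMANOVA permutation p matches exhaustive enumeration (n = 6)", {
  set.seed(41)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("s", 1:6)
  groups <- rep(c("a", "b"), each = 3)
  frame <- data.frame(grp = groups)
  d <- dist(pts)
  perms <- all_perms(6)   # 720 relabelings
  res <- permanova(d, frame, "grp", permutations = perms[-1, , drop = FALSE])
  # oracle: pseudo-F over every relabeling from first principles
  f_all <- apply(perms, 1, function(p) brute_pseudo_f(d, groups[p]))
  f_obs <- brute_pseudo_f(d, groups)
  expect_equal(res$F[1], f_obs, tolerance = 1e-9)
  p_oracle <- (sum(f_all[-1] >= f_obs - 1e-12) + 1) / 720
  expect_equal(res$p[1], p_oracle, tolerance = 1e-9)
})

test_that("PERMANOVA is invariant to jointly permuting distances and frame", {
  set.seed(42)
  pts <- matrix(rnorm(24), 12, 2)
  frame <- data.frame(grp = rep(c("a", "b", "c"), each = 4))
  d <- as.matrix(dist(pts))
  idx <- sample(12)
  r1 <- permanova(as.dist(d), frame, "grp", n_perm = 99, seed = 9)
  r2 <- permanova(as.dist(d[idx, idx]),
                  frame[idx, , drop = FALSE], "grp",
                  n_perm = 99, seed = 9)
  expect_equal(r1$F[1], r2$F[1], tolerance = 1e-9)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-9)
})

test_that("Mantel r and p behave and match exhaustive enumeration (n = 5)", {
  set.seed(43)
  pts <- matrix(rnorm(10), 5, 2)
  da <- dist(pts)
  expect_equal(mantel_test(da, da, n_perm = 49, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_equal(mantel_test(da, 3 * da + 2, n_perm = 49, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_error(mantel_test(da, dist(matrix(1, 5, 2))), "constant")

  db <- dist(matrix(rnorm(10), 5, 2))
  perms <- all_perms(5)
  res <- mantel_test(da, db, permutations = perms[-1, , drop = FALSE])
  A <- as.matrix(da); B <- as.matrix(db)
  r_obs <- offdiag_cor(A, B)
  r_all <- apply(perms, 1, function(p) offdiag_cor(A, B[p, p]))
  expect_equal(res$r, r_obs, tolerance = 1e-12)
  expect_equal(res$p, (sum(r_all[-1] >= r_obs - 1e-12) + 1) / 120,
               tolerance = 1e-9)
})

test_that("distance decay reports similarity-scale r and the fitted slope", {
  # perfect linear decay of similarity with distance
  x <- seq(0, 1, length.out = 8)
  sim <- outer(x, x, function(a, b) 1 - abs(a - b))
  bc <- as.dist(1 - sim)
  geo <- dist(x)
  dd <- distance_decay(bc, geo, n_perm = 99, seed = 1)
  expect_equal(dd$r, -1, tolerance = 1e-9)
  expect_equal(dd$slope, -1, tolerance = 1e-9)
  expect_lte(dd$p, 0.05)
  # shuffled similarities: no decay signal
  set.seed(44)
  bc2 <- as.dist(matrix(runif(64), 8, 8))
  dd2 <- distance_decay(as.dist(as.matrix(bc2)), geo, n_perm = 99, seed = 2)
  expect_lt(abs(dd2$r), 0.6)
})

test_that("Procrustes statistic matches a brute-force rotation search", {
  set.seed(45)
  X <- matrix(rnorm(8), 4, 2)
  # exact rotation + reflection: perfect congruence
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- X %*% R %*% diag(c(1, -1)) * 3 + 5
  pro <- procrustes_test(X, Y, n_perm = 99, seed = 1)
  expect_lt(pro$m12_squared, 1e-9)
  expect_equal(pro$r, 1, tolerance = 1e-6)

  Y2 <- matrix(rnorm(8), 4, 2)
  pro2 <- procrustes_test(X, Y2, n_perm = 199, seed = 1)
  # oracle: center, unit-normalize, scan rotations/reflections
  ctr <- function(M) { M <- scale(M, scale = FALSE); M / sqrt(sum(M^2)) }
  Xc <- ctr(X); Yc <- ctr(Y2)
  best <- -Inf
  for (t_ in seq(0, 2 * pi, by = 1e-4)) {
    Rt <- matrix(c(cos(t_), sin(t_), -sin(t_), cos(t_)), 2, 2)
    for (s in c(1, -1)) {
      Tr <- sum(Xc * (Yc %*% (Rt %*% diag(c(1, s)))))
      best <- max(best, Tr)
    }
  }
  expect_equal(pro2$m12_squared, 1 - best^2, tolerance = 1e-6)
  expect_equal(pro2$r, sqrt(1 - pro2$m12_squared), tolerance = 1e-9)
})

test_that("DistLM forward selection finds a planted gradient and stops on noise", {
  set.seed(46)
  grad <- seq(-2, 2, length.out = 20)
  comp <- cbind(grad, rnorm(20, 0, 0.2), rnorm(20, 0, 0.2))
  d <- dist(comp)
  ord1 <- pcoa_ord(d)$points[, 1]
  chem <- cbind(pc1 = ord1, junk1 = rnorm(20), junk2 = rnorm(20))
  res <- distlm_forward(d, chem, n_perm = 199, seed = 1)
  expect_equal(res$selected$variable[1], "pc1")
  # Euclidean input: a column equal to the first PCoA axis explains
  # exactly that axis' variance share
  expect_equal(res$marginal$R2[res$marginal$variable == "pc1"],
               pcoa_ord(d)$prop_var[1], tolerance = 1e-9)
  # pure-noise chemistry: usually nothing is selected at alpha = 0.05
  none <- 0
  for (s in 1:40) {
    set.seed(100 + s)
    chem_n <- matrix(rnorm(60), 20, 3,
                     dimnames = list(NULL, paste0("x", 1:3)))
    r <- distlm_forward(d, chem_n, n_perm = 99, alpha = 0.05,
                        seed = 200 + s)
    if (nrow(r$selected) == 0) none <- none + 1
  }
  expect_gte(none, 40 * 0.8)
})
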