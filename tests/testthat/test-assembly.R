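test_that("betaMNTD matches its closed-form cases", {
  tr <- toy_tree()
  # identical communities score 0
  tab <- make_counts(rbind(c(2, 1, 0), c(2, 1, 0)), taxa = c("A", "B", "C"))
  expect_equal(beta_mntd(tab, tr)["S1", "S2"], 0)
  # single-taxon communities collapse to the one patristic distance
  tab2 <- make_counts(rbind(c(5, 0, 0), c(0, 3, 0)), taxa = c("A", "B", "C"))
  expect_equal(beta_mntd(tab2, tr)["S1", "S2"], 2)
  tab3 <- make_counts(rbind(c(5, 0, 0), c(0, 0, 3)), taxa = c("A", "B", "C"))
  expect_equal(beta_mntd(tab3, tr)["S1", "S2"], 4)
})

test_that("betaMNTD equals the brute-force double loop on random communities", {
  set.seed(11)
  for (rep in 1:10) {
    t_n <- sample(4:10, 1)
    tree <- simulate_phylogeny(t_n, seed = rep)
    D <- ape::cophenetic.phylo(tree)
    m <- t(rmultinom(5, 40, runif(t_n) + 0.05))
    m[m == 0 & row(m) == 1] <- 0   # keep natural zeros
    tab <- make_counts(m, taxa = tree$tip.label)
    for (w in c(TRUE, FALSE)) {
      B <- beta_mntd(tab, tree, abundance_weighted = w)
      for (p in list(c(1, 2), c(2, 4), c(3, 5))) {
        expect_equal(B[p[1], p[2]],
                     brute_beta_mntd(unclass(tab)[p[1], ],
                                     unclass(tab)[p[2], ], D, weighted = w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("betaNTI matches exhaustive tip-relabeling enumeration", {
  tree <- simulate_phylogeny(4, seed = 21)
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  tab <- make_counts(rbind(c(6, 2, 0, 1), c(0, 3, 3, 2)),
                     taxa = tree$tip.label)
  perms <- all_perms(4)                      # all 24 relabelings
  res <- bnti(tab, tree, permutations = perms)
  # oracle: betaMNTD under every relabeled distance matrix
  vals <- apply(perms, 1, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    brute_beta_mntd(unclass(tab)[1, ], unclass(tab)[2, ], Dp)
  })
  z_oracle <- (brute_beta_mntd(unclass(tab)[1, ], unclass(tab)[2, ], D) -
                 mean(vals)) / sd(vals)
  expect_equal(res$bnti[1, 2], z_oracle, tolerance = 1e-9)
  expect_equal(res$obs[1, 2],
               brute_beta_mntd(unclass(tab)[1, ], unclass(tab)[2, ], D),
               tolerance = 1e-12)
})

test_that("a sampled null converges to the exhaustive one for 5 taxa", {
  tree <- simulate_phylogeny(5, seed = 22)
  tab <- make_counts(rbind(c(4, 1, 0, 2, 0), c(0, 2, 3, 0, 1)),
                     taxa = tree$tip.label)
  exact <- bnti(tab, tree, permutations = all_perms(5))
  sampled <- bnti(tab, tree, n_null = 2000, seed = 5)
  expect_equal(sampled$bnti[1, 2], exact$bnti[1, 2], tolerance = 0.15)
})

test_that("betaNTI is flagged undefined on a symmetric star phylogeny", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- make_counts(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                     taxa = c("A", "B", "C", "D"))
  res <- bnti(tab, star, n_null = 50, seed = 1)
  expect_true(is.na(res$bnti[1, 2]))
  expect_equal(res$n_undefined, 1)
})

test_that("betaNTI is invariant to joint relabeling and to doubling counts", {
  tree <- simulate_phylogeny(12, seed = 23)
  set.seed(23)
  m <- t(rmultinom(4, 100, runif(12)))
  dimnames(m) <- list(sprintf("S%d", 1:4), tree$tip.label)
  tab <- comm_table(m, "counts")
  base <- bnti(tab, tree, n_null = 99, seed = 7)
  # joint relabeling of table columns and tree tips
  perm <- sample(12)
  tree2 <- tree
  tree2$tip.label <- paste0("X", seq_len(12))
  m2 <- m[, perm]
  # relabel: taxon tree$tip.label[perm][i] -> X index of the same tip
  map <- setNames(paste0("X", seq_len(12)), tree$tip.label)
  colnames(m2) <- unname(map[tree$tip.label[perm]])
  tab2 <- comm_table(m2, "counts")
  again <- bnti(tab2, tree2, n_null = 99, seed = 7)
  expect_equal(sort(base$obs[upper.tri(base$obs)]),
               sort(again$obs[upper.tri(again$obs)]), tolerance = 1e-12)
  # doubling every count changes neither betaMNTD nor betaNTI
  dbl <- bnti(make_counts(2 * m, taxa = tree$tip.label), tree,
              n_null = 99, seed = 7)
  expect_equal(dbl$obs, base$obs, tolerance = 1e-12)
  expect_equal(dbl$bnti, base$bnti, tolerance = 1e-10)
})

test_that("RCBray hits its boundary values", {
  # identical samples from a diverse pool: obs BC = 0, below every null
  set.seed(31)
  pool_m <- t(rmultinom(6, 200, runif(20)))
  m <- rbind(pool_m[1, ], pool_m[1, ], pool_m[2:4, ])
  tab <- make_counts(m)
  rc <- rc_bray(tab, n_null = 99, seed = 2, pairs = cbind(1, 2))
  expect_equal(rc[1, 2], -1)
  # disjoint extreme pair: obs BC = 1, above every nondegenerate null
  m2 <- rbind(c(50, 50, 0, 0, rep(1, 6)), c(0, 0, 50, 50, rep(1, 6)))
  m2 <- rbind(m2, t(rmultinom(4, 100, rep(1, 10))))
  tab2 <- make_counts(m2)
  rc2 <- rc_bray(tab2, n_null = 99, seed = 3, pairs = cbind(1, 2))
  expect_gt(rc2[1, 2], 0.95)
  expect_true(all(abs(rc2[1, 2]) <= 1))
})

test_that("RCBray is seed-deterministic, bounded, and symmetric", {
  set.seed(32)
  m <- t(rmultinom(6, 150, runif(15) + 0.1))
  tab <- make_counts(m)
  r1 <- rc_bray(tab, n_null = 99, seed = 11)
  r2 <- rc_bray(tab, n_null = 99, seed = 11)
  expect_identical(r1, r2)
  v <- r1[upper.tri(r1)]
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(r1, t(r1))
  # the null is individual-based, so RC is defined at a common depth;
  # comparing tables rarefied to different depths is not meaningful and
  # no invariance across depths is claimed
  r3 <- rc_bray(tab, n_null = 99, seed = 12)
  expect_false(identical(r1, r3))
})

test_that("process classification follows the two-step thresholds", {
  expect_equal(classify_processes(-2.5, NA), "homogeneous_selection")
  expect_equal(classify_processes(3.1, NA), "heterogeneous_selection")
  expect_equal(classify_processes(1.0, 0.2), "undominated")
  expect_equal(classify_processes(0.0, 0.96), "dispersal_limitation")
  expect_equal(classify_processes(0.0, -0.97), "homogenizing_dispersal")
  # boundaries fall through to the non-significant branch
  expect_equal(classify_processes(2, 0.2), "undominated")
  expect_equal(classify_processes(-2, -0.95), "undominated")
  expect_equal(classify_processes(0, 0.95), "undominated")
  expect_true(is.na(classify_processes(NA, 0.5)))
  expect_error(classify_processes(0.5, NA), "required")
  # the five labels partition the plane
  set.seed(33)
  z <- runif(200, -4, 4); r <- runif(200, -1, 1)
  lab <- classify_processes(z, r)
  expect_false(any(is.na(lab)))
  expect_true(all(lab %in% c("homogeneous_selection",
                             "heterogeneous_selection",
                             "dispersal_limitation",
                             "homogenizing_dispersal", "undominated")))
})

test_that("process summaries are percentages of classified pairs", {
  df <- data.frame(sample_i = c("a", "a", "b"), sample_j = c("b", "c", "c"),
                   process = c("homogeneous_selection",
                               "homogeneous_selection",
                               "dispersal_limitation"))
  s <- summarize_processes(df)
  expect_equal(s$percent[s$process == "homogeneous_selection"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  all_hs <- df; all_hs$process <- "homogeneous_selection"
  expect_equal(summarize_processes(all_hs)$percent,
               c(100, 0, 0, 0, 0))
  # within-group restriction
  g <- c(a = "g1", b = "g1", c = "g2")
  s2 <- summarize_processes(df, groups = g)
  expect_equal(attr(s2, "n_pairs"), 1)
})

test_that("the full two-step driver only computes RC where selection fails", {
  set.seed(34)
  tree <- simulate_phylogeny(30, seed = 35)
  m <- t(rmultinom(6, 400, runif(30)))
  tab <- make_counts(m, taxa = tree$tip.label)
  pr <- assembly_processes(tab, tree, n_null = 99, seed = 3)
  expect_equal(nrow(pr), choose(6, 2))
  sel <- !is.na(pr$bnti) & abs(pr$bnti) > 2
  expect_true(all(is.na(pr$rc_bray[sel])))
  expect_true(all(!is.na(pr$rc_bray[!sel & !is.na(pr$bnti)])))
  expect_identical(pr$process,
                   unname(classify_processes(pr$bnti, pr$rc_bray)))
})
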