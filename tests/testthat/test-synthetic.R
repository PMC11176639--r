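test_that("simulated phylogenies are ultrametric Yule trees with labeled tips", {
  tr <- simulate_phylogeny(2, seed = 1)
  D <- ape::cophenetic.phylo(tr)
  depth <- max(ape::node.depth.edgelength(tr))
  expect_equal(unname(D["T0001", "T0002"]), 2 * depth, tolerance = 1e-9)
  tr2 <- simulate_phylogeny(40, seed = 2)
  expect_equal(ape::Ntip(tr2), 40)
  expect_true(ape::is.ultrametric(tr2, tol = 1e-6))
  expect_identical(tr2$tip.label[1], "T0001")
  # determinism
  expect_equal(simulate_phylogeny(10, seed = 9)$edge.length,
               simulate_phylogeny(10, seed = 9)$edge.length)
})

test_that("Brownian traits follow the tree's covariance structure", {
  tr <- simulate_phylogeny(24, seed = 3)
  expect_equal(unname(evolve_trait(tr, sigma_bm = 0, root_value = 1.5,
                                   seed = 1)),
               rep(1.5, 24))
  # sister tips more similar than distant tips, on average
  D <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
  close_pair <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  far_pair <- which(D == max(D), arr.ind = TRUE)[1, ]
  d_close <- d_far <- numeric(300)
  for (r in 1:300) {
    x <- evolve_trait(tr, 1, 0, seed = 1000 + r)
    d_close[r] <- (x[close_pair[1]] - x[close_pair[2]])^2
    d_far[r] <- (x[far_pair[1]] - x[far_pair[2]])^2
  }
  expect_lt(mean(d_close), mean(d_far))
  # expected squared difference = sigma^2 * patristic distance
  expect_equal(mean(d_far), D[far_pair[1], far_pair[2]],
               tolerance = 0.25 * D[far_pair[1], far_pair[2]])
})

test_that("scenario datasets are internally aligned with planted structure", {
  cfg <- scenario_config("homogeneous_selection", n_samples = 24,
                         n_taxa = 120, seed = 2)
  ds <- assemble_communities(cfg)
  # align_inputs leaves a generated dataset unchanged
  al <- align_inputs(ds$table, ds$tree, ds$frame)
  expect_equal(dim(al$table), dim(ds$table))
  expect_identical(al$frame$sample_id, ds$frame$sample_id)
  # plots tile the strip with the 3/3/2 type layout
  expect_equal(sort(unique(ds$frame$plot_id)), 1:8)
  tt <- table(unique(ds$frame[c("plot_id", "plot_type")])$plot_type)
  expect_equal(as.vector(tt[c("grass", "mixed", "monoculture")]),
               c(2, 3, 3))
  expect_true(all(ds$frame$x >= 0 & ds$frame$x <= 272))
  expect_true(all(ds$frame$y >= 0 & ds$frame$y <= 30))
  # exactly n_shallow samples below 1000 reads
  expect_equal(sum(rowSums(ds$table) < 1000), cfg$n_shallow)
  expect_identical(ds$truth$shallow,
                   ds$frame$sample_id[rowSums(ds$table) < 1000])
})

test_that("degenerate selection keeps only the best-matching taxon", {
  cfg <- scenario_config("homogeneous_selection", n_samples = 8,
                         n_taxa = 60, sigma_sel = 1e-6, imm_floor = 0,
                         p_col = 1, drift_jitter = 0, n_shallow = 0,
                         seed = 4)
  ds <- assemble_communities(cfg)
  rich <- rowSums(ds$table > 0)
  expect_true(all(rich == 1))
  expect_equal(length(unique(apply(ds$table, 1, which.max))), 1)
})

test_that("infinite dispersal decay removes the distance-decay signal", {
  near <- assemble_communities(scenario_config("dispersal_limitation",
                                               n_samples = 20, n_taxa = 80,
                                               lambda = 10, n_shallow = 0,
                                               seed = 5))
  flat <- assemble_communities(scenario_config("dispersal_limitation",
                                               n_samples = 20, n_taxa = 80,
                                               lambda = 1e9, n_shallow = 0,
                                               seed = 5))
  geo <- function(ds) dist(ds$frame[, c("x", "y")])
  r_near <- mantel_test(bray_curtis(ds <- near$table), geo(near),
                        n_perm = 99, seed = 1)$r
  r_flat <- mantel_test(bray_curtis(flat$table), geo(flat),
                        n_perm = 99, seed = 1)$r
  expect_gt(r_near, 0.3)
  expect_lt(abs(r_flat), 0.2)
})

test_that("the planted collinear chemistry block prunes to the nine bases", {
  ds <- assemble_communities(scenario_config("drift", n_samples = 64,
                                             seed = 1))
  chem <- as.matrix(ds$frame[, attr(ds$frame, "chem_vars")])
  expect_equal(ncol(chem), 16)
  pr <- prune_collinear(chem, 0.65)
  expect_length(pr$kept, 9)
  expect_setequal(pr$dropped, ds$truth$nuisance_chem)
})

test_that("functional tables carry a complete category map and planted effects", {
  sim <- simulate_functional_table(n_categories = 100, n_samples = 12,
                                   effect_size = 4, enriched_per_group = 8,
                                   seed = 6)
  expect_setequal(sim$category_map$feature, colnames(sim$table))
  expect_equal(length(sim$enriched$monoculture), 8)
  rel <- to_relative(sim$table)
  enr <- sim$enriched$monoculture
  in_mono <- colMeans(unclass(rel)[sim$groups == "monoculture", enr])
  in_mix <- colMeans(unclass(rel)[sim$groups == "mixed", enr])
  expect_gt(mean(in_mono / in_mix), 2)
})
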