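#' Simulate a Yule phylogeny
#'
#' Pure-birth tree with unit speciation rate, ultrametric, tips labeled
#' `T0001...`.
#'
#' @param n_taxa number of tips, `>= 2`.
#' @param seed integer seed.
#' @return an [ape::phylo].
#' @export
simulate_phylogeny <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 2)
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- sprintf("T%04d", seq_len(n_taxa))
  tree
}

#' Evolve a continuous trait by Brownian motion
#'
#' Gaussian increments with variance `sigma_bm^2 * branch length` along
#' every branch, so tip covariances equal `sigma_bm^2` times shared path
#' length; this is the niche axis that gives the phylogenetic null model
#' a signal to detect.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param sigma_bm Brownian rate (per square-root unit branch length).
#' @param root_value trait value at the root (default 0).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, sigma_bm = 1, root_value = 0, seed = NULL) {
  with_seed(seed,
    ape::rTraitCont(tree, model = "BM", sigma = sigma_bm,
                    root.value = root_value))
}

#' Scenario configuration for the metacommunity simulator
#'
#' Defaults emulate the structure of a ~60-sample survey of a 272 m x 30 m
#' planted riparian strip: 8 plots (3 monoculture, 3 mixed, 2 grass),
#' lognormal sequencing depths around 20,000 reads with a few shallow
#' samples planted below 1000 reads, thousands-fold abundance variation in
#' a lognormal regional pool, and spatially autocorrelated soil
#' chemistry. The homogenizing-dispersal scenario uses moderate depths
#' (around 2000 reads) so taxon occupancy is sporadic rather than
#' saturated; see the vignette for why that matters.
#'
#' @param scenario one of `"homogeneous_selection"`,
#'   `"heterogeneous_selection"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`, `"drift"`.
#' @param n_taxa,n_samples community dimensions (`n_samples >= 4`).
#'   `n_taxa` defaults to 1000 for the two selection scenarios -- the
#'   nearest-taxon null needs a phylogenetically rich pool relative to
#'   per-sample richness to have contrast -- and to 300 otherwise, where
#'   the signature is depth-driven and a smaller pool keeps the
#'   individual-based null affordable.
#' @param depth_meanlog,depth_sdlog lognormal depth parameters; scenario
#'   defaults are log(20000)/0.5 for the dispersal-limitation and drift
#'   scenarios, log(5000)/0.3 for the two selection scenarios and
#'   log(2000)/0.3 for homogenizing dispersal, so that taxon occupancy is
#'   sporadic rather than saturated, as in real amplicon surveys.
#' @param n_shallow samples planted with depth below 1000 reads to
#'   exercise depth filtering.
#' @param sigma_sel selection width on the z-scored trait axis (smaller =
#'   stronger filtering).
#' @param env_contrast trait optimum magnitude (z-trait units): the
#'   homogeneous-selection optimum is `+env_contrast`, and the
#'   heterogeneous-selection scenario uses `-env_contrast` and
#'   `+env_contrast` on the two halves of the strip. Placed in the trait
#'   tail because extreme trait values are phylogenetically clustered
#'   under Brownian evolution, as environmental tolerances are on real
#'   phylogenies.
#' @param imm_floor weak flat immigration floor added to the selection
#'   kernel; keeps phylogenetically scattered taxa flickering through the
#'   observed regional pool at trace abundance.
#' @param p_col colonization-lottery probability: in the selection
#'   scenarios each taxon independently colonizes each site with this
#'   probability, the local-drift component that generates compositional
#'   turnover among the selected taxa.
#' @param drift_jitter lognormal sd of per-site abundance jitter in the
#'   selection scenarios.
#' @param lambda dispersal decay length in meters.
#' @param sigma_bm Brownian trait rate.
#' @param extent landscape width and height in meters.
#' @param pool_sdlog lognormal sd of regional-pool abundances.
#' @param core_pool_size,peri_pool_size,n_peripheral homogenizing-dispersal
#'   controls: size of the shared realized pool draw, size of each
#'   peripheral site's independent draw, and number of peripheral sites
#'   (default `round(n_samples / 8)`).
#' @param seed integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("homogeneous_selection",
                                         "heterogeneous_selection",
                                         "dispersal_limitation",
                                         "homogenizing_dispersal",
                                         "drift"),
                            n_taxa = NULL, n_samples = 64,
                            depth_meanlog = NULL, depth_sdlog = NULL,
                            n_shallow = 3,
                            sigma_sel = 0.4, env_contrast = 1.5,
                            imm_floor = 0.002, p_col = 0.6,
                            drift_jitter = 0.5,
                            lambda = 30, sigma_bm = 1,
                            extent = c(272, 30), pool_sdlog = 1,
                            core_pool_size = 1500, peri_pool_size = 400,
                            n_peripheral = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(n_taxa))
    n_taxa <- if (scenario %in% c("homogeneous_selection",
                                  "heterogeneous_selection")) 1000L else 300L
  if (is.null(depth_meanlog))
    depth_meanlog <- switch(scenario,
      homogenizing_dispersal = log(2000),
      homogeneous_selection = ,
      heterogeneous_selection = log(5000),
      log(20000))
  if (is.null(depth_sdlog))
    depth_sdlog <- if (scenario %in% c("dispersal_limitation", "drift"))
      0.5 else 0.3
  if (is.null(n_peripheral)) n_peripheral <- max(2L, round(n_samples / 8))
  stopifnot(n_samples >= 4, n_taxa >= 2, sigma_sel > 0, lambda > 0,
            sigma_bm >= 0, all(extent > 0), pool_sdlog > 0,
            n_shallow >= 0, n_shallow < n_samples, imm_floor >= 0,
            p_col > 0, p_col <= 1, drift_jitter >= 0)
  structure(as.list(environment()), class = "scenario_config")
}

# Spatially autocorrelated standard-normal field over coordinates
smooth_field <- function(xy, range = 50) {
  W <- exp(-as.matrix(dist(xy))^2 / (2 * range^2))
  f <- W %*% rnorm(nrow(xy))
  as.vector(scale(f))
}

# 16 soil-chemistry variables: 9 base variables (some tracking the
# selection environment or coordinates, the rest spatially autocorrelated
# or plain noise) plus 7 derived variables, one child per parent, each
# loading ~0.8 on its base parent and ~0.4 on two shared nitrogen
# variables. The nitrogen secondaries are residualized in-sample against
# the seven parents so the greedy |r| > 0.65 pruning margin (children
# carry the secondary correlations, parents do not) is deterministic
# rather than at the mercy of sampling correlations, and the pruned set
# is exactly the nine base variables.
simulate_chemistry <- function(xy, env) {
  n <- nrow(xy)
  zs <- function(v) if (sd(v) == 0) rnorm(n) else as.vector(scale(v))
  # noise components orthonormalized in-sample: base-variable
  # correlations then reflect only the planted structure (environment,
  # coordinates, smooth fields), not sampling accidents
  # with very few samples the 9 noise vectors cannot be orthogonalized;
  # fall back to plain noise (the pruning guarantee targets full-size
  # surveys)
  E <- if (n > 16) apply(qr.Q(qr(matrix(rnorm(n * 9), n, 9))), 2, zs)
  else matrix(rnorm(n * 9), n, 9)
  # smooth fields keep their within-field spatial autocorrelation but are
  # residualized against the design variables and each other, again so
  # that only planted structure drives between-variable correlation
  design <- cbind(zs(env), zs(xy[, 1]), zs(xy[, 2]))
  sm <- matrix(0, n, 3)
  for (k in 1:3) {
    f <- smooth_field(xy)
    f <- stats::lm.fit(cbind(1, design, sm[, seq_len(k - 1),
                                           drop = FALSE]), f)$residuals
    sm[, k] <- zs(f)
  }
  base <- list(
    pH             = 0.8 * zs(env) + 0.6 * E[, 1],
    water_content  = 0.6 * zs(xy[, 2]) + 0.8 * E[, 2],
    sulphate_S     = 0.5 * zs(xy[, 1]) + 0.87 * E[, 3],
    exchangeable_K = 0.45 * sm[, 1] + 0.89 * E[, 4],
    olsen_P        = 0.45 * sm[, 2] + 0.89 * E[, 5],
    total_C        = 0.45 * sm[, 3] + 0.89 * E[, 6],
    CEC            = E[, 7],
    nitrate_N      = E[, 8],
    ammonium_N     = E[, 9])
  base <- lapply(base, zs)
  parents <- c("pH", "water_content", "sulphate_S", "exchangeable_K",
               "olsen_P", "total_C", "CEC")
  P <- do.call(cbind, base[parents])
  resid_z <- function(v) {
    r <- stats::lm.fit(cbind(1, P), v)$residuals
    zs(r)
  }
  s1 <- resid_z(base$nitrate_N)
  s2 <- resid_z(base$ammonium_N)
  s2 <- zs(s2 - s1 * sum(s1 * s2) / sum(s1^2))
  # the table's nitrogen columns are the residualized vectors themselves,
  # so their in-sample correlation with every parent is exactly zero
  base$nitrate_N <- s1
  base$ammonium_N <- s2
  child <- function(parent)
    0.9 * base[[parent]] + 0.3 * s1 + 0.3 * s2 + 0.03 * rnorm(n)
  derived <- list(
    base_saturation   = child("pH"),
    moisture_capacity = child("water_content"),
    EC                = child("sulphate_S"),
    calcium           = child("exchangeable_K"),
    total_P           = child("olsen_P"),
    organic_matter    = child("total_C"),
    magnesium         = child("CEC"))
  chem <- do.call(cbind, c(base, derived))
  # realistic units (affine; correlations untouched)
  shifts <- c(pH = 5.8, water_content = 35, sulphate_S = 12,
              exchangeable_K = 0.6, olsen_P = 28, nitrate_N = 14,
              ammonium_N = 9, total_C = 4.2, CEC = 18,
              base_saturation = 62, moisture_capacity = 48, EC = 0.15,
              calcium = 7.4, total_P = 720, organic_matter = 7.5,
              magnesium = 1.9)
  scales <- c(pH = 0.4, water_content = 6, sulphate_S = 4,
              exchangeable_K = 0.2, olsen_P = 9, nitrate_N = 5,
              ammonium_N = 3, total_C = 1.1, CEC = 4,
              base_saturation = 9, moisture_capacity = 8, EC = 0.05,
              calcium = 2.2, total_P = 160, organic_matter = 1.9,
              magnesium = 0.6)
  sweep(sweep(chem, 2, scales[colnames(chem)], "*"), 2,
        shifts[colnames(chem)], "+")
}

#' Assemble a synthetic metacommunity under a known process
#'
#' Generates a phylogeny with a Brownian niche trait, a lognormal regional
#' pool, a spatial layout of 8 plots on the landscape strip, per-sample
#' taxon-sampling weights determined by the scenario, multinomial counts
#' at lognormal depths (with a few planted shallow samples), and a
#' 16-variable soil-chemistry block of which 7 variables are collinear
#' with the other 9.
#'
#' Scenario mechanisms: *homogeneous_selection* filters all sites toward
#' one trait optimum (`exp(-(trait - E)^2 / 2 sigma_sel^2)` weights);
#' *heterogeneous_selection* applies two contrasting optima (+/-
#' `env_contrast`) to the two halves of the strip;
#' *dispersal_limitation* gives each taxon a home coordinate and decays
#' its weight as `exp(-distance / lambda)` with no trait selection;
#' *homogenizing_dispersal* draws a connected "core" of sites from one
#' shared realized pool draw (mass effects) while `n_peripheral` sites
#' carry independent realized draws, providing the regional heterogeneity
#' against which homogenization is detectable; *drift* samples every site
#' independently from the pool.
#'
#' @param config a [scenario_config()].
#' @return list of class `synthetic_dataset`: `table` (counts
#'   [comm_table()]), `tree`, `frame` (sample metadata with chemistry),
#'   `truth` (scenario, parameters, per-sample environment, peripheral
#'   sample ids, taxon home coordinates).
#' @export
assemble_communities <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  tree <- simulate_phylogeny(cf$n_taxa, seed = cf$seed)
  trait <- evolve_trait(tree, cf$sigma_bm, 0, seed = cf$seed + 1)
  out <- with_seed(cf$seed + 2, {
    zt <- as.vector(scale(trait))
    pool <- rlnorm(cf$n_taxa, 0, cf$pool_sdlog)
    pool <- pool / sum(pool)

    plot_x <- (seq_len(8) - 0.5) * cf$extent[1] / 8
    plot_type <- c("grass", "monoculture", "mixed", "monoculture",
                   "mixed", "monoculture", "mixed", "grass")
    plot_of <- rep_len(seq_len(8), cf$n_samples)
    x <- plot_x[plot_of] + runif(cf$n_samples, -cf$extent[1] / 16,
                                 cf$extent[1] / 16)
    y <- runif(cf$n_samples, 0, cf$extent[2])
    xy <- cbind(x = x, y = y)

    env <- switch(cf$scenario,
      homogeneous_selection = rep(cf$env_contrast, cf$n_samples),
      heterogeneous_selection =
        cf$env_contrast * ifelse(x < cf$extent[1] / 2, -1, 1),
      rep(0, cf$n_samples))

    peripheral <- integer(0)
    homes <- NULL
    if (cf$scenario == "dispersal_limitation")
      homes <- cbind(runif(cf$n_taxa, 0, cf$extent[1]),
                     runif(cf$n_taxa, 0, cf$extent[2]))
    if (cf$scenario == "homogenizing_dispersal") {
      peripheral <- sort(sample.int(cf$n_samples, cf$n_peripheral))
      q_core <- as.vector(rmultinom(1, cf$core_pool_size, pool))
      q_core <- q_core / sum(q_core)
    }

    weights <- function(s) {
      w <- switch(cf$scenario,
        homogeneous_selection = ,
        heterogeneous_selection = {
          lw <- -(zt - env[s])^2 / (2 * cf$sigma_sel^2)
          sel <- exp(lw - max(lw))
          w0 <- pool * ((1 - cf$imm_floor) * sel + cf$imm_floor) *
            rbinom(cf$n_taxa, 1, cf$p_col) *
            exp(rnorm(cf$n_taxa, 0, cf$drift_jitter))
          if (sum(w0) == 0) pool * sel else w0
        },
        dispersal_limitation = {
          d <- sqrt((homes[, 1] - x[s])^2 + (homes[, 2] - y[s])^2)
          pool * exp(-d / cf$lambda)
        },
        homogenizing_dispersal = {
          if (s %in% peripheral) {
            q <- as.vector(rmultinom(1, cf$peri_pool_size, pool))
            q / sum(q)
          } else q_core
        },
        drift = pool)
      w / sum(w)
    }

    depths <- round(rlnorm(cf$n_samples, cf$depth_meanlog, cf$depth_sdlog))
    shallow <- if (cf$n_shallow > 0)
      sort(sample.int(cf$n_samples, cf$n_shallow)) else integer(0)
    depths[shallow] <- sample(400:900, length(shallow), replace = TRUE)

    counts <- if (cf$scenario == "drift") {
      # neutral assembly by the two-step lottery the undominated class is
      # defined against: a pilot multinomial realization of every sample
      # fixes richness, totals and the occurrence/abundance weights, and
      # the final communities are drawn from that lottery
      pilot <- t(vapply(seq_len(cf$n_samples),
                        function(s) as.vector(rmultinom(1, depths[s],
                                                        pool)),
                        numeric(cf$n_taxa)))
      occ0 <- colSums(pilot > 0)
      ab0 <- colSums(pilot / rowSums(pilot))
      t(vapply(seq_len(cf$n_samples), function(s)
        rc_null_community(occ0, ab0, sum(pilot[s, ] > 0), depths[s]),
        numeric(cf$n_taxa)))
    } else {
      t(vapply(seq_len(cf$n_samples),
               function(s) as.vector(rmultinom(1, depths[s], weights(s))),
               numeric(cf$n_taxa)))
    }
    sample_ids <- sprintf("S%02d", seq_len(cf$n_samples))
    dimnames(counts) <- list(sample_ids, tree$tip.label)

    chem <- simulate_chemistry(xy, env)
    frame <- data.frame(sample_id = sample_ids, plot_id = plot_of,
                        plot_type = plot_type[plot_of],
                        host_species = ifelse(plot_type[plot_of] == "grass",
                                              "none", "L_scoparium"),
                        x = x, y = y, chem,
                        stringsAsFactors = FALSE)
    attr(frame, "chem_vars") <- colnames(chem)
    list(table = comm_table(counts, "counts"), frame = frame,
         truth = list(scenario = cf$scenario, config = cf, env = env,
                      peripheral = sample_ids[peripheral],
                      shallow = sample_ids[shallow],
                      homes = homes,
                      nuisance_chem = c("base_saturation",
                                        "moisture_capacity", "EC",
                                        "calcium", "total_P",
                                        "organic_matter", "magnesium")))
  })
  structure(c(out, list(tree = tree)), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic metacommunity: %s, %d samples x %d taxa\n",
              x$truth$scenario, nrow(x$table), ncol(x$table)))
  invisible(x)
}

#' Simulate a functional-category table with planted group indicators
#'
#' Dirichlet-multinomial counts over functional categories for two groups
#' of samples (monoculture vs mixed); `enriched_per_group` categories per
#' group have their expected relative abundance multiplied by
#' `effect_size` in that group. Enriched categories are planted among
#' intermediate-abundance ranks so that they are neither trivially
#' dominant nor starved of counts. `effect_size = 1` yields a null table
#' with no true indicators. Each category also carries a coarse top-level
#' label, mimicking hierarchical functional annotations.
#'
#' @param n_categories number of functional categories (default 400).
#' @param n_level1 number of top-level categories (default 6).
#' @param enriched_per_group categories enriched in each group.
#' @param effect_size multiplicative enrichment (1 = none).
#' @param n_samples total samples, split evenly between groups.
#' @param depth reads per sample.
#' @param concentration Dirichlet concentration (larger = less
#'   overdispersion; the default keeps between-sample proportion CVs
#'   below 1 for mid-abundance categories, as in deeply sequenced
#'   functional profiles).
#' @param seed integer seed.
#' @return list: `table` (counts [comm_table()]), `groups` (factor),
#'   `category_map` (feature -> top-level category), `enriched` (list of
#'   truly enriched features per group).
#' @export
simulate_functional_table <- function(n_categories = 400, n_level1 = 6,
                                      enriched_per_group = 30,
                                      effect_size = 3, n_samples = 30,
                                      depth = 1e5, concentration = 1000,
                                      seed = 1) {
  stopifnot(2 * enriched_per_group <= n_categories, n_samples >= 4)
  with_seed(seed, {
    base <- rlnorm(n_categories, 0, 1)
    base <- base / sum(base)
    feats <- sprintf("K%04d", seq_len(n_categories))
    lev1 <- paste0("L1_", sample.int(n_level1, n_categories,
                                     replace = TRUE))
    ord <- order(base, decreasing = TRUE)
    lo <- if (n_categories >= 100) 26L else 1L
    hi <- min(n_categories, lo + 8 * enriched_per_group - 1)
    mid <- ord[lo:hi]
    if (length(mid) < 2 * enriched_per_group) mid <- ord
    planted <- sample(mid, 2 * enriched_per_group)
    enr <- list(monoculture = feats[planted[seq_len(enriched_per_group)]],
                mixed = feats[planted[-seq_len(enriched_per_group)]])
    groups <- factor(rep(c("monoculture", "mixed"),
                         length.out = n_samples))
    p_group <- function(g) {
      p <- base
      p[match(enr[[g]], feats)] <- p[match(enr[[g]], feats)] * effect_size
      p / sum(p)
    }
    counts <- t(vapply(as.character(groups), function(g) {
      alpha <- p_group(g) * concentration
      p <- rgamma(n_categories, alpha)
      as.vector(rmultinom(1, depth, p / sum(p)))
    }, numeric(n_categories)))
    dimnames(counts) <- list(sprintf("F%02d", seq_len(n_samples)), feats)
    list(table = comm_table(counts, "counts"), groups = groups,
         category_map = data.frame(feature = feats, category = lev1,
                                   stringsAsFactors = FALSE),
         enriched = enr)
  })
}
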