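#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For samples j and k,
#' `betaMNTD(j,k) = 0.5 * [ sum_{i in j} f_ij min_{i' in k} d(i,i')
#'                        + sum_{i in k} f_ik min_{i' in j} d(i,i') ]`
#' where `f` is within-sample relative abundance (or `1/richness` when
#' `abundance_weighted = FALSE`) and `d` is patristic distance. A taxon
#' present in both samples has nearest-neighbor distance 0 (itself), so
#' identical communities score 0.
#'
#' @param table a [comm_table()]; converted to relative abundances
#'   internally. Every taxon must be a tip of `tree`.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param abundance_weighted weight taxa by relative abundance (default
#'   `TRUE`).
#' @return symmetric n x n matrix of betaMNTD values with sample dimnames.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  prep <- bmntd_prep(table, tree, abundance_weighted)
  res <- .bmntd_engine(prep$D, prep$W,
                       matrix(integer(0), 0, ncol(prep$D)))
  structure(res$obs, dimnames = list(rownames(table), rownames(table)))
}

# Shared setup: patristic distances in table column order, weight matrix.
bmntd_prep <- function(table, tree, abundance_weighted) {
  taxa <- colnames(table)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from phylogeny: ",
         paste(head(missing, 5), collapse = ", "))
  if (length(setdiff(tree$tip.label, taxa)) > 0)
    tree <- ape::keep.tip(tree, taxa)
  D <- ape::cophenetic.phylo(tree)[taxa, taxa]
  m <- if (inherits(table, "comm_table"))
    as_comm_matrix(to_relative(table)) else {
      mm <- as.matrix(table)
      mm / rowSums(mm)
    }
  W <- if (abundance_weighted) m else {
    pres <- m > 0
    pres / rowSums(pres)
  }
  list(D = D, W = W)
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of observed betaMNTD against a null in which the phylogeny's
#' tip labels are shuffled uniformly at random across all taxa in the
#' table. One shuffle per null replicate is shared across all sample pairs
#' (statistically equivalent to per-pair shuffles and n-pairs-fold
#' cheaper). `betaNTI = (obs - mean_null) / sd_null` with the sample
#' standard deviation over replicates. Pairs whose null distribution is
#' degenerate (`sd_null` below `tol`) get `NA` and are counted in
#' `n_undefined`.
#'
#' @inheritParams beta_mntd
#' @param n_null number of null replicates (default 999).
#' @param seed integer seed for the shuffles (ignored when `permutations`
#'   is supplied).
#' @param permutations optional integer matrix (`n_null` x n_taxa) of
#'   explicit taxon-to-tip assignments (1-based), e.g. the full
#'   enumeration for exhaustive testing.
#' @param tol degeneracy tolerance on `sd_null` (default 1e-12).
#' @return list with matrices `bnti`, `obs`, `null_mean`, `null_sd`, and
#'   scalar `n_undefined` (degenerate pairs among the n(n-1)/2).
#' @export
bnti <- function(table, tree, n_null = 999, abundance_weighted = TRUE,
                 seed = NULL, permutations = NULL, tol = 1e-12) {
  prep <- bmntd_prep(table, tree, abundance_weighted)
  t_n <- ncol(prep$D)
  if (is.null(permutations)) {
    permutations <- with_seed(seed,
      t(replicate(n_null, sample.int(t_n))))
  }
  storage.mode(permutations) <- "integer"
  res <- .bmntd_engine(prep$D, prep$W, permutations - 1L)
  z <- (res$obs - res$mean) / res$sd
  z[res$sd < tol] <- NA_real_
  diag(z) <- NA_real_
  dn <- list(rownames(table), rownames(table))
  n_undef <- sum(is.na(z[upper.tri(z)]))
  list(bnti = structure(z, dimnames = dn),
       obs = structure(res$obs, dimnames = dn),
       null_mean = structure(res$mean, dimnames = dn),
       null_sd = structure(res$sd, dimnames = dn),
       n_undefined = n_undef)
}

# Draw one null community: pick `richness` taxa without replacement with
# probability proportional to occurrence frequency, then distribute `total`
# individuals over the drawn taxa with probability proportional to the
# regional relative-abundance weights renormalized over the drawn set.
# Returns a full-length count vector.
rc_null_community <- function(occ_w, ab_w, richness, total) {
  t_n <- length(occ_w)
  if (richness > sum(occ_w > 0))
    stop("sample richness exceeds regional pool size")
  # successive weighted sampling without replacement via exponential keys
  # (Efraimidis-Spirakis); distributionally identical to sample(prob = w)
  idx <- order(stats::rexp(t_n) / occ_w)[seq_len(richness)]
  x <- numeric(t_n)
  # every drawn taxon receives one individual so the null community's
  # realized richness equals the observed richness; the remaining reads
  # are distributed by regional relative abundance
  x[idx] <- 1 + rmultinom(1, max(0, total - richness), ab_w[idx])
  x
}

bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Raup-Crick metric on Bray-Curtis dissimilarity (RCBray)
#'
#' For each sample pair, `n_null` null community pairs are assembled from
#' the regional pool defined by the whole table: each null community draws
#' the sample's observed richness of taxa without replacement with
#' probability proportional to occurrence frequency across samples, then
#' distributes the sample's observed total count over the drawn taxa with
#' probability proportional to the taxa's summed relative abundance. With
#' `obs` the observed Bray-Curtis dissimilarity,
#' `RCBray = 2 * [(#(null < obs) + 0.5 #(null = obs)) / n_null] - 1`,
#' ties judged within `tol`. Values near +1 mean the pair is more
#' dissimilar than the stochastic expectation (dispersal limitation acting
#' with drift); near -1, less dissimilar (homogenizing dispersal).
#'
#' @param table an integer-count [comm_table()] (`counts` or `rarefied`;
#'   rarefied recommended so totals are even).
#' @param n_null null replicates per pair (default 999).
#' @param seed integer seed.
#' @param pairs optional 2-column matrix of sample-index pairs to compute
#'   (default: all pairs).
#' @param pool optional integer-count table defining the regional pool
#'   from which the occurrence and abundance weights are derived; by
#'   default the input table itself (its columns must match `table`'s).
#' @param tol equality tolerance on Bray-Curtis values (default 1e-12).
#' @return symmetric n x n matrix of RCBray values (NA off the requested
#'   pairs and on the diagonal).
#' @export
rc_bray <- function(table, n_null = 999, seed = NULL, pairs = NULL,
                    pool = NULL, tol = 1e-12) {
  stopifnot(tab_kind(table) %in% c("counts", "rarefied"))
  m <- as_comm_matrix(table)
  if (any(rowSums(m) == 0)) stop("zero-sum sample")
  n <- nrow(m)
  pm <- if (is.null(pool)) m else {
    p <- if (inherits(pool, "comm_table")) as_comm_matrix(pool) else
      as.matrix(pool)
    if (!identical(colnames(p), colnames(m)))
      stop("pool taxa must match the table's taxa")
    p
  }
  occ_w <- colSums(pm > 0)
  ab_w <- colSums(pm / rowSums(pm))
  rich <- rowSums(m > 0)
  tot <- round(rowSums(m))
  if (is.null(pairs)) pairs <- t(combn(n, 2))
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  with_seed(seed, {
    for (p in seq_len(nrow(pairs))) {
      j <- pairs[p, 1]; k <- pairs[p, 2]
      obs <- bc_pair(m[j, ], m[k, ])
      lower <- 0; equal <- 0
      for (r in seq_len(n_null)) {
        bc <- bc_pair(rc_null_community(occ_w, ab_w, rich[j], tot[j]),
                      rc_null_community(occ_w, ab_w, rich[k], tot[k]))
        if (bc < obs - tol) lower <- lower + 1
        else if (bc <= obs + tol) equal <- equal + 1
      }
      out[j, k] <- out[k, j] <- 2 * ((lower + 0.5 * equal) / n_null) - 1
    }
  })
  out
}

#' Classify pairwise assembly processes
#'
#' Two-step rule: `betaNTI < -threshold` is homogeneous selection and
#' `betaNTI > +threshold` heterogeneous selection; otherwise
#' `RC > +rc_threshold` is dispersal limitation, `RC < -rc_threshold`
#' homogenizing dispersal, and anything else undominated. Thresholds are
#' strict inequalities (default 2 and 0.95), so boundary values fall
#' through to the non-significant branch. `NA` betaNTI yields `NA`.
#'
#' @param bnti numeric vector/matrix of betaNTI values.
#' @param rc matching RCBray values (may be `NA` where `|bnti|` exceeds
#'   the threshold, since they are not needed there).
#' @param bnti_threshold selection threshold (default 2).
#' @param rc_threshold dispersal threshold (default 0.95).
#' @return character vector/matrix of process labels among
#'   `"homogeneous_selection"`, `"heterogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`,
#'   `"undominated"`.
#' @export
classify_processes <- function(bnti, rc, bnti_threshold = 2,
                               rc_threshold = 0.95) {
  out <- rep(NA_character_, length(bnti))
  sel_lo <- !is.na(bnti) & bnti < -bnti_threshold
  sel_hi <- !is.na(bnti) & bnti > bnti_threshold
  out[sel_lo] <- "homogeneous_selection"
  out[sel_hi] <- "heterogeneous_selection"
  rest <- !is.na(bnti) & !sel_lo & !sel_hi
  if (any(rest & is.na(rc)))
    stop("RCBray required for pairs with |betaNTI| <= threshold")
  out[rest & rc > rc_threshold] <- "dispersal_limitation"
  out[rest & rc < -rc_threshold] <- "homogenizing_dispersal"
  out[rest & abs(rc) <= rc_threshold] <- "undominated"
  if (is.matrix(bnti)) out <- matrix(out, nrow(bnti), ncol(bnti),
                                     dimnames = dimnames(bnti))
  out
}

#' Full pairwise assembly-process analysis
#'
#' Runs the two-step null model end to end: betaNTI for every sample pair
#' (relative abundances), then RCBray (integer counts) only for the pairs
#' the selection step leaves unresolved, then classification.
#'
#' @param table integer-count [comm_table()] (rarefied counts
#'   recommended; relative abundances for betaMNTD are derived from it).
#' @param tree rooted [ape::phylo] covering the table's taxa.
#' @param n_null null replicates for both nulls (default 999).
#' @param seed integer seed (the two nulls use `seed` and `seed + 1`).
#' @param abundance_weighted betaMNTD weighting (default `TRUE`).
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return data.frame of class `assembly_pairs`, one row per pair:
#'   `sample_i`, `sample_j`, `beta_mntd_obs`, `bnti`, `rc_bray` (NA where
#'   not needed), `process`. Attribute `n_undefined` counts pairs with a
#'   degenerate betaNTI null (excluded from summaries).
#' @export
assembly_processes <- function(table, tree, n_null = 999, seed = NULL,
                               abundance_weighted = TRUE,
                               bnti_threshold = 2, rc_threshold = 0.95) {
  nt <- bnti(table, tree, n_null = n_null, seed = seed,
             abundance_weighted = abundance_weighted)
  n <- nrow(table)
  pr <- t(combn(n, 2))
  z <- nt$bnti[pr]
  need_rc <- which(!is.na(z) & abs(z) <= bnti_threshold)
  rc <- rep(NA_real_, nrow(pr))
  if (length(need_rc) > 0) {
    rcm <- rc_bray(table, n_null = n_null,
                   seed = if (is.null(seed)) NULL else seed + 1,
                   pairs = pr[need_rc, , drop = FALSE])
    rc[need_rc] <- rcm[pr[need_rc, , drop = FALSE]]
  }
  proc <- classify_processes(z, rc, bnti_threshold, rc_threshold)
  out <- data.frame(sample_i = rownames(table)[pr[, 1]],
                    sample_j = rownames(table)[pr[, 2]],
                    beta_mntd_obs = nt$obs[pr],
                    bnti = z, rc_bray = rc, process = proc,
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- nt$n_undefined
  class(out) <- c("assembly_pairs", "data.frame")
  out
}

#' Summarize assembly processes as percentages of pairs
#'
#' @param pairs an `assembly_pairs` data.frame (or any data.frame with a
#'   `process` column).
#' @param groups optional factor of group labels per sample (named by
#'   sample id); when given, only within-group pairs are summarized.
#' @return data.frame with one row per process (all five always present),
#'   columns `process`, `n`, `percent`; attributes `n_pairs` (classified
#'   pairs in the denominator) and `n_undefined`.
#' @export
summarize_processes <- function(pairs, groups = NULL) {
  procs <- c("homogeneous_selection", "heterogeneous_selection",
             "dispersal_limitation", "homogenizing_dispersal",
             "undominated")
  df <- pairs
  if (!is.null(groups)) {
    gi <- groups[df$sample_i]; gj <- groups[df$sample_j]
    df <- df[!is.na(gi) & !is.na(gj) & gi == gj, , drop = FALSE]
  }
  lab <- df$process[!is.na(df$process)]
  if (length(lab) == 0) stop("no classified pairs to summarize")
  n <- vapply(procs, function(p) sum(lab == p), numeric(1))
  out <- data.frame(process = procs, n = n,
                    percent = 100 * n / length(lab), row.names = NULL)
  attr(out, "n_pairs") <- length(lab)
  attr(out, "n_undefined") <- sum(is.na(df$process))
  out
}
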