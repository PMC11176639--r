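#' Remove low-depth samples
#'
#' Drops every sample whose total read count is strictly below
#' `min_sample_reads` (default 1000 reads), then drops taxa left with
#' all-zero columns.
#'
#' @param table a counts [comm_table()].
#' @param min_sample_reads minimum total reads to retain a sample.
#' @return filtered counts table.
#' @export
filter_low_depth <- function(table, min_sample_reads = 1000) {
  stopifnot(tab_kind(table) %in% c("counts", "rarefied"))
  keep <- rowSums(table) >= min_sample_reads
  if (!any(keep)) stop("all samples fall below the depth threshold")
  out <- tab_subset(table, which(keep))
  nz <- colSums(out) > 0
  tab_subset(out, j = which(nz))
}

#' Rarefy counts to an even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (a multivariate hypergeometric draw). Samples whose total is
#' already exactly `depth` are returned unchanged; samples below `depth`
#' are dropped with a warning. Each sample uses a seed derived as
#' `seed + sample index` so results never depend on sample order.
#'
#' @param table a counts [comm_table()].
#' @param depth target depth (reads per sample), `>= 1`.
#' @param seed base integer seed.
#' @return rarefied table (`kind = "rarefied"`), every row summing to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(tab_kind(table) == "counts")
  if (depth <= 0) stop("rarefaction depth must be positive")
  tot <- rowSums(table)
  if (any(tot < depth)) {
    warning(sum(tot < depth), " samples shallower than depth; dropped")
    table <- tab_subset(table, which(tot >= depth))
    tot <- rowSums(table)
  }
  m <- as_comm_matrix(table)
  out <- m
  idx_all <- seq_len(ncol(m))
  for (i in seq_len(nrow(m))) {
    if (tot[i] == depth) next
    counts <- as.integer(round(m[i, ]))
    reads <- rep.int(idx_all, counts)
    sub <- with_seed(seed + i, sample(reads, depth))
    out[i, ] <- tabulate(sub, nbins = ncol(m))
  }
  comm_table(out, "rarefied")
}

#' Cumulative sum scaling (CSS) normalization
#'
#' For each sample the scaling factor `s_j` is the sum of its `k` smallest
#' nonzero counts, where `k = max(1, floor(quantile * n_nonzero))`; output
#' values are `count * scale / s_j`. This quantile-index convention makes
#' the factor well defined for heavily tied count distributions (with
#' counts `{1,1,1,1}` and `quantile = 0.5`, `s = 2`). Normalization is
#' invariant to scaling a sample's counts and preserves within-sample rank
#' order.
#'
#' @param table a counts [comm_table()].
#' @param quantile fraction in (0, 1) of the nonzero count distribution to
#'   accumulate (default 0.5).
#' @param scale multiplicative constant for readability (default 1000).
#' @return normalized table (`kind = "css"`).
#' @export
css_normalize <- function(table, quantile = 0.5, scale = 1000) {
  stopifnot(tab_kind(table) == "counts")
  stopifnot(quantile > 0, quantile < 1, scale > 0)
  m <- as_comm_matrix(table)
  s <- apply(m, 1, function(row) {
    nz <- sort(row[row > 0])
    if (length(nz) == 0) return(0)
    k <- max(1L, floor(quantile * length(nz)))
    sum(nz[seq_len(k)])
  })
  if (any(s == 0))
    stop("CSS scaling factor is zero for sample(s): ",
         paste(rownames(m)[s == 0], collapse = ", "))
  comm_table(m * scale / s, "css")
}

#' Convert to relative abundances
#'
#' @param table any [comm_table()] with no all-zero rows.
#' @return table with rows summing to 1 (`kind = "relative"`).
#' @export
to_relative <- function(table) {
  m <- as_comm_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  comm_table(m / rs, "relative")
}

#' Greedy collinearity pruning of covariates
#'
#' While any pair of variables has absolute Pearson correlation strictly
#' above `cutoff`, the worst-offending pair (largest `|r|`) loses one
#' member: the variable with the larger mean `|r|` against all other
#' remaining variables (ties broken lexicographically). This mirrors the
#' common practice of keeping one representative from each block of highly
#' correlated soil variables.
#'
#' @param chemistry numeric matrix or data.frame (samples x variables).
#' @param cutoff `|r|` threshold (default 0.65).
#' @return list with `chemistry` (pruned columns), `kept`, `dropped`, and
#'   `report` (one row per drop: variable, partner, correlation).
#' @export
prune_collinear <- function(chemistry, cutoff = 0.65) {
  m <- as.matrix(chemistry)
  if (!is.numeric(m)) stop("non-numeric chemistry column")
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("need >= 2 variables and >= 3 samples")
  stopifnot(cutoff > 0, cutoff < 1)
  keep <- colnames(m)
  report <- list()
  repeat {
    r <- abs(cor(m[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= cutoff) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- sort(keep[ij])
    others <- setdiff(keep, pair)
    mean_r <- if (length(others) == 0) c(0, 0) else
      rowMeans(r[pair, others, drop = FALSE])
    drop <- if (abs(diff(mean_r)) < 1e-12) pair[2] else
      pair[which.max(mean_r)]
    partner <- setdiff(pair, drop)
    report[[length(report) + 1]] <-
      data.frame(dropped = drop, against = partner,
                 r = cor(m[, drop], m[, partner]))
    keep <- setdiff(keep, drop)
  }
  list(chemistry = m[, keep, drop = FALSE], kept = keep,
       dropped = setdiff(colnames(m), keep),
       report = do.call(rbind, report))
}
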