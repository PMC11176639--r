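#' Indicator value (IndVal) analysis
#'
#' For feature i and group g, specificity
#' `A_ig = mean_g(x_i) / sum_g' mean_g'(x_i)` (group-equalized means, the
#' Dufrene-Legendre definition, so unequal group sizes do not bias A) and
#' fidelity `B_ig` = fraction of g's samples where the feature occurs.
#' `IndVal_i = max_g A_ig B_ig * 100`; significance by permuting group
#' labels and comparing the maximum statistic, with Benjamini-Hochberg
#' adjustment across features. Because A compares mean abundances across
#' groups, inputs must be on a common per-sample scale: a [comm_table()]
#' must have kind `relative` or `css`.
#'
#' @param table [comm_table()] (kind `relative` or `css`) or plain
#'   numeric matrix of normalized abundances (samples x features).
#' @param groups factor/character of group labels, one per sample, >= 2
#'   groups with >= 2 samples each.
#' @param n_perm label permutations (default 999).
#' @param seed integer seed.
#' @param group_equalized use group-equalized A (default `TRUE`); when
#'   `FALSE`, A uses raw sums so large groups weigh more.
#' @param p_adjust adjustment method across features (default `"BH"`,
#'   `"none"` to disable).
#' @return data.frame, one row per feature: `feature`, `group` (best
#'   group), `A`, `B`, `indval` (in [0, 100]), `p`, `p_adj`, sorted by
#'   decreasing indval.
#' @export
indval <- function(table, groups, n_perm = 999, seed = NULL,
                   group_equalized = TRUE, p_adjust = "BH") {
  k <- tab_kind(table)
  if (!is.na(k) && !k %in% c("relative", "css"))
    stop("IndVal requires normalized abundances (kind 'relative' or ",
         "'css'); got '", k, "'")
  m <- if (inherits(table, "comm_table")) as_comm_matrix(table) else
    as.matrix(table)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  if (any(colSums(m) == 0))
    stop("feature(s) absent everywhere: ",
         paste(head(colnames(m)[colSums(m) == 0], 5), collapse = ", "))

  stat_fun <- function(gl) {
    mean_g <- rowsum(m, gl) / as.vector(table(gl))        # groups x feat
    A <- if (group_equalized)
      sweep(mean_g, 2, colSums(mean_g), "/")
    else {
      sums <- rowsum(m, gl)
      sweep(sums, 2, colSums(sums), "/")
    }
    B <- rowsum((m > 0) * 1, gl) / as.vector(table(gl))
    AB <- A * B
    list(stat = apply(AB, 2, max) * 100,
         best = rownames(AB)[apply(AB, 2, which.max)],
         A = A, B = B)
  }
  obs <- stat_fun(g)
  ge <- numeric(ncol(m))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- stat_fun(g[sample.int(length(g))])$stat
      ge <- ge + (s >= obs$stat)
    }
  })
  p <- (ge + 1) / (n_perm + 1)
  best_idx <- cbind(match(obs$best, levels(g)), seq_len(ncol(m)))
  out <- data.frame(feature = colnames(m), group = obs$best,
                    A = obs$A[best_idx], B = obs$B[best_idx],
                    indval = obs$stat, p = p,
                    p_adj = p.adjust(p, p_adjust),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$indval), ]
}

#' Aggregate indicator features by a category mapping
#'
#' Given an IndVal result and a two-column feature-to-category mapping
#' (e.g. fine functional categories to their top-level groups), reports
#' per group of significant indicators the proportion falling in each
#' category.
#'
#' @param result data.frame from [indval()].
#' @param category_map data.frame with columns `feature`, `category`
#'   covering every feature.
#' @param alpha significance cutoff on `p_adj` (default 0.05).
#' @return data.frame: `group`, `category`, `n`, `proportion` (within
#'   group).
#' @export
indicator_by_category <- function(result, category_map, alpha = 0.05) {
  if (!all(result$feature %in% category_map$feature))
    stop("category map does not cover every feature")
  sig <- result[result$p_adj < alpha, , drop = FALSE]
  sig$category <- category_map$category[match(sig$feature,
                                              category_map$feature)]
  if (nrow(sig) == 0)
    return(data.frame(group = character(0), category = character(0),
                      n = integer(0), proportion = numeric(0)))
  tab <- as.data.frame(table(group = sig$group, category = sig$category),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$group, sum)
  tab$proportion <- tab$n / as.vector(tot[tab$group])
  tab
}
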