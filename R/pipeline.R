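#' Pipeline run configuration
#'
#' Bundles inputs and options for [run_pipeline()]. Analyses can be
#' toggled individually; each stage derives its own seed from the global
#' seed and the stage name, so disabling one stage never shifts another
#' stage's random stream.
#'
#' @param table counts [comm_table()].
#' @param tree rooted [ape::phylo].
#' @param frame sample metadata (with `plot_type`, `plot_id`, `x`, `y`
#'   and chemistry columns named by attribute `chem_vars`).
#' @param out_dir output directory (created if absent).
#' @param min_sample_reads depth filter threshold (default 1000).
#' @param rarefaction_depth target depth; `NULL` = minimum retained
#'   sample total.
#' @param css_quantile,css_scale CSS parameters.
#' @param collinearity_cutoff `|r|` threshold for chemistry pruning.
#' @param n_null null replicates for assembly nulls.
#' @param n_perm permutations for the permutation tests.
#' @param assembly_pool `"planted"` (exclude grass samples from the
#'   null-model pool, the default) or `"all"`.
#' @param run_assembly,run_multivar,run_varpart stage toggles.
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(table, tree, frame, out_dir,
                       min_sample_reads = 1000, rarefaction_depth = NULL,
                       css_quantile = 0.5, css_scale = 1000,
                       collinearity_cutoff = 0.65,
                       n_null = 999, n_perm = 999,
                       assembly_pool = c("planted", "all"),
                       run_assembly = TRUE, run_multivar = TRUE,
                       run_varpart = TRUE, seed = 1) {
  assembly_pool <- match.arg(assembly_pool)
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, stage) {
  (seed + sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) * 7919L) %%
    .Machine$integer.max
}

write_tsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes, as toggled: depth filtering, rarefaction, CSS normalization,
#' chemistry pruning, alpha/beta diversity, the two-step assembly null
#' model (on planted-plot samples by default), PERMANOVA (plot type then
#' plot), geographic and environmental distance-decay, Procrustes
#' congruence of the chemistry and community ordinations, and dbMEM
#' environment/space variance partitioning. Results are written as TSV
#' files plus a JSON manifest recording the configuration, seeds and
#' per-stage dimensions; a rerun with an identical configuration is
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("ecoassembly")), seed = cf$seed, stages = list())
  results <- list()

  al <- align_inputs(cf$table, cf$tree, cf$frame)
  filt <- filter_low_depth(al$table, cf$min_sample_reads)
  al <- align_inputs(filt, al$tree, al$frame)
  depth <- cf$rarefaction_depth
  if (is.null(depth)) depth <- min(rowSums(al$table))
  rare <- rarefy(al$table, depth, seed = stage_seed(cf$seed, "rarefy"))
  css <- css_normalize(al$table, cf$css_quantile, cf$css_scale)
  manifest$stages$preprocess <- list(
    samples = nrow(al$table), taxa = ncol(al$table),
    rarefaction_depth = depth,
    min_sample_reads = cf$min_sample_reads)

  chem_vars <- attr(cf$frame, "chem_vars")
  chem <- as.matrix(al$frame[, chem_vars, drop = FALSE])
  pruned <- prune_collinear(chem, cf$collinearity_cutoff)
  write_tsv(data.frame(variable = colnames(chem),
                       kept = colnames(chem) %in% pruned$kept),
            file.path(cf$out_dir, "chemistry_pruning.tsv"))
  manifest$stages$chemistry <- list(n_vars = ncol(chem),
                                    n_kept = length(pruned$kept))

  sh <- shannon(rare)
  bc <- bray_curtis(css)
  write_tsv(data.frame(sample_id = names(sh), shannon = sh),
            file.path(cf$out_dir, "alpha_diversity.tsv"))
  write_tsv(data.frame(sample_id = labels(bc), as.matrix(bc)),
            file.path(cf$out_dir, "bray_curtis.tsv"))
  results$diversity <- list(shannon = sh, bray_curtis = bc)
  manifest$stages$diversity <- list(done = TRUE)

  if (cf$run_assembly) {
    keep <- if (cf$assembly_pool == "planted")
      al$frame$plot_type != "grass" else rep(TRUE, nrow(al$frame))
    sub <- tab_subset(rare, which(keep))
    sub <- tab_subset(sub, j = which(colSums(sub) > 0))
    pairs <- assembly_processes(sub, al$tree, n_null = cf$n_null,
                                seed = stage_seed(cf$seed, "assembly"))
    summ <- summarize_processes(pairs)
    write_tsv(as.data.frame(pairs),
              file.path(cf$out_dir, "assembly_pairs.tsv"))
    write_tsv(summ, file.path(cf$out_dir, "assembly_summary.tsv"))
    results$assembly <- list(pairs = pairs, summary = summ)
    manifest$stages$assembly <- list(
      n_samples = nrow(sub), n_pairs = nrow(pairs),
      n_null = cf$n_null, pool = cf$assembly_pool,
      n_undefined = attr(pairs, "n_undefined"))
  }

  if (cf$run_multivar) {
    sd_ <- stage_seed(cf$seed, "multivar")
    perm_tab <- permanova(bc, al$frame, c("plot_type", "plot_id"),
                          n_perm = cf$n_perm, seed = sd_)
    write_tsv(perm_tab, file.path(cf$out_dir, "permanova.tsv"))
    geo <- dist(al$frame[, c("x", "y")])
    env <- euclidean_dist(pruned$chemistry, standardize = TRUE)
    dd_geo <- distance_decay(bc, geo, n_perm = cf$n_perm, seed = sd_ + 1)
    dd_env <- distance_decay(bc, env, n_perm = cf$n_perm, seed = sd_ + 2)
    ord_comm <- pcoa_ord(bc)
    ord_chem <- pcoa_ord(euclidean_dist(pruned$chemistry,
                                        standardize = TRUE))
    k <- min(ncol(ord_comm$points), ncol(ord_chem$points))
    pro <- procrustes_test(ord_chem$points[, seq_len(k), drop = FALSE],
                           ord_comm$points[, seq_len(k), drop = FALSE],
                           n_perm = cf$n_perm, seed = sd_ + 3)
    write_tsv(data.frame(
      test = c("distance_decay_geographic", "distance_decay_environmental",
               "procrustes_chemistry_vs_community"),
      r = c(dd_geo$r, dd_env$r, pro$r),
      p = c(dd_geo$p, dd_env$p, pro$p)),
      file.path(cf$out_dir, "multivariate_tests.tsv"))
    results$multivar <- list(permanova = perm_tab, decay_geo = dd_geo,
                             decay_env = dd_env, procrustes = pro)
    manifest$stages$multivar <- list(n_perm = cf$n_perm)
  }

  if (cf$run_varpart) {
    sd_ <- stage_seed(cf$seed, "varpart")
    mem <- build_dbmem(al$frame[, c("x", "y")])
    mem <- select_mems(mem, bc, n_perm = cf$n_perm, alpha = 0.05,
                       seed = sd_)
    vp <- varpart_env_space(bc, pruned$chemistry, mem)
    write_tsv(data.frame(fraction = names(vp$fractions),
                         value = vp$fractions),
              file.path(cf$out_dir, "varpart.tsv"))
    results$varpart <- list(mem = mem, varpart = vp)
    manifest$stages$varpart <- list(
      n_mem = ncol(mem$vectors), n_mem_selected = length(mem$selected),
      fractions = as.list(vp$fractions))
  }

  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}
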