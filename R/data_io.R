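#' Read a community table from TSV
#'
#' Reads either a dense tab-delimited table (header row of identifiers,
#' first column of identifiers) or a sparse triplet TSV with columns
#' `taxon`, `sample`, `count` (BIOM-style). The returned table is always
#' oriented samples-as-rows; `orientation` declares how a dense file is laid
#' out on disk.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows of the dense file are samples,
#'   `"taxa"` if rows are taxa (the table is transposed on read).
#' @param format `"wide"` (dense) or `"triplet"` (sparse three-column).
#' @param kind value kind passed to [comm_table()] (default `"counts"`).
#' @return a [comm_table()].
#' @export
read_community_table <- function(path,
                                 orientation = c("samples", "taxa"),
                                 format = c("wide", "triplet"),
                                 kind = "counts") {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "triplet") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("triplet table needs columns taxon, sample, count")
    names(df)[1:3] <- c("taxon", "sample", "count")
    if (!is.numeric(df$count)) stop("non-numeric count in triplet table")
    if (anyDuplicated(df[c("taxon", "sample")]))
      stop("duplicated (taxon, sample) entry in triplet table")
    samples <- sort(unique(df$sample))
    taxa <- sort(unique(df$taxon))
    m <- matrix(0, length(samples), length(taxa),
                dimnames = list(samples, taxa))
    m[cbind(match(df$sample, samples), match(df$taxon, taxa))] <- df$count
    return(comm_table(m, kind))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated identifiers in first column")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric cell in community table")
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  comm_table(m, kind)
}

#' Write a community table as dense TSV (samples as rows)
#'
#' @param x a [comm_table()].
#' @param path output path.
#' @export
write_community_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as_comm_matrix(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' Branch lengths are required (the nearest-taxon null model is undefined
#' without patristic distances) and must be non-negative; the tree must be
#' rooted.
#'
#' @param path newick file path (or a newick string via [ape::read.tree]'s
#'   `text` argument when `text = TRUE`).
#' @param text if `TRUE`, `path` is taken as a literal newick string.
#' @return an [ape::phylo] object.
#' @export
read_phylogeny <- function(path, text = FALSE) {
  tree <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("unparseable newick input")
  if (is.null(tree$edge.length))
    stop("phylogeny has no branch lengths; they are required")
  if (any(tree$edge.length < 0)) stop("negative branch length in phylogeny")
  if (!ape::is.rooted(tree)) stop("phylogeny must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels")
  tree
}

#' Read per-sample metadata
#'
#' CSV with one row per sample. Must contain a `sample_id` column;
#' conventional columns are `plot_id`, `plot_type` (monoculture / mixed /
#' grass), `host_species`, coordinates `x`, `y` in meters, and any number of
#' numeric soil-chemistry columns. Samples with missing chemistry values are
#' flagged (attribute `incomplete_chemistry`) rather than imputed; callers
#' of environmental analyses should exclude them.
#'
#' @param path CSV path.
#' @param chem_vars optional character vector naming the chemistry columns;
#'   defaults to every numeric column other than `x`, `y`, `plot_id`.
#' @return a data.frame with attributes `chem_vars` and
#'   `incomplete_chemistry` (sample ids with missing chemistry).
#' @export
read_sample_frame <- function(path, chem_vars = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample frame needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in sample frame")
  if (all(c("x", "y") %in% names(df)) &&
      !all(is.finite(df$x) & is.finite(df$y)))
    stop("non-finite coordinates in sample frame")
  if (is.null(chem_vars)) {
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    chem_vars <- setdiff(num, c("x", "y", "plot_id"))
  }
  attr(df, "chem_vars") <- chem_vars
  inc <- df$sample_id[rowSums(is.na(df[, chem_vars, drop = FALSE])) > 0]
  attr(df, "incomplete_chemistry") <- inc
  df
}

#' Align a community table, phylogeny and sample frame
#'
#' Restricts samples to the intersection of the table and the frame, prunes
#' tree tips absent from the table (silently, with a message), orders
#' samples and taxa lexicographically for determinism, and errors if any
#' table taxon is missing from the tree (the nearest-taxon metric is
#' undefined for it). Idempotent.
#'
#' @param table a [comm_table()].
#' @param tree an [ape::phylo].
#' @param frame sample metadata data.frame with `sample_id`.
#' @return list with elements `table`, `tree`, `frame`, and `dropped`
#'   (record of removed samples/tips).
#' @export
align_inputs <- function(table, tree, frame) {
  samples <- sort(intersect(rownames(table), frame$sample_id))
  if (length(samples) == 0)
    stop("no samples shared between table and sample frame")
  taxa <- sort(colnames(table))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("table taxa absent from phylogeny: ",
         paste(head(missing, 5), collapse = ", "))
  extra_tips <- setdiff(tree$tip.label, taxa)
  if (length(extra_tips) > 0) {
    message(length(extra_tips), " tree tips absent from table; pruned")
    tree <- ape::keep.tip(tree, taxa)
  }
  dropped_samples <- union(setdiff(rownames(table), samples),
                           setdiff(frame$sample_id, samples))
  if (length(dropped_samples) > 0)
    message(length(dropped_samples), " samples outside the table/frame ",
            "intersection; dropped")
  table <- tab_subset(table, samples, taxa)
  frame <- frame[match(samples, frame$sample_id), , drop = FALSE]
  rownames(frame) <- NULL
  list(table = table, tree = tree, frame = frame,
       dropped = list(samples = dropped_samples, tips = extra_tips))
}
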