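#' Community abundance table
#'
#' A `comm_table` is a numeric matrix with samples as rows and taxa (or
#' functional features) as columns, carrying a `kind` flag that records how
#' the values were produced: raw `counts`, `rarefied` counts, `css`
#' (cumulative-sum-scaled) abundances or `relative` abundances. All
#' downstream functions check the flag where the method cares about it
#' (e.g. the Raup-Crick null draws individuals and so requires integer
#' counts).
#'
#' @param x numeric matrix with unique row (sample) and column (taxon)
#'   names; all values must be finite and non-negative.
#' @param kind one of `"counts"`, `"rarefied"`, `"css"`, `"relative"`.
#'   Count kinds must hold integer values; `relative` rows must sum to 1.
#'
#' @return `x` with class `comm_table` and attribute `kind`.
#' @export
comm_table <- function(x, kind = c("counts", "rarefied", "css", "relative")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x))) stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicated taxon identifiers")
  if (!all(is.finite(x))) stop("community table contains non-finite values")
  if (any(x < 0)) stop("community table contains negative values")
  if (kind %in% c("counts", "rarefied") &&
      any(abs(x - round(x)) > 1e-9))
    stop("kind '", kind, "' requires integer values")
  if (kind == "relative") {
    rs <- rowSums(x)
    if (any(rs == 0)) stop("relative-abundance table has all-zero rows")
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-abundance rows must sum to 1")
  }
  structure(x, kind = kind, class = c("comm_table", "matrix", "array"))
}

#' @export
print.comm_table <- function(x, ...) {
  cat(sprintf("comm_table [%s]: %d samples x %d taxa\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname comm_table
#' @export
tab_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) NA_character_ else k
}

#' Subset a community table preserving its class and kind
#'
#' @param x a [comm_table()].
#' @param i,j row (sample) / column (taxon) indices; `NULL` keeps all.
#' @rdname comm_table
#' @export
tab_subset <- function(x, i = NULL, j = NULL) {
  kind <- tab_kind(x)
  m <- unclass(x)
  attr(m, "kind") <- NULL
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  comm_table(m, kind)
}

as_comm_matrix <- function(x) {
  m <- as.matrix(unclass(x))
  attr(m, "kind") <- NULL
  m
}
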