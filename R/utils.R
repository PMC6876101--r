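#' @importFrom methods as is
#' @importFrom Matrix Diagonal rowSums colSums t sparseMatrix
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_(sprintf("'%s' must be a single number in [0, 1]", name))
  invisible(x)
}

#' Convert an undirected edge list to a symmetric sparse adjacency matrix
#'
#' Self-loops are dropped; duplicate edges (in either orientation) collapse to
#' a single entry. Unknown endpoints are an error.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`.
#' @param nodes character vector of node identifiers defining the matrix index.
#' @return a symmetric `dgCMatrix` with zero diagonal, dimnames = `nodes`.
#' @keywords internal
edges_to_adjacency <- function(edges, nodes) {
  n <- length(nodes)
  if (anyDuplicated(nodes)) stop_("node identifiers must be unique")
  if (nrow(edges) == 0L) {
    A <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n, n), dimnames = list(nodes, nodes))
    return(as(A, "generalMatrix"))
  }
  i <- match(as.character(edges$from), nodes)
  j <- match(as.character(edges$to), nodes)
  if (anyNA(i) || anyNA(j)) stop_("edge list references nodes absent from the index")
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
  keep <- i != j & w != 0
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  ii <- c(i, j); jj <- c(j, i); ww <- c(w, w)
  first <- !duplicated(cbind(ii, jj))
  A <- sparseMatrix(i = ii[first], j = jj[first], x = ww[first],
                    dims = c(n, n), dimnames = list(nodes, nodes))
  as(A, "generalMatrix")
}

#' Convert an association table to a sparse binary incidence matrix
#'
#' @param pairs data.frame, first column left entity, second column right entity.
#' @param left_ids,right_ids identifier vectors defining rows and columns.
#' @param drop_unmatched drop pairs whose endpoints are missing from the index
#'   (with a warning reporting the count) instead of erroring.
#' @return sparse binary matrix `length(left_ids)` x `length(right_ids)`.
#' @keywords internal
pairs_to_incidence <- function(pairs, left_ids, right_ids, drop_unmatched = TRUE) {
  i <- match(as.character(pairs[[1L]]), left_ids)
  j <- match(as.character(pairs[[2L]]), right_ids)
  bad <- is.na(i) | is.na(j)
  if (any(bad)) {
    if (!drop_unmatched) stop_("association endpoints missing from the node index")
    if (all(bad) && nrow(pairs) > 0L)
      stop_("association table references no known node in either layer")
    warning(sprintf("dropped %d association pair(s) with unknown endpoints", sum(bad)),
            call. = FALSE)
    i <- i[bad == FALSE]; j <- j[bad == FALSE]
  }
  keep <- !duplicated(cbind(i, j))
  sparseMatrix(i = i[keep], j = j[keep], x = 1,
               dims = c(length(left_ids), length(right_ids)),
               dimnames = list(left_ids, right_ids))
}
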