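#' RNA functional similarity from disease associations
#'
#' Two RNAs (miRNAs or lncRNAs) are functionally similar when the diseases
#' they are associated with are similar. Given a precomputed disease-disease
#' semantic similarity matrix, the similarity between two RNAs with disease
#' groups \eqn{D_1} and \eqn{D_2} is the symmetric average of best-match
#' similarities:
#' \deqn{S(D_1, D_2) = \frac{\sum_{d \in D_1} \max_{d' \in D_2} sim(d, d') +
#'   \sum_{d \in D_2} \max_{d' \in D_1} sim(d, d')}{|D_1| + |D_2|}.}
#'
#' @name rna-similarity
NULL

validate_dsim <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop_("disease similarity must be a square matrix")
  if (is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim)))
    stop_("disease similarity matrix needs identical row and column names")
  if (any(sim < 0 | sim > 1)) stop_("disease similarities must lie in [0, 1]")
  if (max(abs(sim - t(sim))) > 1e-8) stop_("disease similarity matrix must be symmetric")
  invisible(sim)
}

#' Best-match similarity between a disease and a disease group
#'
#' @param d a disease identifier.
#' @param D non-empty character vector of disease identifiers.
#' @param sim square named disease similarity matrix with unit diagonal.
#' @return the maximum similarity between `d` and any member of `D`.
#' @examples
#' sim <- diag(3); dimnames(sim) <- list(c("a","b","c"), c("a","b","c"))
#' sim["a","b"] <- sim["b","a"] <- 0.4
#' group_similarity("a", c("b", "c"), sim)
#' @export
group_similarity <- function(d, D, sim) {
  if (length(D) == 0L) stop_("disease group is empty")
  ids <- rownames(sim)
  if (!(d %in% ids)) stop_(sprintf("disease '%s' absent from similarity matrix", d))
  miss <- setdiff(D, ids)
  if (length(miss)) stop_(sprintf("disease(s) absent from similarity matrix: %s",
                                  paste(miss, collapse = ", ")))
  max(sim[d, D])
}

#' Functional similarity between two disease groups
#'
#' Symmetric average of best-match disease similarities; used to score pairs
#' of miRNAs or lncRNAs via the disease sets they are associated with.
#'
#' @param D1,D2 non-empty character vectors of disease identifiers.
#' @param sim square named disease similarity matrix.
#' @return similarity score in \[0, 1\]; symmetric in `D1`, `D2`.
#' @export
rna_functional_similarity <- function(D1, D2, sim) {
  if (length(D1) == 0L || length(D2) == 0L) stop_("disease group is empty")
  s1 <- vapply(D1, function(d) group_similarity(d, D2, sim), numeric(1))
  s2 <- vapply(D2, function(d) group_similarity(d, D1, sim), numeric(1))
  (sum(s1) + sum(s2)) / (length(D1) + length(D2))
}

#' Pairwise RNA functional similarity matrix
#'
#' Vectorized computation of [rna_functional_similarity()] over all pairs of
#' entities in an association table. Entities associated with zero diseases
#' get similarity 0 to everything (and 0 to themselves): the measure is
#' undefined for empty disease groups and such entities later enter the
#' similarity network as isolated nodes.
#'
#' @param assoc data.frame: column 1 entity id, column 2 disease id.
#' @param dsim named square disease similarity matrix.
#' @param entities optional entity universe (defaults to entities in `assoc`).
#' @return symmetric similarity matrix over `entities`.
#' @export
rna_similarity_matrix <- function(assoc, dsim, entities = NULL) {
  validate_dsim(dsim)
  entities <- entities %||% sort(unique(as.character(assoc[[1L]])))
  A <- as.matrix(pairs_to_incidence(assoc, entities, rownames(dsim)))
  sizes <- rowSums(A)
  # Gmax[e, d] = max over diseases of entity e of sim(d, .): best-match profile
  Gmax <- matrix(0, length(entities), nrow(dsim),
                 dimnames = list(entities, rownames(dsim)))
  has <- sizes > 0
  if (any(has)) {
    for (e in which(has)) {
      De <- A[e, ] > 0
      Gmax[e, ] <- apply(dsim[, De, drop = FALSE], 1L, max)
    }
  }
  # term[e1, e2] = sum_{d in D_{e1}} max-match of d against D_{e2}
  term <- A %*% t(Gmax)
  S <- (term + t(term)) / outer(sizes, sizes, `+`)
  S[!has, ] <- 0
  S[, !has] <- 0
  diag(S)[!has] <- 0
  dimnames(S) <- list(entities, entities)
  S
}

#' Build a k-nearest-neighbour similarity network
#'
#' Links every node to its `k` most similar other nodes; the edge set is the
#' union over nodes (an edge exists if either endpoint selects the other).
#' Zero-similarity candidates are never selected, so nodes with an all-zero
#' similarity row become isolated. Ties at the k-th rank are broken by
#' lexicographic node identifier for determinism.
#'
#' @param entities ordered character vector of node identifiers.
#' @param sim_matrix square symmetric similarity matrix matching `entities`.
#' @param k number of neighbours, `1 <= k < length(entities)`.
#' @param weighted if `TRUE` (default) edges carry the similarity as weight,
#'   otherwise weight 1.
#' @return an object of class `similarity_network`: list with `nodes` and an
#'   `edges` data.frame (`from`, `to`, `weight`).
#' @export
build_knn_network <- function(entities, sim_matrix, k, weighted = TRUE) {
  n <- length(entities)
  if (n < 2L) stop_("need at least two entities")
  if (!is.numeric(k) || k < 1L || k >= n) stop_("'k' must satisfy 1 <= k < number of entities")
  k <- as.integer(k)
  if (!all(dim(sim_matrix) == c(n, n))) stop_("similarity matrix does not match entities")
  sel_i <- integer(0); sel_j <- integer(0)
  ord_id <- order(entities)            # lexicographic tie-break
  for (i in seq_len(n)) {
    s <- sim_matrix[i, ]
    s[i] <- -Inf
    cand <- which(s > 0)
    if (!length(cand)) next
    o <- cand[order(-s[cand], match(cand, ord_id))]
    nb <- o[seq_len(min(k, length(o)))]
    sel_i <- c(sel_i, rep.int(i, length(nb)))
    sel_j <- c(sel_j, nb)
  }
  a <- pmin(sel_i, sel_j); b <- pmax(sel_i, sel_j)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  w <- if (length(a)) sim_matrix[cbind(a, b)] else numeric(0)
  if (!weighted) w <- rep(1, length(a))
  structure(list(nodes = entities,
                 edges = data.frame(from = entities[a], to = entities[b],
                                    weight = w, stringsAsFactors = FALSE)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Adjacency matrix of a similarity network
#' @param net a `similarity_network`.
#' @return symmetric sparse adjacency with the edge weights.
#' @export
network_adjacency <- function(net) {
  edges_to_adjacency(net$edges, net$nodes)
}
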