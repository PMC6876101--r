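#' Row-normalize a nonnegative matrix
#'
#' Rows with positive sum are divided by their sum; all-zero rows are left as
#' zero (dangling rows), so the result is row-stochastic up to dangling rows.
#'
#' @param A nonnegative matrix (dense or sparse).
#' @return matrix of the same shape with rows summing to 1 or 0.
#' @export
row_normalize <- function(A) {
  if (min(A) < 0) stop_("matrix has negative entries")
  rs <- Matrix::rowSums(A)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  out <- Diagonal(x = inv) %*% A
  dimnames(out) <- dimnames(A)
  out
}

#' Transition matrix of a single network
#'
#' The within-network walk operator: each row of the adjacency divided by its
#' degree (weighted row sum); isolated nodes keep an all-zero row.
#'
#' @param adj nonnegative square adjacency matrix.
#' @return row-stochastic (up to dangling rows) matrix.
#' @export
single_network_transition <- function(adj) {
  if (nrow(adj) != ncol(adj)) stop_("adjacency must be square")
  row_normalize(adj)
}

#' Network membership count per gene
#'
#' Counts in how many of the two gene-evidence networks (PPI, pathway) each
#' gene has at least one incident edge. Used to average the two per-network
#' transition operators: a gene present in both splits its step between them.
#'
#' @param ppi_adj,path_adj adjacencies on the same gene index.
#' @return integer vector, values 0, 1 or 2.
#' @export
membership_count <- function(ppi_adj, path_adj) {
  if (!all(dim(ppi_adj) == dim(path_adj)))
    stop_("PPI and pathway adjacencies must share the gene index")
  as.integer(Matrix::rowSums(ppi_adj) > 0) + as.integer(Matrix::rowSums(path_adj) > 0)
}

#' Protein-complex feedback weights
#'
#' For each gene i in at least one complex, its feedback ratio is the maximum
#' over complexes containing i of (number of cancer genes in the complex /
#' complex size). The feedback matrix assigns that ratio to every neighbour j
#' of i in the merged gene network, boosting transitions out of genes sitting
#' in cancer-enriched complexes.
#'
#' @param gene_adj merged gene adjacency (defines the neighbourhoods).
#' @param complexes a [complex_catalog()].
#' @param cancer_genes character vector of genes currently treated as
#'   cancer-associated.
#' @param warn_missing warn when a complex member is absent from the gene
#'   index (set to `FALSE` on deliberately restricted indices, e.g. the
#'   second-round network).
#' @return list with `ratio` (per-gene numeric vector in \[0,1\]) and `W_com`
#'   (sparse matrix, `ratio[i]` wherever `gene_adj[i, j] > 0`).
#' @export
complex_weight <- function(gene_adj, complexes, cancer_genes, warn_missing = TRUE) {
  genes <- rownames(gene_adj)
  if (is.null(genes)) stop_("gene adjacency needs row names")
  ratio <- numeric(length(genes))
  names(ratio) <- genes
  unknown <- setdiff(unique(unlist(complexes$complexes)), genes)
  if (length(unknown) && warn_missing)
    warning(sprintf("%d complex member(s) absent from the gene index were ignored",
                    length(unknown)), call. = FALSE)
  for (cpx in complexes$complexes) {
    members <- intersect(cpx, genes)
    if (length(members) == 0L) next
    r <- sum(cpx %in% cancer_genes) / length(cpx)
    upd <- members[ratio[members] < r]
    ratio[upd] <- r
  }
  W_com <- Diagonal(x = ratio) %*% (gene_adj > 0)
  dimnames(W_com) <- dimnames(gene_adj)
  list(ratio = ratio, W_com = as(W_com, "generalMatrix"))
}

#' Gene-layer transition matrix fusing PPI, pathway and complex evidence
#'
#' Averages the row-normalized PPI and pathway operators over the networks
#' each source gene belongs to, adds the complex feedback, and row-normalizes:
#' \deqn{W_G = rownorm( (1/N_i) W_P + (1/N_i) W_{Path} + W_{com} )}
#' where \eqn{N_i \in \{1, 2\}} counts the evidence networks gene i is
#' non-isolated in (genes isolated in both contribute nothing from the two
#' network terms).
#'
#' @param ppi_adj,path_adj gene adjacencies on the shared merged index.
#' @param complexes a [complex_catalog()] or `NULL` to disable the feedback.
#' @param cancer_genes cancer-associated gene ids (used by the feedback only).
#' @return row-stochastic (up to dangling rows) sparse gene transition matrix.
#' @export
gene_transition <- function(ppi_adj, path_adj, complexes = NULL,
                            cancer_genes = character(0), warn_missing = TRUE) {
  N <- membership_count(ppi_adj, path_adj)
  invN <- ifelse(N > 0, 1 / N, 0)
  W_P <- single_network_transition(ppi_adj)
  W_Path <- single_network_transition(path_adj)
  initial <- Diagonal(x = invN) %*% W_P + Diagonal(x = invN) %*% W_Path
  if (!is.null(complexes) && length(complexes$complexes)) {
    union_adj <- (ppi_adj + path_adj) > 0
    union_adj <- as(union_adj, "dMatrix")
    dimnames(union_adj) <- dimnames(ppi_adj)
    initial <- initial + complex_weight(union_adj, complexes, cancer_genes, warn_missing)$W_com
  }
  W_G <- row_normalize(initial)
  dimnames(W_G) <- dimnames(ppi_adj)
  W_G
}

#' Global transition matrix of the quadruple-layer network
#'
#' Assembles the walk operator over all four layers: diagonal blocks are the
#' intra-layer transitions scaled by (1 - delta); off-diagonal blocks are the
#' row-normalized bipartite couplings scaled by the jump probability delta
#' split equally over the inter-layer blocks that are non-empty for that row.
#' A node with no inter-layer couplings keeps full mass 1 in its own layer; a
#' node with couplings but no intra-layer edges spreads mass 1 over its
#' couplings. Every non-dangling row therefore sums to exactly 1.
#'
#' @param net a `het_network`.
#' @param W_G precomputed gene-layer transition (see [gene_transition()]); if
#'   `NULL`, the row-normalized merged gene adjacency is used.
#' @param delta jump probability in \[0, 1\].
#' @return a `transition_matrix` object: list with `W` (sparse, row-stochastic
#'   up to dangling rows), `index`, and `delta`.
#' @export
global_transition <- function(net, W_G = NULL, delta = 0.5) {
  assert_prob(delta, "delta")
  idx <- net$index
  intra <- list(
    gene = if (is.null(W_G)) single_network_transition(net$intra$G) else W_G,
    mirna = single_network_transition(net$intra$M),
    lncrna = single_network_transition(net$intra$L),
    cancer = single_network_transition(net$intra$C))
  # normalized inter blocks per direction
  inter_for <- function(layer) {
    out <- list()
    for (s in inter_slots) {
      lr <- inter_layers[[s]]
      if (lr[1L] == layer) out[[lr[2L]]] <- row_normalize(net$inter[[s]])
      else if (lr[2L] == layer) out[[lr[1L]]] <- row_normalize(Matrix::t(net$inter[[s]]))
    }
    out[setdiff(layer_slots, layer)]
  }
  rows <- vector("list", 4L)
  for (r in seq_along(layer_slots)) {
    layer <- layer_slots[r]
    Wd <- intra[[layer]]
    nb <- inter_for(layer)
    s0 <- Matrix::rowSums(Wd) > 1e-300
    present <- vapply(nb, function(B) Matrix::rowSums(B) > 1e-300,
                      logical(idx$sizes[[layer]]))
    if (idx$sizes[[layer]] == 1L)
      present <- matrix(present, nrow = 1L, dimnames = list(NULL, names(nb)))
    kk <- rowSums(present)
    w_intra <- ifelse(s0, ifelse(kk > 0, 1 - delta, 1), 0)
    blocks <- vector("list", 4L)
    blocks[[r]] <- Diagonal(x = w_intra) %*% Wd
    other <- setdiff(layer_slots, layer)
    for (j in seq_along(layer_slots)) {
      if (j == r) next
      tgt <- layer_slots[j]
      w_inter <- ifelse(present[, tgt], ifelse(s0, delta / pmax(kk, 1), 1 / pmax(kk, 1)), 0)
      blocks[[j]] <- Diagonal(x = w_inter) %*% nb[[tgt]]
    }
    rows[[r]] <- do.call(cbind, blocks)
  }
  W <- do.call(rbind, rows)
  ids <- c(idx$gene, idx$mirna, idx$lncrna, idx$cancer)
  dimnames(W) <- list(ids, ids)
  structure(list(W = W, index = idx, delta = delta), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  rs <- Matrix::rowSums(x$W)
  cat(sprintf("transition_matrix: %d nodes, delta = %g, %d dangling row(s)\n",
              nrow(x$W), x$delta, sum(rs == 0)))
  invisible(x)
}
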