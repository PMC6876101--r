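#' Merge PPI and pathway networks into a single gene network
#'
#' The merged gene layer is the union of the two edge sets (duplicates and
#' self-loops removed). Because the two evidence sources keep distinct roles
#' downstream (the gene-layer transition averages their individual
#' row-normalized operators), per-network membership is returned alongside the
#' union.
#'
#' @param ppi,pathway data.frames with columns `from`, `to` (undirected edges).
#' @return list with `nodes` (sorted union), `edges` (deduplicated union,
#'   columns `from`, `to`), and `membership` data.frame (`node`, `in_ppi`,
#'   `in_pathway`): presence means >= 1 incident edge in that network.
#' @export
merge_gene_networks <- function(ppi, pathway) {
  clean <- function(e) {
    e <- data.frame(from = as.character(e[[1L]]), to = as.character(e[[2L]]),
                    stringsAsFactors = FALSE)
    e <- e[e$from != e$to, , drop = FALSE]
    a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
    unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  }
  p <- clean(ppi); q <- clean(pathway)
  nodes <- sort(unique(c(p$from, p$to, q$from, q$to)))
  if (length(nodes) == 0L) stop_("merged gene network is empty")
  edges <- unique(rbind(p, q))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  membership <- data.frame(
    node = nodes,
    in_ppi = nodes %in% c(p$from, p$to),
    in_pathway = nodes %in% c(q$from, q$to),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, membership = membership)
}

#' Layered node index of a quadruple-layer network
#'
#' @param gene_ids,mirna_ids,lncrna_ids,cancer_ids ordered identifier vectors.
#' @return a `layer_index` object: the four id vectors, per-layer sizes
#'   `(n, m, l, c)` and 0-based `offsets` of each layer in the concatenation
#'   gene, miRNA, lncRNA, cancer.
#' @export
layer_index <- function(gene_ids, mirna_ids, lncrna_ids, cancer_ids) {
  ids <- list(gene = as.character(gene_ids), mirna = as.character(mirna_ids),
              lncrna = as.character(lncrna_ids), cancer = as.character(cancer_ids))
  for (nm in names(ids))
    if (anyDuplicated(ids[[nm]])) stop_(sprintf("duplicate identifiers in %s layer", nm))
  sizes <- vapply(ids, length, integer(1))
  structure(c(ids, list(sizes = sizes,
                        offsets = cumsum(c(0L, unname(sizes)))[1:4])),
            class = "layer_index")
}

#' @export
print.layer_index <- function(x, ...) {
  cat(sprintf("layer_index: %d genes, %d miRNAs, %d lncRNAs, %d cancers\n",
              x$sizes[["gene"]], x$sizes[["mirna"]], x$sizes[["lncrna"]],
              x$sizes[["cancer"]]))
  invisible(x)
}

layer_slots <- c("gene", "mirna", "lncrna", "cancer")
inter_slots <- c("GM", "GL", "GC", "ML", "MC", "LC")
inter_layers <- list(GM = c("gene", "mirna"), GL = c("gene", "lncrna"),
                     GC = c("gene", "cancer"), ML = c("mirna", "lncrna"),
                     MC = c("mirna", "cancer"), LC = c("lncrna", "cancer"))

#' Assemble the quadruple-layer heterogeneous network
#'
#' Builds the block adjacency over the four node layers: the intra-layer
#' adjacencies G, M, L, C on the diagonal and the six bipartite association
#' blocks GM, GL, GC, ML, MC, LC (plus transposes) off the diagonal.
#' Association pairs whose endpoints are missing from the corresponding layer
#' are dropped with a warning count; inter-layer weights are binary.
#'
#' @param gene_net merged gene network as returned by [merge_gene_networks()],
#'   or a list with `nodes` and `edges`.
#' @param mirna_net,lncrna_net,cancer_net `similarity_network` objects (or
#'   lists with `nodes`/`edges`).
#' @param gene_mirna,gene_lncrna,gene_cancer,mirna_lncrna,mirna_cancer,lncrna_cancer
#'   two-column association data.frames (left entity, right entity); may be
#'   empty.
#' @param ppi,pathway optional original gene edge lists; when supplied they are
#'   carried along (indexed on the merged gene set) for the gene-layer
#'   transition builder.
#' @return a `het_network`: list with `index` (a [layer_index()]), `intra`
#'   (named list G, M, L, C of symmetric sparse matrices) and `inter` (named
#'   list of the six sparse bipartite blocks), plus optional `evidence`
#'   (`ppi`, `pathway` adjacencies on the gene index).
#' @export
assemble_heterogeneous <- function(gene_net, mirna_net, lncrna_net, cancer_net,
                                   gene_mirna, gene_lncrna, gene_cancer,
                                   mirna_lncrna, mirna_cancer, lncrna_cancer,
                                   ppi = NULL, pathway = NULL) {
  idx <- layer_index(gene_net$nodes, mirna_net$nodes, lncrna_net$nodes,
                     cancer_net$nodes)
  intra <- list(
    G = edges_to_adjacency(gene_net$edges, idx$gene),
    M = edges_to_adjacency(mirna_net$edges, idx$mirna),
    L = edges_to_adjacency(lncrna_net$edges, idx$lncrna),
    C = edges_to_adjacency(cancer_net$edges, idx$cancer))
  assoc <- list(GM = gene_mirna, GL = gene_lncrna, GC = gene_cancer,
                ML = mirna_lncrna, MC = mirna_cancer, LC = lncrna_cancer)
  inter <- lapply(inter_slots, function(s) {
    lr <- inter_layers[[s]]
    pairs_to_incidence(assoc[[s]], idx[[lr[1L]]], idx[[lr[2L]]])
  })
  names(inter) <- inter_slots
  evidence <- NULL
  if (!is.null(ppi) || !is.null(pathway)) {
    restrict <- function(e) {
      if (is.null(e)) return(NULL)
      e <- e[as.character(e[[1L]]) %in% idx$gene &
               as.character(e[[2L]]) %in% idx$gene, , drop = FALSE]
      names(e)[1:2] <- c("from", "to")
      edges_to_adjacency(e, idx$gene)
    }
    evidence <- list(ppi = restrict(ppi), pathway = restrict(pathway))
  }
  structure(list(index = idx, intra = intra, inter = inter, evidence = evidence),
            class = "het_network")
}

#' @export
print.het_network <- function(x, ...) {
  print(x$index)
  ne <- vapply(x$intra, function(a) length(a@x) / 2, numeric(1))
  na <- vapply(x$inter, function(a) length(a@x), numeric(1))
  cat("intra-layer edges:", paste(sprintf("%s=%d", names(ne), ne), collapse = " "), "\n")
  cat("inter-layer pairs:", paste(sprintf("%s=%d", names(na), na), collapse = " "), "\n")
  invisible(x)
}

#' Full block adjacency matrix of a heterogeneous network
#'
#' Concatenates the ten blocks into the single symmetric adjacency over all
#' n + m + l + c nodes, in layer order gene, miRNA, lncRNA, cancer.
#'
#' @param net a `het_network`.
#' @return symmetric sparse matrix with concatenated dimnames.
#' @export
block_adjacency <- function(net) {
  w <- net$intra; b <- net$inter
  H <- rbind(
    cbind(w$G, b$GM, b$GL, b$GC),
    cbind(Matrix::t(b$GM), w$M, b$ML, b$MC),
    cbind(Matrix::t(b$GL), Matrix::t(b$ML), w$L, b$LC),
    cbind(Matrix::t(b$GC), Matrix::t(b$MC), Matrix::t(b$LC), w$C))
  ids <- c(net$index$gene, net$index$mirna, net$index$lncrna, net$index$cancer)
  dimnames(H) <- list(ids, ids)
  H
}

#' Protein complex catalog
#'
#' @param complexes list of character vectors of gene identifiers. Complexes
#'   with fewer than two members are removed.
#' @return a `complex_catalog` (list of membership vectors).
#' @export
complex_catalog <- function(complexes) {
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  complexes <- complexes[vapply(complexes, length, integer(1)) >= 2L]
  structure(list(complexes = complexes), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog: %d complexes, %d distinct proteins\n",
              length(x$complexes), length(unique(unlist(x$complexes)))))
  invisible(x)
}
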