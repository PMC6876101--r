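#' Walk parameters
#'
#' Container for the tunable parameters of the two-round walk. Defaults are
#' the values used throughout: delta = 0.5 and eta_i = 0.25 (uniform layer
#' importance), gamma = 0.6, sigma = 0.6, alpha = 0.9, convergence tolerance
#' 1e-6 (Euclidean norm of the iterate difference).
#'
#' @param delta probability of jumping between layers at each step.
#' @param eta length-4 nonnegative vector summing to 1: restart-mass share of
#'   the gene, miRNA, lncRNA and cancer layers.
#' @param gamma restart probability.
#' @param sigma fraction of genes kept after the first round (k = round(sigma n),
#'   minimum 1).
#' @param alpha fusion weight of the first-round score in the final score.
#' @param tol convergence threshold on the Euclidean residual.
#' @param max_iter iteration cap for the power iteration.
#' @return a `walk_params` list.
#' @export
walk_params <- function(delta = 0.5, eta = rep(0.25, 4), gamma = 0.6,
                        sigma = 0.6, alpha = 0.9, tol = 1e-6, max_iter = 1000L) {
  assert_prob(delta, "delta"); assert_prob(gamma, "gamma")
  assert_prob(sigma, "sigma"); assert_prob(alpha, "alpha")
  if (length(eta) != 4L || any(eta < 0) || abs(sum(eta) - 1) > 1e-9)
    stop_("'eta' must be 4 nonnegative weights summing to 1")
  if (!is.numeric(tol) || tol <= 0) stop_("'tol' must be positive")
  structure(list(delta = delta, eta = as.numeric(eta), gamma = gamma,
                 sigma = sigma, alpha = alpha, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "walk_params")
}

#' Per-layer seed sets
#'
#' @param gene_seeds,mirna_seeds,lncrna_seeds,cancer_seeds identifier vectors
#'   (may be empty, but not all of them).
#' @return a `seed_set` list.
#' @export
seed_set <- function(gene_seeds = character(0), mirna_seeds = character(0),
                     lncrna_seeds = character(0), cancer_seeds = character(0)) {
  s <- list(gene = unique(as.character(gene_seeds)),
            mirna = unique(as.character(mirna_seeds)),
            lncrna = unique(as.character(lncrna_seeds)),
            cancer = unique(as.character(cancer_seeds)))
  if (all(vapply(s, length, integer(1)) == 0L))
    stop_("at least one layer must contain a seed")
  structure(s, class = "seed_set")
}

#' Initial restart distribution over the layered node index
#'
#' Within each layer, that layer's eta mass is spread uniformly over its
#' seeds. Layers without seeds contribute nothing and their eta is
#' redistributed proportionally over the seeded layers, so the vector always
#' sums to 1.
#'
#' @param seeds a [seed_set()].
#' @param eta length-4 layer importance weights.
#' @param index a [layer_index()].
#' @return named probability vector over all n + m + l + c nodes.
#' @export
initial_probability <- function(seeds, eta, index) {
  if (length(eta) != 4L || any(eta < 0)) stop_("invalid eta")
  ids <- c(index$gene, index$mirna, index$lncrna, index$cancer)
  p0 <- numeric(length(ids)); names(p0) <- ids
  seeded <- vapply(layer_slots, function(l) length(seeds[[l]]) > 0L, logical(1))
  w <- eta * seeded
  if (sum(w) <= 0) stop_("no restart mass: every seeded layer has eta = 0")
  w <- w / sum(w)
  for (r in seq_along(layer_slots)) {
    l <- layer_slots[r]
    if (!seeded[r]) next
    miss <- setdiff(seeds[[l]], index[[l]])
    if (length(miss)) stop_(sprintf("seed(s) absent from %s layer: %s", l,
                                    paste(miss, collapse = ", ")))
    p0[seeds[[l]]] <- w[r] / length(seeds[[l]])
  }
  p0
}

#' Random walk with restart
#'
#' Power iteration \eqn{P(t+1) = (1-\gamma) W^T P(t) + \gamma P(0)} until the
#' Euclidean norm of the difference between successive iterates falls below
#' `tol`. The transpose propagates probability along edges so that a
#' distribution stays a distribution on a dangling-free operator.
#'
#' @param W a `transition_matrix` or a row-stochastic sparse matrix.
#' @param p0 initial (restart) probability vector.
#' @param gamma restart probability.
#' @param tol convergence threshold (default 1e-6).
#' @param max_iter iteration cap; exceeded caps raise an error carrying the
#'   last residual.
#' @return stationary probability vector, with attribute `"iterations"`.
#' @export
rwr <- function(W, p0, gamma, tol = 1e-6, max_iter = 1000L) {
  if (inherits(W, "transition_matrix")) W <- W$W
  assert_prob(gamma, "gamma")
  if (abs(sum(p0) - 1) > 1e-8) stop_("'p0' must sum to 1")
  Wt <- Matrix::t(W)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - gamma) * (Wt %*% p)) + gamma * p0
    res <- sqrt(sum((p_new - p)^2))
    p <- p_new
    if (res < tol) {
      names(p) <- names(p0)
      attr(p, "iterations") <- it
      return(p)
    }
  }
  stop_(sprintf("random walk did not converge in %d iterations (residual %.3g)",
                max_iter, res))
}

#' Genes/miRNAs/lncRNAs associated with at least one cancer
#' @param net a `het_network`.
#' @return list of identifier vectors `gene`, `mirna`, `lncrna`.
#' @export
cancer_associated <- function(net) {
  list(gene = net$index$gene[Matrix::rowSums(net$inter$GC) > 0],
       mirna = net$index$mirna[Matrix::rowSums(net$inter$MC) > 0],
       lncrna = net$index$lncrna[Matrix::rowSums(net$inter$LC) > 0])
}

gene_evidence <- function(net) {
  ev <- net$evidence
  list(ppi = ev$ppi %||% net$intra$G, pathway = ev$pathway %||% net$intra$G)
}

#' First-round walk: class-level screening of candidate genes
#'
#' Seeds every cancer node and every gene, miRNA and lncRNA associated with
#' any cancer, runs the restart walk on the full quadruple-layer network, and
#' keeps the k = round(sigma n) highest-scoring genes.
#'
#' @param net a `het_network`.
#' @param complexes a [complex_catalog()] or `NULL`.
#' @param params a [walk_params()].
#' @param cancer_gene_set genes treated as cancer-associated for the complex
#'   feedback; defaults to the genes with at least one cancer association.
#' @return list with `P1` (full stationary vector), `topk` (retained gene
#'   ids, best first), `W_G` and `W` (the operators used).
#' @export
first_round <- function(net, complexes, params, cancer_gene_set = NULL) {
  assoc <- cancer_associated(net)
  cancer_gene_set <- cancer_gene_set %||% assoc$gene
  ev <- gene_evidence(net)
  W_G <- gene_transition(ev$ppi, ev$pathway, complexes, cancer_gene_set,
                         warn_missing = FALSE)
  W <- global_transition(net, W_G, params$delta)
  seeds <- seed_set(assoc$gene, assoc$mirna, assoc$lncrna, net$index$cancer)
  p0 <- initial_probability(seeds, params$eta, net$index)
  P1 <- rwr(W, p0, params$gamma, params$tol, params$max_iter)
  genes <- net$index$gene
  pg <- P1[genes]
  k <- max(1L, as.integer(round(params$sigma * length(genes))))
  ord <- order(-pg, genes)
  topk <- genes[ord[seq_len(k)]]
  list(P1 = P1, topk = topk, W_G = W_G, W = W)
}

#' Reconstruct the network for the second round
#'
#' Restricts the gene layer to the genes retained by the first round (induced
#' subgraph of the gene network; gene rows of the gene-miRNA, gene-lncRNA and
#' gene-cancer blocks restricted). The miRNA, lncRNA and cancer layers are
#' unchanged.
#'
#' @param net a `het_network`.
#' @param topk_genes subset of the gene layer to keep.
#' @return a `het_network` on the restricted gene index.
#' @export
build_second_round_network <- function(net, topk_genes) {
  if (length(topk_genes) == 0L) stop_("empty gene selection")
  miss <- setdiff(topk_genes, net$index$gene)
  if (length(miss)) stop_("selection contains unknown genes")
  keep <- net$index$gene %in% topk_genes       # preserve original order
  idx <- layer_index(net$index$gene[keep], net$index$mirna,
                     net$index$lncrna, net$index$cancer)
  intra <- net$intra
  intra$G <- net$intra$G[keep, keep, drop = FALSE]
  inter <- net$inter
  for (s in c("GM", "GL", "GC")) inter[[s]] <- net$inter[[s]][keep, , drop = FALSE]
  evidence <- net$evidence
  if (!is.null(evidence)) {
    evidence <- lapply(evidence, function(A)
      if (is.null(A)) NULL else A[keep, keep, drop = FALSE])
  }
  structure(list(index = idx, intra = intra, inter = inter, evidence = evidence),
            class = "het_network")
}

#' Second-round walk: disease-specific prioritization
#'
#' Runs the restart walk on the reconstructed network with the one cancer
#' node and its associated genes/miRNAs/lncRNAs as seeds.
#'
#' @param subnet reconstructed `het_network` (see
#'   [build_second_round_network()]).
#' @param complexes a [complex_catalog()] or `NULL`.
#' @param params a [walk_params()].
#' @param disease cancer node identifier.
#' @param cancer_gene_set genes treated as cancer-associated for the complex
#'   feedback (same class-level set as the first round, restricted to the
#'   surviving genes).
#' @return stationary probability vector over the subnetwork index.
#' @export
second_round <- function(subnet, complexes, params, disease,
                         cancer_gene_set = NULL) {
  idx <- subnet$index
  if (!(disease %in% idx$cancer)) stop_(sprintf("unknown cancer '%s'", disease))
  dg <- idx$gene[subnet$inter$GC[, disease] > 0]
  dm <- idx$mirna[subnet$inter$MC[, disease] > 0]
  dl <- idx$lncrna[subnet$inter$LC[, disease] > 0]
  if (length(dg) + length(dm) + length(dl) == 0L)
    stop_(sprintf("cancer '%s' has no associated seed entities in the subnetwork",
                  disease))
  cancer_gene_set <- cancer_gene_set %||% cancer_associated(subnet)$gene
  ev <- gene_evidence(subnet)
  W_G <- gene_transition(ev$ppi, ev$pathway, complexes,
                         intersect(cancer_gene_set, idx$gene),
                         warn_missing = FALSE)
  W <- global_transition(subnet, W_G, params$delta)
  seeds <- seed_set(dg, dm, dl, disease)
  p0 <- initial_probability(seeds, params$eta, idx)
  rwr(W, p0, params$gamma, params$tol, params$max_iter)
}

#' Fuse the two walk rounds into one per-gene score
#'
#' Score = alpha P1 + (1 - alpha) P2 on the genes retained in round one;
#' genes ejected in round one have no second-round score and get
#' Score = alpha P1 (their P2 is taken as 0), so every gene keeps a score and
#' can be ranked.
#'
#' @param P1 full stationary vector of the first round.
#' @param P2 stationary vector over the reconstructed network.
#' @param index full [layer_index()].
#' @param topk_genes genes retained in round one.
#' @param alpha fusion weight in \[0, 1\].
#' @return named per-gene score vector over all genes.
#' @export
combine_scores <- function(P1, P2, index, topk_genes, alpha) {
  assert_prob(alpha, "alpha")
  genes <- index$gene
  p2 <- numeric(length(genes)); names(p2) <- genes
  common <- intersect(names(P2), genes)
  p2[common] <- P2[common]
  alpha * P1[genes] + (1 - alpha) * p2
}

#' Prioritize candidate genes for one cancer by the two-round walk
#'
#' End-to-end run: first-round class-level screen, network reconstruction,
#' disease-specific second round, score fusion and rank scoring over all
#' genes.
#'
#' @inheritParams first_round
#' @param disease cancer node identifier.
#' @param first optional precomputed [first_round()] result (the first round
#'   does not depend on the disease, so it can be shared across diseases).
#' @return data.frame with columns `gene`, `P1`, `P2`, `score`, `rank_score`,
#'   ordered by decreasing score.
#' @export
prioritize <- function(net, complexes, params, disease,
                       cancer_gene_set = NULL, first = NULL) {
  cancer_gene_set <- cancer_gene_set %||% cancer_associated(net)$gene
  fr <- first %||% first_round(net, complexes, params, cancer_gene_set)
  subnet <- build_second_round_network(net, fr$topk)
  P2 <- second_round(subnet, complexes, params, disease, cancer_gene_set)
  score <- combine_scores(fr$P1, P2, net$index, fr$topk, params$alpha)
  genes <- net$index$gene
  p2full <- numeric(length(genes)); names(p2full) <- genes
  p2full[intersect(names(P2), genes)] <- P2[intersect(names(P2), genes)]
  out <- data.frame(gene = genes,
                    P1 = as.numeric(fr$P1[genes]),
                    P2 = as.numeric(p2full),
                    score = as.numeric(score),
                    rank_score = rank_score(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}
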