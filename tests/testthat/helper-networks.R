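# Small builders shared across tests. Everything is generated in code.

# named disease similarity matrix with unit diagonal
make_dsim <- function(ids, fill) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- fill
  m <- m + t(m)
  diag(m) <- 1
  m
}

random_dsim <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("d%02d", seq_len(n))
  make_dsim(ids, runif(n * (n - 1) / 2))
}

# random association table between two id sets
random_assoc <- function(left, right, p, seed) {
  set.seed(seed)
  grid <- expand.grid(left = left, right = right, stringsAsFactors = FALSE)
  grid[runif(nrow(grid)) < p, , drop = FALSE]
}

random_edges <- function(ids, p, seed) {
  set.seed(seed)
  n <- length(ids)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < p
  data.frame(from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
             stringsAsFactors = FALSE)
}

# a small random quadruple-layer network built directly from raw tables
random_het_network <- function(seed, n = 12, m = 5, l = 4, c = 3,
                               p_intra = 0.35, p_inter = 0.25,
                               with_evidence = TRUE) {
  set.seed(seed)
  g_ids <- sprintf("g%02d", seq_len(n))
  m_ids <- sprintf("m%02d", seq_len(m))
  l_ids <- sprintf("l%02d", seq_len(l))
  c_ids <- sprintf("c%02d", seq_len(c))
  ppi <- random_edges(g_ids, p_intra, seed + 1)
  pathway <- random_edges(g_ids, p_intra, seed + 2)
  merged <- merge_gene_networks(ppi, pathway)
  gene_net <- list(nodes = g_ids, edges = merged$edges)
  mk_net <- function(ids, s) list(nodes = ids, edges = random_edges(ids, 0.5, s))
  assemble_heterogeneous(
    gene_net, mk_net(m_ids, seed + 3), mk_net(l_ids, seed + 4),
    mk_net(c_ids, seed + 5),
    gene_mirna = random_assoc(g_ids, m_ids, p_inter, seed + 6),
    gene_lncrna = random_assoc(g_ids, l_ids, p_inter, seed + 7),
    gene_cancer = random_assoc(g_ids, c_ids, p_inter, seed + 8),
    mirna_lncrna = random_assoc(m_ids, l_ids, p_inter, seed + 9),
    mirna_cancer = random_assoc(m_ids, c_ids, p_inter, seed + 10),
    lncrna_cancer = random_assoc(l_ids, c_ids, p_inter, seed + 11),
    ppi = if (with_evidence) ppi, pathway = if (with_evidence) pathway)
}

# small planted fixture for fast end-to-end tests
small_fixture <- function(seed = 3) {
  generate_fixture(fixture_config(n_genes = 80L, n_mirna = 15L, n_lncrna = 15L,
                                  n_cancer = 4L, n_modules = 4L,
                                  module_size = 6L, seed = seed))
}

# brute-force RNA functional similarity (literal double loop)
brute_rna_similarity <- function(assoc, dsim, entities) {
  groups <- lapply(entities, function(e) unique(assoc[[2]][assoc[[1]] == e]))
  names(groups) <- entities
  S <- matrix(0, length(entities), length(entities),
              dimnames = list(entities, entities))
  for (i in seq_along(entities)) for (j in seq_along(entities)) {
    D1 <- groups[[i]]; D2 <- groups[[j]]
    if (!length(D1) || !length(D2)) next
    s <- 0
    for (d in D1) s <- s + max(dsim[d, D2])
    for (d in D2) s <- s + max(dsim[d, D1])
    S[i, j] <- s / (length(D1) + length(D2))
  }
  S
}

# brute-force complex feedback ratio per gene (literal loop)
brute_complex_ratio <- function(genes, complexes, cancer_genes) {
  ratio <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    best <- 0
    for (cpx in complexes) {
      if (!(g %in% cpx)) next
      best <- max(best, sum(cpx %in% cancer_genes) / length(cpx))
    }
    ratio[g] <- best
  }
  ratio
}

# brute-force rank score (literal double loop)
brute_rank_score <- function(scores) {
  n <- length(scores)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0
    for (j in seq_len(n)) if (j != i && scores[i] > scores[j]) cnt <- cnt + 1
    out[i] <- cnt / n
  }
  out
}
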