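adj <- function(edges, ids) {
  e <- if (length(edges)) {
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)],
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0))
  trwr:::edges_to_adjacency(e, ids)
}

test_that("row normalization preserves zero rows and rejects negatives", {
  A <- matrix(c(2, 2, 0, 0), 2, byrow = TRUE)
  expect_equal(as.matrix(row_normalize(A)), matrix(c(0.5, 0.5, 0, 0), 2, byrow = TRUE))
  expect_equal(as.matrix(row_normalize(diag(3))), diag(3))
  set.seed(1)
  B <- matrix(runif(25), 5)
  rs <- Matrix::rowSums(row_normalize(B))
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  expect_error(row_normalize(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("single-network transition splits rows by degree, zero for isolated nodes", {
  ids <- c("a", "b", "c", "z")
  A <- adj(c("a", "b", "b", "c"), ids)   # path a-b-c plus isolated z
  W <- single_network_transition(A)
  expect_equal(as.numeric(W["b", ]), c(0.5, 0, 0.5, 0))
  expect_equal(as.numeric(W["z", ]), rep(0, 4))
  star <- adj(c("h", "x1", "h", "x2", "h", "x3", "h", "x4"),
              c("h", "x1", "x2", "x3", "x4"))
  Ws <- single_network_transition(star)
  expect_equal(as.numeric(Ws["h", -1]), rep(0.25, 4))
})

test_that("membership count distinguishes both / one / neither network", {
  ids <- c("a", "b", "c")
  ppi <- adj(c("a", "b"), ids)
  pw <- adj(c("a", "c"), ids)
  expect_equal(membership_count(ppi, pw), c(2L, 1L, 1L))
  none <- adj(character(0), ids)
  expect_equal(membership_count(none, none), c(0L, 0L, 0L))
})

test_that("complex feedback ratio follows the worked examples", {
  ids <- sprintf("g%d", 1:5)
  G <- adj(c("g1", "g5", "g2", "g3"), ids)
  cpx <- complex_catalog(list(c("g1", "g2", "g3", "g4")))
  cw <- complex_weight(G, cpx, cancer_genes = c("g1", "g2"))
  expect_equal(cw$W_com["g1", "g5"], 0.5)     # 2 cancer genes of 4 members
  expect_equal(sum(cw$W_com["g5", ]), 0)      # g5 is in no complex
  # gene in two complexes takes the larger ratio
  cpx2 <- complex_catalog(list(c("g1", "g2", "g3", "g4"), c("g1", "g2")))
  cw2 <- complex_weight(G, cpx2, cancer_genes = c("g1", "g2"))
  expect_equal(unname(cw2$ratio["g1"]), 1.0)
  # empty cancer set zeroes the feedback; ratios stay in [0, 1]
  cw3 <- complex_weight(G, cpx2, cancer_genes = character(0))
  expect_equal(sum(cw3$W_com), 0)
  expect_true(all(cw2$ratio >= 0 & cw2$ratio <= 1))
})

test_that("complex members outside the index are ignored with optional warning", {
  ids <- c("g1", "g2")
  G <- adj(c("g1", "g2"), ids)
  cpx <- complex_catalog(list(c("g1", "g2", "ghost")))
  expect_warning(complex_weight(G, cpx, "g1"), "ignored")
  expect_silent(complex_weight(G, cpx, "g1", warn_missing = FALSE))
})

test_that("gene transition reduces to the single-network operator when evidence coincides", {
  ids <- sprintf("g%d", 1:6)
  net <- adj(c("g1", "g2", "g2", "g3", "g3", "g4", "g4", "g5", "g5", "g6"), ids)
  W_plain <- single_network_transition(net)
  W_G <- gene_transition(net, net, complexes = NULL)
  expect_equal(as.matrix(W_G), as.matrix(W_plain))
  W_G2 <- gene_transition(net, net, complexes = complex_catalog(list()))
  expect_equal(as.matrix(W_G2), as.matrix(W_plain))
})

test_that("gene transition averages PPI and pathway rows then renormalizes", {
  ids <- c("a", "b", "c", "d")
  ppi <- adj(c("a", "b", "a", "c"), ids)
  pw <- adj(c("a", "d"), ids)
  W_G <- gene_transition(ppi, pw, NULL)
  # a: PPI row (1/2, 1/2 over b,c) and pathway row (1 over d), averaged then
  # renormalized: (0.25, 0.25, 0.5)
  expect_equal(as.numeric(W_G["a", ]), c(0, 0.25, 0.25, 0.5))
  # b: PPI only (N = 1): row equals the PPI transition row
  expect_equal(as.numeric(W_G["b", ]), c(1, 0, 0, 0))
})

test_that("a cancer-enriched complex shifts mass toward complex-member neighbours", {
  ids <- sprintf("g%d", 1:6)
  # g1 has two neighbours: g2 (complex partner) and g5 (background)
  net <- adj(c("g1", "g2", "g1", "g5", "g2", "g3", "g5", "g6"), ids)
  base <- gene_transition(net, net, NULL)
  cpx <- complex_catalog(list(c("g2", "g3", "g4")))
  with_cpx <- gene_transition(net, net, cpx, cancer_genes = c("g3", "g4"))
  expect_gt(with_cpx["g2", "g1"], base["g2", "g1"] - 1e-15)
  # rows of genes in enriched complexes stay stochastic
  expect_equal(sum(with_cpx["g2", ]), 1)
})

test_that("the global transition is block-diagonal at delta 0 and splits delta otherwise", {
  net <- random_het_network(2)
  W0 <- global_transition(net, NULL, delta = 0)
  off <- net$index$offsets; sz <- net$index$sizes
  rng <- function(i) seq(off[i] + 1L, off[i] + sz[[i]])
  # nodes with intra-layer edges keep all mass in their layer at delta = 0;
  # intra-isolated nodes with couplings are re-routed out (reallocation rule)
  intra_ok <- c(Matrix::rowSums(net$intra$G) > 0, Matrix::rowSums(net$intra$M) > 0,
                Matrix::rowSums(net$intra$L) > 0, Matrix::rowSums(net$intra$C) > 0)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    blk <- W0$W[rng(i), rng(j), drop = FALSE]
    expect_equal(sum(blk[intra_ok[rng(i)], , drop = FALSE]), 0)
  }
  Wm <- as.matrix(W0$W[rng(2), rng(2)])
  Wm_exp <- as.matrix(single_network_transition(net$intra$M))
  ok <- intra_ok[rng(2)]
  expect_equal(unname(Wm[ok, ]), unname(Wm_exp[ok, ]))
  expect_error(global_transition(net, NULL, delta = 1.2), "delta")
})

test_that("rows with couplings to all three layers split delta in thirds", {
  net <- random_het_network(4, p_inter = 0.9)
  delta <- 0.5
  W <- global_transition(net, NULL, delta)$W
  idx <- net$index
  g <- idx$gene[1]
  stopifnot(Matrix::rowSums(net$inter$GM)[g] > 0,
            Matrix::rowSums(net$inter$GL)[g] > 0,
            Matrix::rowSums(net$inter$GC)[g] > 0)
  row <- W[g, ]
  mass <- function(layer_ids) sum(row[layer_ids])
  expect_equal(mass(idx$mirna), delta / 3)
  expect_equal(mass(idx$lncrna), delta / 3)
  expect_equal(mass(idx$cancer), delta / 3)
  expect_equal(mass(idx$gene), 1 - delta)
})

test_that("a node with no inter-layer couplings keeps full mass in its layer", {
  empty <- data.frame(a = character(0), b = character(0))
  net <- assemble_heterogeneous(
    list(nodes = c("g1", "g2"), edges = data.frame(from = "g1", to = "g2")),
    list(nodes = c("m1", "m2"), edges = data.frame(from = "m1", to = "m2")),
    list(nodes = c("l1", "l2"), edges = data.frame(from = "l1", to = "l2")),
    list(nodes = c("c1", "c2"), edges = data.frame(from = "c1", to = "c2")),
    empty, empty, gene_cancer = data.frame(g = "g1", c = "c1"),
    empty, empty, empty)
  W <- global_transition(net, NULL, delta = 0.5)$W
  expect_equal(as.numeric(W["g2", ]), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(sum(W["g1", c("m1", "m2", "l1", "l2")]), 0)
  expect_equal(W["g1", "c1"], 0.5)
})

test_that("every non-dangling row of the global transition sums to one", {
  for (s in 1:8) {
    net <- random_het_network(s * 13)
    for (delta in c(0, 0.25, 0.5, 1)) {
      W <- global_transition(net, NULL, delta)$W
      rs <- Matrix::rowSums(W)
      expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    }
  }
})
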