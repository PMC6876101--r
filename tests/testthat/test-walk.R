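test_that("walk parameter validation catches out-of-range values", {
  expect_error(walk_params(gamma = 1.5), "gamma")
  expect_error(walk_params(eta = c(0.5, 0.5, 0.5, 0.5)), "eta")
  expect_error(walk_params(eta = c(1, 0, 0)), "eta")
  expect_error(walk_params(tol = 0), "tol")
  p <- walk_params()
  expect_equal(p$delta, 0.5)
  expect_equal(p$eta, rep(0.25, 4))
  expect_equal(c(p$gamma, p$sigma, p$alpha), c(0.6, 0.6, 0.9))
})

test_that("restart mass is redistributed over seeded layers", {
  idx <- layer_index(c("g1", "g2", "g3"), "m1", "l1", c("c1", "c2"))
  # seeds in gene and cancer layers only: eta2 + eta3 redistributed
  p0 <- initial_probability(seed_set(gene_seeds = c("g1", "g2"),
                                     cancer_seeds = "c1"),
                            rep(0.25, 4), idx)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0[c("g1", "g2")]), c(0.25, 0.25))
  expect_equal(unname(p0["c1"]), 0.5)
  # one seed per layer at uniform eta
  p1 <- initial_probability(seed_set("g1", "m1", "l1", "c1"), rep(0.25, 4), idx)
  expect_equal(unname(p1[c("g1", "m1", "l1", "c1")]), rep(0.25, 4))
  # all mass on the gene layer
  p2 <- initial_probability(seed_set(gene_seeds = c("g1", "g2", "g3")),
                            c(1, 0, 0, 0), idx)
  expect_equal(unname(p2[1:3]), rep(1 / 3, 3))
  expect_equal(sum(p2[-(1:3)]), 0)
  # seeded layers all carry zero eta -> no valid restart vector
  expect_error(initial_probability(seed_set(mirna_seeds = "m1"),
                                   c(1, 0, 0, 0), idx),
               "restart mass")
})

test_that("restart probability one returns the initial vector", {
  net <- random_het_network(6)
  W <- global_transition(net, NULL, 0.5)
  p0 <- numeric(nrow(W$W)); names(p0) <- rownames(W$W)
  p0[1:4] <- 0.25
  out <- rwr(W, p0, gamma = 1)
  expect_equal(as.numeric(out), as.numeric(p0))
})

test_that("the iterative walk matches the direct linear solve", {
  # 3-node chain
  ids <- c("a", "b", "c")
  A <- trwr:::edges_to_adjacency(data.frame(from = c("a", "b"), to = c("b", "c")), ids)
  W <- single_network_transition(A)
  p0 <- c(1, 0, 0); names(p0) <- ids
  it <- rwr(W, p0, gamma = 0.5, tol = 1e-10)
  direct <- solve(diag(3) - 0.5 * t(as.matrix(W)), 0.5 * p0)
  expect_lt(max(abs(it - direct)), 1e-6)
  # random heterogeneous fixtures
  for (s in c(3, 9)) {
    net <- random_het_network(s)
    Wt <- global_transition(net, NULL, 0.5)$W
    n <- nrow(Wt)
    p0 <- rep(1 / n, n); names(p0) <- rownames(Wt)
    it <- rwr(Wt, p0, gamma = 0.6, tol = 1e-12, max_iter = 5000)
    direct <- solve(diag(n) - 0.4 * t(as.matrix(Wt)), 0.6 * p0)
    expect_lt(max(abs(it - direct)), 1e-10)
  }
})

test_that("probability is conserved on dangling-free operators", {
  net <- random_het_network(8, p_intra = 0.8, p_inter = 0.6)
  W <- global_transition(net, NULL, 0.5)$W
  expect_true(all(Matrix::rowSums(W) > 0))  # dense fixture has no dangling rows
  p0 <- rep(1 / nrow(W), nrow(W)); names(p0) <- rownames(W)
  out <- rwr(W, p0, gamma = 0.3, tol = 1e-12, max_iter = 5000)
  expect_lt(abs(sum(out) - 1), 1e-9)
})

test_that("the walk approaches the restart vector as gamma tends to one", {
  net <- random_het_network(12)
  W <- global_transition(net, NULL, 0.5)
  p0 <- numeric(nrow(W$W)); names(p0) <- rownames(W$W)
  p0[c(2, 5, 9)] <- 1 / 3
  dist <- vapply(c(0.9, 0.99, 0.999), function(g)
    sqrt(sum((rwr(W, p0, g, tol = 1e-12, max_iter = 5000) - p0)^2)), numeric(1))
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[3], 1e-2)
})

test_that("non-convergence raises an error carrying the residual", {
  net <- random_het_network(6)
  W <- global_transition(net, NULL, 0.5)
  p0 <- numeric(nrow(W$W)); names(p0) <- rownames(W$W); p0[1] <- 1
  expect_error(rwr(W, p0, gamma = 0.1, tol = 1e-14, max_iter = 2),
               "did not converge")
})

test_that("first round keeps the top sigma fraction of genes by stationary mass", {
  fx <- assemble_fixture(small_fixture())
  params <- walk_params(sigma = 1)
  fr <- first_round(fx$net, fx$complexes, params)
  expect_setequal(fr$topk, fx$net$index$gene)
  params2 <- walk_params(sigma = 0.5)
  fr2 <- first_round(fx$net, fx$complexes, params2)
  expect_length(fr2$topk, 40)
  pg <- sort(fr$P1[fx$net$index$gene], decreasing = TRUE)
  expect_setequal(fr2$topk, names(pg)[1:40])
})

test_that("planted module genes are over-represented in the screened top set", {
  b <- small_fixture()
  fx <- assemble_fixture(b)
  fr <- first_round(fx$net, fx$complexes, walk_params(sigma = 0.3))
  planted <- unique(b$ledger$gene)
  hits <- sum(fr$topk %in% planted)
  # hypergeometric upper tail: planted genes among the top 24 of 80
  pval <- phyper(hits - 1, length(planted), 80 - length(planted),
                 length(fr$topk), lower.tail = FALSE)
  expect_lt(pval, 1e-4)
})

test_that("second-round network restriction is the induced subgraph", {
  net <- random_het_network(21, n = 20)
  topk <- net$index$gene[c(1:5, 11:15)]
  sub <- build_second_round_network(net, topk)
  expect_equal(sub$index$gene, topk)
  expect_equal(sub$index$mirna, net$index$mirna)
  # brute-force induced-subgraph comparison
  Gd <- as.matrix(net$intra$G)[topk, topk]
  expect_equal(as.matrix(sub$intra$G), Gd)
  expect_equal(as.matrix(sub$inter$GM), as.matrix(net$inter$GM)[topk, ])
  # excluded genes leave no trace
  H <- block_adjacency(sub)
  expect_false(any(rownames(H) %in% setdiff(net$index$gene, topk)))
  # keeping everything is the identity
  all_sub <- build_second_round_network(net, net$index$gene)
  expect_equal(as.matrix(block_adjacency(all_sub)), as.matrix(block_adjacency(net)))
  expect_error(build_second_round_network(net, character(0)), "empty")
})

test_that("second round with full network and class-wide seeds reproduces round one", {
  # single cancer node: the disease-specific seed set IS the class-level one,
  # so with sigma = 1 the two rounds coincide exactly
  set.seed(17)
  g_ids <- sprintf("g%02d", 1:15)
  m_ids <- c("m1", "m2", "m3")
  l_ids <- c("l1", "l2", "l3")
  net <- assemble_heterogeneous(
    list(nodes = g_ids, edges = random_edges(g_ids, 0.3, 18)),
    list(nodes = m_ids, edges = data.frame(from = "m1", to = "m2")),
    list(nodes = l_ids, edges = data.frame(from = "l1", to = "l2")),
    list(nodes = "c1", edges = data.frame(from = character(0), to = character(0))),
    gene_mirna = data.frame(g = c("g01", "g02"), m = c("m1", "m2")),
    gene_lncrna = data.frame(g = "g03", l = "l1"),
    gene_cancer = data.frame(g = c("g01", "g04"), c = c("c1", "c1")),
    mirna_lncrna = data.frame(m = "m1", l = "l2"),
    mirna_cancer = data.frame(m = "m2", c = "c1"),
    lncrna_cancer = data.frame(l = "l2", c = "c1"))
  params <- walk_params(sigma = 1)
  fr <- first_round(net, NULL, params)
  sub <- build_second_round_network(net, fr$topk)
  P2 <- second_round(sub, NULL, params, "c1",
                     cancer_gene_set = cancer_associated(net)$gene)
  expect_equal(unname(P2[names(fr$P1)]), unname(as.numeric(fr$P1)),
               tolerance = 1e-10)
})

test_that("score fusion follows the alpha limits and direct arithmetic", {
  idx <- layer_index(c("g1", "g2", "g3"), "m1", "l1", "c1")
  P1 <- setNames(c(0.02, 0.05, 0.01, 0.3, 0.3, 0.32), c("g1", "g2", "g3", "m1", "l1", "c1"))
  P2 <- setNames(c(0.1, 0.2), c("g1", "g2"))   # g3 ejected in round one
  topk <- c("g1", "g2")
  expect_equal(unname(combine_scores(P1, P2, idx, topk, alpha = 1)),
               unname(P1[c("g1", "g2", "g3")]))
  s0 <- combine_scores(P1, P2, idx, topk, alpha = 0)
  expect_equal(unname(s0), c(0.1, 0.2, 0))
  s <- combine_scores(P1, P2, idx, topk, alpha = 0.9)
  expect_equal(unname(s["g1"]), 0.9 * 0.02 + 0.1 * 0.1)  # 0.028
  expect_error(combine_scores(P1, P2, idx, topk, alpha = 2), "alpha")
})

test_that("score conservation holds when no gene is ejected", {
  fx <- assemble_fixture(small_fixture())
  params <- walk_params(sigma = 1, alpha = 0.7)
  fr <- first_round(fx$net, fx$complexes, params)
  sub <- build_second_round_network(fx$net, fr$topk)
  P2 <- second_round(sub, fx$complexes, params, "can1",
                     cancer_gene_set = cancer_associated(fx$net)$gene)
  sc <- combine_scores(fr$P1, P2, fx$net$index, fr$topk, 0.7)
  genes <- fx$net$index$gene
  expect_equal(sum(sc), 0.7 * sum(fr$P1[genes]) + 0.3 * sum(P2[genes]))
})

test_that("prioritization is deterministic and ranks planted genes high", {
  b <- small_fixture()
  fx <- assemble_fixture(b)
  r1 <- prioritize(fx$net, fx$complexes, walk_params(), "can2")
  r2 <- prioritize(fx$net, fx$complexes, walk_params(), "can2")
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 80)
  planted <- b$ledger$gene[b$ledger$disease == "can2"]
  mean_rank_planted <- mean(match(planted, r1$gene))
  expect_lt(mean_rank_planted, 30)
})
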