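#' Rank score of a score vector
#'
#' The rank score of gene i is the fraction of the ranking population it
#' strictly outranks: count(Score(i) > Score(j), j != i) / n with n the size
#' of the population. Ties contribute nothing, so identical scores map to
#' identical rank scores and an all-tied vector maps to all zeros. The rank
#' score is invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric vector of scores (the ranking population).
#' @return numeric vector of values in \[0, (n-1)/n\].
#' @export
rank_score <- function(scores) {
  n <- length(scores)
  if (n < 1L) stop_("empty score vector")
  (rank(scores, ties.method = "min") - 1) / n
}

#' Leave-one-out cross-validation of gene prioritization
#'
#' For every known gene-cancer association (g, d): the association is removed,
#' gene g is removed from the class-level cancer gene set (used by the complex
#' feedback) and from every seed set, the prioritization pipeline is run for
#' disease d, and g's rank score is recorded against the candidate set
#' \{g\} union \{genes with no known association to d\}. Records whose disease
#' is left with no associated entities after the removal are skipped.
#'
#' Negative controls are the genes with no association to any cancer; their
#' rank scores in each record's candidate ranking are kept for ROC
#' construction.
#'
#' @param net a `het_network`.
#' @param complexes a [complex_catalog()] or `NULL`.
#' @param params a [walk_params()].
#' @param method `"trwr"` (two-round walk), `"rwr"` (single-layer gene-network
#'   baseline) or `"rwrh"` (two-layer gene + cancer baseline).
#' @param guard leakage guard. `"full"` (default) hides every cancer coupling
#'   of the held-out gene while it is evaluated, so the network carries no
#'   trace that it is cancer-associated and positives are structurally
#'   exchangeable with never-associated genes under a null; `"association"`
#'   removes only the held-out pair, leaving the gene's other cancer links in
#'   place (its rank then benefits from them).
#' @param progress print one line per 25 records to stderr.
#' @return a `loocv_result`: list with `records` (data.frame `disease`,
#'   `gene`, `rank_score`, `candidate_count`), `negatives` (never-associated
#'   gene ids), `neg_scores` (per-record rank scores of the negatives),
#'   `skipped` (count), `method`.
#' @export
loocv <- function(net, complexes, params, method = c("trwr", "rwr", "rwrh"),
                  guard = c("full", "association"), progress = FALSE) {
  method <- match.arg(method)
  guard <- match.arg(guard)
  idx <- net$index
  GC <- net$inter$GC
  pairs <- which(as.matrix(GC > 0), arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop_("no gene-cancer associations to cross-validate")
  negatives <- idx$gene[Matrix::rowSums(GC) == 0]
  records <- vector("list", nrow(pairs))
  neg_scores <- vector("list", nrow(pairs))
  skipped <- 0L
  o <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[o, , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    g <- idx$gene[pairs[r, 1L]]
    d <- idx$cancer[pairs[r, 2L]]
    scores <- tryCatch(
      holdout_scores(net, complexes, params, g, d, method, guard),
      trwr_skip = function(e) NULL)
    if (is.null(scores)) { skipped <- skipped + 1L; next }
    candidates <- union(g, idx$gene[GC[, d] == 0])
    rs <- rank_score(scores[candidates])
    names(rs) <- candidates
    records[[r]] <- data.frame(disease = d, gene = g,
                               rank_score = unname(rs[g]),
                               candidate_count = length(candidates),
                               stringsAsFactors = FALSE)
    neg_scores[[r]] <- rs[negatives]
    if (progress && r %% 25L == 0L)
      message(sprintf("loocv [%s]: %d/%d records", method, r, nrow(pairs)))
  }
  done <- !vapply(records, is.null, logical(1))
  structure(list(records = do.call(rbind, records[done]),
                 negatives = negatives,
                 neg_scores = neg_scores[done],
                 skipped = skipped, method = method, guard = guard),
            class = "loocv_result")
}

# per-gene score vector for one hold-out record, or a "trwr_skip" condition
holdout_scores <- function(net, complexes, params, g, d, method, guard = "full") {
  idx <- net$index
  net2 <- net
  if (guard == "full") net2$inter$GC[g, ] <- 0 else net2$inter$GC[g, d] <- 0
  remaining <- sum(net2$inter$GC[, d] > 0) +
    sum(net$inter$MC[, d] > 0) + sum(net$inter$LC[, d] > 0)
  if (remaining == 0L)
    stop(structure(class = c("trwr_skip", "condition"),
                   list(message = "disease has no remaining evidence", call = NULL)))
  if (method == "trwr") {
    assoc <- cancer_associated(net2)
    cgs <- setdiff(assoc$gene, g)
    fr <- first_round_excluding(net2, complexes, params, cgs, g)
    subnet <- build_second_round_network(net2, fr$topk)
    P2 <- tryCatch(
      second_round(subnet, complexes, params, d, cgs),
      error = function(e)
        stop(structure(class = c("trwr_skip", "condition"),
                       list(message = conditionMessage(e), call = NULL))))
    return(combine_scores(fr$P1, P2, idx, fr$topk, params$alpha))
  }
  if (method == "rwr") {
    seeds <- setdiff(idx$gene[net2$inter$GC[, d] > 0], g)
    if (!length(seeds))
      stop(structure(class = c("trwr_skip", "condition"),
                     list(message = "no gene seeds", call = NULL)))
    W <- single_network_transition(net$intra$G)
    p0 <- numeric(length(idx$gene)); names(p0) <- idx$gene
    p0[seeds] <- 1 / length(seeds)
    p <- rwr(W, p0, params$gamma, params$tol, params$max_iter)
    return(p)
  }
  # rwrh: gene + cancer bilayer
  seeds_g <- setdiff(idx$gene[net2$inter$GC[, d] > 0], g)
  W <- bilayer_transition(net2, params$delta)
  w_g <- params$eta[1L]; w_c <- params$eta[4L]
  if (!length(seeds_g)) { w_g <- 0; w_c <- 1 }
  tot <- w_g + w_c
  p0 <- numeric(length(idx$gene) + length(idx$cancer))
  names(p0) <- c(idx$gene, idx$cancer)
  if (length(seeds_g)) p0[seeds_g] <- (w_g / tot) / length(seeds_g)
  p0[d] <- w_c / tot
  p <- rwr(W, p0, params$gamma, params$tol, params$max_iter)
  p[idx$gene]
}

# first round with one gene excluded from every seed list
first_round_excluding <- function(net, complexes, params, cancer_gene_set, g) {
  assoc <- cancer_associated(net)
  ev <- gene_evidence(net)
  W_G <- gene_transition(ev$ppi, ev$pathway, complexes, cancer_gene_set,
                         warn_missing = FALSE)
  W <- global_transition(net, W_G, params$delta)
  seeds <- seed_set(setdiff(assoc$gene, g), setdiff(assoc$mirna, g),
                    setdiff(assoc$lncrna, g), net$index$cancer)
  p0 <- initial_probability(seeds, params$eta, net$index)
  P1 <- rwr(W, p0, params$gamma, params$tol, params$max_iter)
  genes <- net$index$gene
  k <- max(1L, as.integer(round(params$sigma * length(genes))))
  ord <- order(-P1[genes], genes)
  list(P1 = P1, topk = genes[ord[seq_len(k)]])
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result [%s]: %d records (%d skipped), %d negative genes\n",
              x$method, nrow(x$records), x$skipped, length(x$negatives)))
  invisible(x)
}

#' ROC curve from positive and negative scores
#'
#' Sweeps a threshold over the pooled unique scores (ties grouped at one
#' threshold) classifying `score >= threshold` as positive; TPR/FPR per
#' threshold, area by the trapezoid rule.
#'
#' @param pos,neg numeric score vectors of positive and negative observations.
#' @return list with `thresholds`, `tpr`, `fpr` (both nondecreasing along the
#'   sweep) and `auc`.
#' @export
roc_curve <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop_("need at least one positive and one negative")
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr); th <- c(Inf, th)
  if (tpr[length(tpr)] < 1 || fpr[length(fpr)] < 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1); th <- c(th, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc)
}

#' ROC/AUC of a cross-validation run
#'
#' Positives are the held-out genes' rank scores; negatives are the rank
#' scores of the genes never associated with any cancer, pooled over all
#' records.
#'
#' @param result a [loocv()] result.
#' @return list as in [roc_curve()].
#' @export
roc_auc <- function(result) {
  pos <- result$records$rank_score
  neg <- unlist(result$neg_scores, use.names = FALSE)
  if (!length(neg)) stop_("no negative genes in this fixture")
  roc_curve(pos, neg)
}

#' Null-calibration rank statistic of the held-out genes
#'
#' For each record, the standing of the held-out gene within its exchangeable
#' reference population: the genes with no association to any cancer. With the
#' full leakage guard the network carries no trace of the held-out gene's
#' label during its evaluation, so under a label-shuffled (null) fixture the
#' held-out gene is exchangeable with the never-associated genes and this
#' statistic is uniform on \[0, 1\]. (The raw per-record rank score over the
#' whole candidate set is NOT uniform under the null: candidates associated
#' with other cancers are first-round seeds and systematically occupy the top
#' of every ranking, truncating the rank-score distribution at about one minus
#' the seeded fraction of candidates.)
#'
#' @param result a [loocv()] result.
#' @return numeric vector, one value per record: the fraction of negatives the
#'   held-out gene outranks (ties counted half).
#' @export
holdout_null_ranks <- function(result) {
  mapply(function(ho, negs) {
    (sum(negs < ho) + 0.5 * sum(negs == ho) + 0.5) / (length(negs) + 1)
  }, result$records$rank_score, result$neg_scores)
}

#' Exchangeable null controls for the hold-out calibration
#'
#' Runs the identical hold-out machinery on genes that have no association to
#' any cancer: each control (gene, disease) pair is evaluated exactly like a
#' held-out association (full leakage guard, same pipeline, same candidate
#' ranking) and its standing among the remaining never-associated genes is
#' returned. Because a control gene is by construction exchangeable with the
#' negative panel, these values calibrate the null distribution of
#' [holdout_null_ranks()] on the same fixture, including the dependence the
#' records share through the common network and negative panel (which makes
#' the raw one-sample uniformity test over-reject).
#'
#' @inheritParams loocv
#' @param n_controls number of control evaluations.
#' @param seed seed for sampling the control pairs.
#' @return numeric vector of `n_controls` null rank statistics.
#' @export
exchangeable_null_ranks <- function(net, complexes, params, n_controls = 150L,
                                    method = "trwr", seed = 1L) {
  idx <- net$index
  GC <- net$inter$GC
  negs <- idx$gene[Matrix::rowSums(GC) == 0]
  if (length(negs) < 2L) stop_("need at least two never-associated genes")
  ctl <- with_seed(seed, data.frame(
    gene = sample(negs, n_controls, replace = TRUE),
    disease = sample(idx$cancer, n_controls, replace = TRUE),
    stringsAsFactors = FALSE))
  u <- numeric(n_controls)
  for (r in seq_len(n_controls)) {
    g <- ctl$gene[r]; d <- ctl$disease[r]
    sc <- holdout_scores(net, complexes, params, g, d, method, "full")
    cand <- union(g, idx$gene[GC[, d] == 0])
    rs <- rank_score(sc[cand]); names(rs) <- cand
    others <- setdiff(negs, g)
    u[r] <- (sum(rs[others] < rs[g]) + 0.5 * sum(rs[others] == rs[g]) + 0.5) /
      (length(others) + 1)
  }
  u
}

#' Held-out genes recovered in the top k percent
#'
#' A record counts for level k when its held-out gene sits within the top k%
#' of its candidate ranking, i.e. when 1 - rank_score <= k / 100.
#'
#' @param result a [loocv()] result.
#' @param k_percent numeric vector of percentage levels.
#' @return named integer vector of counts per level.
#' @export
topk_counts <- function(result, k_percent = c(5, 7, 10, 15)) {
  rs <- result$records$rank_score
  counts <- vapply(k_percent, function(k) sum(1 - rs <= k / 100 + 1e-12), numeric(1))
  stats::setNames(as.integer(counts), paste0("top", k_percent))
}

# two-layer (gene + cancer) transition for the RWRH baseline
bilayer_transition <- function(net, delta) {
  Wg <- single_network_transition(net$intra$G)
  Wc <- single_network_transition(net$intra$C)
  Wgc <- row_normalize(net$inter$GC)
  Wcg <- row_normalize(Matrix::t(net$inter$GC))
  s_g <- Matrix::rowSums(Wg) > 0; c_g <- Matrix::rowSums(Wgc) > 0
  s_c <- Matrix::rowSums(Wc) > 0; c_c <- Matrix::rowSums(Wcg) > 0
  wi_g <- ifelse(s_g, ifelse(c_g, 1 - delta, 1), 0)
  wx_g <- ifelse(c_g, ifelse(s_g, delta, 1), 0)
  wi_c <- ifelse(s_c, ifelse(c_c, 1 - delta, 1), 0)
  wx_c <- ifelse(c_c, ifelse(s_c, delta, 1), 0)
  W <- rbind(cbind(Diagonal(x = wi_g) %*% Wg, Diagonal(x = wx_g) %*% Wgc),
             cbind(Diagonal(x = wx_c) %*% Wcg, Diagonal(x = wi_c) %*% Wc))
  ids <- c(net$index$gene, net$index$cancer)
  dimnames(W) <- list(ids, ids)
  W
}
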