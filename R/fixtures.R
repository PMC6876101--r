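#' Configuration of a synthetic fixture
#'
#' Describes a synthetic quadruple-layer dataset with planted cancer-gene
#' signal: a modular gene network (Erdos-Renyi background with edge-enriched
#' planted modules, split into overlapping PPI and pathway evidence), one
#' planted disease per module, gene/miRNA/lncRNA associations to the planted
#' disease at the signal rate plus uniform association noise, cancer-enriched
#' protein complexes, and a disease similarity matrix with high within-group,
#' low between-group similarity.
#'
#' Default sizes and rates are the conditions used throughout the package's
#' validation: 300 genes, 40 miRNAs, 40 lncRNAs and 6 cancers; six planted
#' 10-gene modules with a 5-fold within-module edge enrichment over a
#' mean-degree-4 background; association signal 0.8 and per-pair association
#' noise 0.005, so that spurious associations contaminate roughly 15% of the
#' gene-cancer table (the per-pair noise rate multiplies the full n x c pair
#' space, so it must stay well below signal x module_size / n).
#'
#' @param n_genes,n_mirna,n_lncrna,n_cancer layer sizes.
#' @param n_modules,module_size planted disease modules (one per cancer up to
#'   `n_cancer`).
#' @param mean_degree expected background degree of the gene network.
#' @param enrichment multiplier on the background edge probability inside a
#'   planted module (1 = no enrichment).
#' @param signal probability that a planted entity is associated with (or, for
#'   RNA-gene pairs, interacts with) its module's disease/genes.
#' @param noise probability of a uniform random association for any pair.
#' @param n_complexes,complex_size_range,complex_enriched_frac protein-complex
#'   catalog: count, size range, and the fraction of complexes drawn from a
#'   planted module (the rest are random background complexes).
#' @param knn_cancer,knn_mirna,knn_lncrna k of the per-layer k-nearest-
#'   neighbour similarity networks.
#' @param seed integer seed controlling all randomness of the generator.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 300L, n_mirna = 40L, n_lncrna = 40L,
                           n_cancer = 6L, n_modules = 6L, module_size = 10L,
                           mean_degree = 4, enrichment = 5, signal = 0.8,
                           noise = 0.005, n_complexes = 20L,
                           complex_size_range = c(3L, 6L),
                           complex_enriched_frac = 0.5,
                           knn_cancer = 3L, knn_mirna = 10L, knn_lncrna = 10L,
                           seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna), n_cancer = as.integer(n_cancer),
              n_modules = as.integer(n_modules), module_size = as.integer(module_size),
              mean_degree = mean_degree, enrichment = enrichment,
              signal = signal, noise = noise,
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              complex_enriched_frac = complex_enriched_frac,
              knn_cancer = as.integer(knn_cancer), knn_mirna = as.integer(knn_mirna),
              knn_lncrna = as.integer(knn_lncrna), seed = as.integer(seed))
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop_("planted modules do not fit into the gene layer")
  if (cfg$n_modules > cfg$n_cancer)
    stop_("need at least one cancer per planted module")
  for (p in c("signal", "noise", "complex_enriched_frac")) assert_prob(cfg[[p]], p)
  if (cfg$enrichment < 0) stop_("'enrichment' must be nonnegative")
  structure(cfg, class = "fixture_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_pairs <- function(left, right, prob) {
  if (prob <= 0 || !length(left) || !length(right))
    return(data.frame(left = character(0), right = character(0),
                      stringsAsFactors = FALSE))
  grid <- expand.grid(left = left, right = right, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid[stats::runif(nrow(grid)) < prob, , drop = FALSE]
}

#' Generate a synthetic fixture bundle
#'
#' Deterministic given `config$seed`. See [fixture_config()] for the generative
#' model. The bundle contains every raw input of the pipeline (edge lists,
#' association tables, disease similarity matrix, complex catalog) plus the
#' ground-truth ledger of planted gene-disease pairs.
#'
#' @param config a [fixture_config()].
#' @return a `fixture_bundle` list: `gene_ids`, `mirna_ids`, `lncrna_ids`,
#'   `cancer_ids`, `ppi`, `pathway` (edge data.frames), `gene_cancer`,
#'   `mirna_cancer`, `lncrna_cancer`, `mirna_gene`, `lncrna_gene`,
#'   `mirna_lncrna` (association data.frames), `dsim` (disease similarity
#'   matrix), `complexes` (list), `ledger` (planted gene-disease data.frame),
#'   `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    pad <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
    genes <- pad("g", cfg$n_genes)
    mirnas <- pad("mir", cfg$n_mirna)
    lncrnas <- pad("lnc", cfg$n_lncrna)
    cancers <- sprintf("can%d", seq_len(cfg$n_cancer))

    # planted modules: disjoint gene blocks, module i tied to cancer i
    module_of_gene <- rep(NA_integer_, cfg$n_genes)
    planted <- sample(cfg$n_genes, cfg$n_modules * cfg$module_size)
    module_of_gene[planted] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
    ledger <- data.frame(gene = genes[planted],
                         disease = cancers[module_of_gene[planted]],
                         stringsAsFactors = FALSE)
    ledger <- ledger[order(ledger$gene), , drop = FALSE]

    # gene network: background density + within-module enrichment
    p0 <- min(1, cfg$mean_degree / (cfg$n_genes - 1))
    ut <- which(upper.tri(matrix(0, cfg$n_genes, cfg$n_genes)), arr.ind = TRUE)
    m1 <- module_of_gene[ut[, 1L]]; m2 <- module_of_gene[ut[, 2L]]
    same_module <- !is.na(m1) & !is.na(m2) & m1 == m2
    p_edge <- ifelse(same_module, pmin(1, cfg$enrichment * p0), p0)
    keep <- stats::runif(nrow(ut)) < p_edge
    e_i <- ut[keep, 1L]; e_j <- ut[keep, 2L]
    # split union edges into overlapping PPI / pathway evidence
    src <- sample(c("ppi", "pathway", "both"), length(e_i), replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    edge_df <- function(sel) data.frame(from = genes[e_i[sel]], to = genes[e_j[sel]],
                                        stringsAsFactors = FALSE)
    ppi <- edge_df(src != "pathway")
    pathway <- edge_df(src != "ppi")

    # disease similarity: two super-groups of cancers
    group <- rep(seq_len(2L), length.out = cfg$n_cancer)
    dsim <- matrix(0, cfg$n_cancer, cfg$n_cancer, dimnames = list(cancers, cancers))
    for (i in seq_len(cfg$n_cancer)) for (j in seq_len(cfg$n_cancer)) {
      if (j <= i) next
      dsim[i, j] <- dsim[j, i] <- if (group[i] == group[j])
        stats::runif(1, 0.6, 0.9) else stats::runif(1, 0.05, 0.3)
    }
    diag(dsim) <- 1

    # associations: planted signal + uniform noise
    assoc <- function(planted_pairs, left, right) {
      noise <- sample_pairs(left, right, cfg$noise)
      out <- unique(rbind(planted_pairs, noise))
      out <- out[order(out[[1L]], out[[2L]]), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    planted_assoc <- function(left_by_module, right_by_module) {
      pairs <- do.call(rbind, lapply(seq_len(cfg$n_modules), function(mod) {
        l <- left_by_module[[mod]]
        r <- right_by_module[[mod]]
        grid <- expand.grid(left = l, right = r, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        grid[stats::runif(nrow(grid)) < cfg$signal, , drop = FALSE]
      }))
      pairs %||% data.frame(left = character(0), right = character(0))
    }
    genes_by_module <- lapply(seq_len(cfg$n_modules),
                              function(mod) genes[which(module_of_gene == mod)])
    cancers_by_module <- lapply(seq_len(cfg$n_modules), function(mod) cancers[mod])
    mirna_module <- rep(seq_len(cfg$n_modules), length.out = cfg$n_mirna)
    lnc_module <- rep(seq_len(cfg$n_modules), length.out = cfg$n_lncrna)
    mirnas_by_module <- lapply(seq_len(cfg$n_modules),
                               function(mod) mirnas[mirna_module == mod])
    lnc_by_module <- lapply(seq_len(cfg$n_modules),
                            function(mod) lncrnas[lnc_module == mod])

    gene_cancer <- assoc(planted_assoc(genes_by_module, cancers_by_module),
                         genes, cancers)
    mirna_cancer <- assoc(planted_assoc(mirnas_by_module, cancers_by_module),
                          mirnas, cancers)
    lncrna_cancer <- assoc(planted_assoc(lnc_by_module, cancers_by_module),
                           lncrnas, cancers)
    mirna_gene <- assoc(planted_assoc(mirnas_by_module, genes_by_module),
                        mirnas, genes)
    lncrna_gene <- assoc(planted_assoc(lnc_by_module, genes_by_module),
                         lncrnas, genes)
    mirna_lncrna <- assoc(planted_assoc(mirnas_by_module, lnc_by_module),
                          mirnas, lncrnas)

    # protein complexes: a fraction drawn from planted modules, rest background
    complexes <- lapply(seq_len(cfg$n_complexes), function(i) {
      s <- sample(seq(cfg$complex_size_range[1L], cfg$complex_size_range[2L]), 1L)
      if (stats::runif(1) < cfg$complex_enriched_frac && cfg$enrichment > 1) {
        mod <- sample(cfg$n_modules, 1L)
        core <- sample(genes_by_module[[mod]], min(s - 1L, cfg$module_size))
        rest <- sample(setdiff(genes, core), max(0L, s - length(core)))
        c(core, rest)
      } else {
        sample(genes, s)
      }
    })

    names(gene_cancer) <- names(mirna_cancer) <- names(lncrna_cancer) <-
      c("entity", "disease")
    names(mirna_gene) <- c("mirna", "gene")
    names(lncrna_gene) <- c("lncrna", "gene")
    names(mirna_lncrna) <- c("mirna", "lncrna")

    structure(list(gene_ids = genes, mirna_ids = mirnas, lncrna_ids = lncrnas,
                   cancer_ids = cancers, ppi = ppi, pathway = pathway,
                   gene_cancer = gene_cancer, mirna_cancer = mirna_cancer,
                   lncrna_cancer = lncrna_cancer, mirna_gene = mirna_gene,
                   lncrna_gene = lncrna_gene, mirna_lncrna = mirna_lncrna,
                   dsim = dsim, complexes = complexes, ledger = ledger,
                   config = cfg),
              class = "fixture_bundle")
  })
}

#' Matched no-signal fixture
#'
#' Same layer sizes and generative machinery with every signal parameter at
#' its null value: association signal 0, no module edge enrichment, no
#' cancer-enriched complexes. Associations are pure uniform noise, so held-out
#' genes carry no recoverable signal; used for AUC-near-0.5 calibration. The
#' default noise rate 0.15 yields a few hundred gene-cancer associations under
#' the default layer sizes so that calibration runs have enough records.
#'
#' @param config a [fixture_config()]; its signal parameters are overridden.
#' @return a `fixture_bundle`.
#' @export
null_fixture <- function(config = fixture_config(noise = 0.15)) {
  config$signal <- 0
  config$enrichment <- 1
  config$complex_enriched_frac <- 0
  generate_fixture(config)
}

#' Permute the gene labels of the gene-cancer associations
#'
#' Replaces each gene in the gene-cancer table by a uniformly resampled gene,
#' breaking any relation between association labels and network topology while
#' keeping the number of associations; the ledger is dropped. Used for null
#' calibration of held-out rank scores.
#'
#' @param bundle a `fixture_bundle`.
#' @param seed integer seed for the permutation.
#' @return the modified bundle.
#' @export
shuffle_gene_associations <- function(bundle, seed = 1L) {
  with_seed(seed, {
    n <- nrow(bundle$gene_cancer)
    shuffled <- data.frame(entity = sample(bundle$gene_ids, n, replace = TRUE),
                           disease = bundle$gene_cancer$disease,
                           stringsAsFactors = FALSE)
    shuffled <- unique(shuffled)
    bundle$gene_cancer <- shuffled[order(shuffled$entity, shuffled$disease), ,
                                   drop = FALSE]
    bundle$ledger <- NULL
    bundle
  })
}

#' Assemble a fixture bundle into a heterogeneous network
#'
#' Merges the PPI and pathway edge lists, computes the miRNA and lncRNA
#' functional similarity matrices from their disease associations and the
#' disease similarity matrix, builds the three k-nearest-neighbour similarity
#' networks, and assembles the quadruple-layer network.
#'
#' @param bundle a `fixture_bundle` (or anything with the same fields).
#' @return list with `net` (a `het_network`) and `complexes` (a
#'   [complex_catalog()]).
#' @export
assemble_fixture <- function(bundle) {
  cfg <- bundle$config
  merged <- merge_gene_networks(bundle$ppi, bundle$pathway)
  gene_net <- list(nodes = bundle$gene_ids, edges = merged$edges)
  msim <- rna_similarity_matrix(bundle$mirna_cancer, bundle$dsim, bundle$mirna_ids)
  lsim <- rna_similarity_matrix(bundle$lncrna_cancer, bundle$dsim, bundle$lncrna_ids)
  mirna_net <- build_knn_network(bundle$mirna_ids, msim,
                                 min(cfg$knn_mirna, length(bundle$mirna_ids) - 1L))
  lncrna_net <- build_knn_network(bundle$lncrna_ids, lsim,
                                  min(cfg$knn_lncrna, length(bundle$lncrna_ids) - 1L))
  cancer_net <- build_knn_network(bundle$cancer_ids, bundle$dsim,
                                  min(cfg$knn_cancer, length(bundle$cancer_ids) - 1L))
  net <- assemble_heterogeneous(
    gene_net, mirna_net, lncrna_net, cancer_net,
    gene_mirna = bundle$mirna_gene[, c("gene", "mirna")],
    gene_lncrna = bundle$lncrna_gene[, c("gene", "lncrna")],
    gene_cancer = bundle$gene_cancer,
    mirna_lncrna = bundle$mirna_lncrna,
    mirna_cancer = bundle$mirna_cancer,
    lncrna_cancer = bundle$lncrna_cancer,
    ppi = bundle$ppi, pathway = bundle$pathway)
  list(net = net, complexes = complex_catalog(bundle$complexes))
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(paste0("fixture_bundle: %d genes, %d miRNAs, %d lncRNAs, %d cancers; ",
                     "%d gene-cancer associations, %d planted pairs (seed %d)\n"),
              length(x$gene_ids), length(x$mirna_ids), length(x$lncrna_ids),
              length(x$cancer_ids), nrow(x$gene_cancer),
              if (is.null(x$ledger)) 0L else nrow(x$ledger), x$config$seed))
  invisible(x)
}
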