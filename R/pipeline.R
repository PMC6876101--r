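#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key value` separated by tabs); blank
#' lines and lines starting with `#` are ignored. Values that parse as numbers
#' are converted. Recognized keys: the walk parameters (`delta`, `eta1` ..
#' `eta4`, `gamma`, `sigma`, `alpha`, `tol`, `max_iter`), the kNN sizes
#' (`knn_cancer`, `knn_mirna`, `knn_lncrna`), and input paths (`ppi`,
#' `pathway`, `disease_similarity`, `gene_cancer`, `mirna_cancer`,
#' `lncrna_cancer`, `mirna_gene`, `lncrna_gene`, `mirna_lncrna`, `complexes`),
#' either absolute or relative to `input_dir`.
#'
#' @param path configuration file.
#' @param overrides named list applied on top of the file's values.
#' @return named list of configuration values.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_(sprintf("config file not found: %s", path))
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(sub("=", "\x01", ln), "\x01", fixed = TRUE)[[1L]]
      if (length(kv) == 1L) kv <- strsplit(ln, "[ \t]+")[[1L]][1:2]
      key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  utils::modifyList(cfg, overrides)
}

config_params <- function(cfg) {
  eta <- c(cfg$eta1 %||% 0.25, cfg$eta2 %||% 0.25,
           cfg$eta3 %||% 0.25, cfg$eta4 %||% 0.25)
  walk_params(delta = cfg$delta %||% 0.5, eta = eta,
              gamma = cfg$gamma %||% 0.6, sigma = cfg$sigma %||% 0.6,
              alpha = cfg$alpha %||% 0.9, tol = cfg$tol %||% 1e-6,
              max_iter = cfg$max_iter %||% 1000L)
}

input_keys <- c("ppi", "pathway", "disease_similarity", "gene_cancer",
                "mirna_cancer", "lncrna_cancer", "mirna_gene", "lncrna_gene",
                "mirna_lncrna", "complexes")

resolve_inputs <- function(cfg) {
  dir <- cfg$input_dir %||% "."
  paths <- lapply(input_keys, function(k) {
    p <- cfg[[k]] %||% paste0(k, ".tsv")
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dir, p)
    p
  })
  names(paths) <- input_keys
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing))
    stop_(sprintf("missing input file(s): %s",
                  paste(unlist(paths[missing]), collapse = ", ")))
  paths
}

#' Load pipeline inputs described by a configuration
#'
#' Reads the ten TSV inputs, builds the RNA/cancer similarity networks and
#' assembles the heterogeneous network. All input files are checked for
#' existence before any computation.
#'
#' @param cfg configuration list (see [read_config()]).
#' @return list with `net`, `complexes` and `paths`.
#' @export
load_inputs <- function(cfg) {
  paths <- resolve_inputs(cfg)
  ppi <- read_edge_list(paths$ppi)
  pathway <- read_edge_list(paths$pathway)
  dsim <- read_disease_similarity(paths$disease_similarity)
  gene_cancer <- read_association_table(paths$gene_cancer)
  mirna_cancer <- read_association_table(paths$mirna_cancer)
  lncrna_cancer <- read_association_table(paths$lncrna_cancer)
  mirna_gene <- read_association_table(paths$mirna_gene)
  lncrna_gene <- read_association_table(paths$lncrna_gene)
  mirna_lncrna <- read_association_table(paths$mirna_lncrna)
  complexes <- complex_catalog(read_complexes(paths$complexes))

  merged <- merge_gene_networks(ppi, pathway)
  genes <- sort(unique(c(merged$nodes, mirna_gene[[2L]], lncrna_gene[[2L]],
                         gene_cancer[[1L]])))
  mirnas <- sort(unique(c(mirna_cancer[[1L]], mirna_gene[[1L]], mirna_lncrna[[1L]])))
  lncrnas <- sort(unique(c(lncrna_cancer[[1L]], lncrna_gene[[1L]], mirna_lncrna[[2L]])))
  cancers <- rownames(dsim)
  orphan <- setdiff(unique(unlist(complexes$complexes)), genes)
  if (length(orphan))
    warning(sprintf("%d complex member gene(s) absent from the assembled gene layer",
                    length(orphan)), call. = FALSE)
  msim <- rna_similarity_matrix(mirna_cancer, dsim, mirnas)
  lsim <- rna_similarity_matrix(lncrna_cancer, dsim, lncrnas)
  k_of <- function(k, n) max(1L, min(as.integer(k), n - 1L))
  mirna_net <- build_knn_network(mirnas, msim, k_of(cfg$knn_mirna %||% 10L, length(mirnas)))
  lncrna_net <- build_knn_network(lncrnas, lsim, k_of(cfg$knn_lncrna %||% 10L, length(lncrnas)))
  cancer_net <- build_knn_network(cancers, dsim, k_of(cfg$knn_cancer %||% 3L, length(cancers)))
  net <- assemble_heterogeneous(
    list(nodes = genes, edges = merged$edges), mirna_net, lncrna_net, cancer_net,
    gene_mirna = mirna_gene[, 2:1], gene_lncrna = lncrna_gene[, 2:1],
    gene_cancer = gene_cancer, mirna_lncrna = mirna_lncrna,
    mirna_cancer = mirna_cancer, lncrna_cancer = lncrna_cancer,
    ppi = ppi, pathway = pathway)
  list(net = net, complexes = complexes, paths = paths)
}

run_manifest <- function(cfg, paths, timings, outputs, out_dir) {
  manifest <- list(
    config = cfg,
    inputs = as.list(tools::md5sum(unlist(paths))),
    version = as.character(utils::packageVersion("trwr")),
    timings_sec = timings,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the two-round prioritization for one cancer
#'
#' Assembles the network from the configured inputs, runs both walk rounds for
#' `disease`, and writes the per-gene score table (`gene`, `P1`, `P2`,
#' `score`, `rank_score`) plus a run manifest with input checksums and
#' per-stage timings.
#'
#' @param config path to a configuration file, or a configuration list.
#' @param disease cancer identifier to prioritize for.
#' @param out_dir output directory (default `trwr_out`, from the config key
#'   `out_dir` when set).
#' @return the score table, invisibly.
#' @export
run_prioritize <- function(config, disease, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% "trwr_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  t0 <- proc.time()[["elapsed"]]
  inputs <- load_inputs(cfg)
  timings["load"] <- proc.time()[["elapsed"]] - t0
  params <- config_params(cfg)
  t0 <- proc.time()[["elapsed"]]
  scores <- prioritize(inputs$net, inputs$complexes, params, disease)
  timings["walk"] <- proc.time()[["elapsed"]] - t0
  out <- file.path(out_dir, sprintf("scores_%s.tsv", disease))
  utils::write.table(scores, out, sep = "\t", quote = FALSE, row.names = FALSE)
  run_manifest(cfg, inputs$paths, as.list(timings), list(scores = out), out_dir)
  invisible(scores)
}

#' Run leave-one-out cross-validation from a configuration
#'
#' Writes the per-record TSV (`disease`, `gene`, `rank_score`,
#' `candidate_count`), the ROC curve TSV (`threshold`, `fpr`, `tpr`) and a
#' JSON summary with the AUC and top-k% counts.
#'
#' @inheritParams run_prioritize
#' @param method prioritization method, see [loocv()].
#' @param k_percent levels of the top-k% summary.
#' @return list with `records`, `roc`, `auc`, `topk`, invisibly.
#' @export
run_loocv <- function(config, out_dir = NULL, method = "trwr",
                      k_percent = c(5, 7, 10, 15)) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% "trwr_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(cfg)
  params <- config_params(cfg)
  t0 <- proc.time()[["elapsed"]]
  res <- loocv(inputs$net, inputs$complexes, params, method = method)
  timing <- proc.time()[["elapsed"]] - t0
  roc <- roc_auc(res)
  counts <- topk_counts(res, k_percent)
  rec_path <- file.path(out_dir, "loocv_records.tsv")
  utils::write.table(res$records, rec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roc_path <- file.path(out_dir, "roc.tsv")
  utils::write.table(
    data.frame(threshold = roc$thresholds,
               fpr = roc$fpr, tpr = roc$tpr),
    roc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(method = method, auc = roc$auc,
                            records = nrow(res$records), skipped = res$skipped,
                            topk = as.list(counts)),
                       summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_manifest(cfg, inputs$paths, list(loocv = timing),
               list(records = rec_path, roc = roc_path, summary = summary_path),
               out_dir)
  invisible(list(records = res$records, roc = roc, auc = roc$auc, topk = counts))
}

#' Grid sweep of the restart, retention and fusion parameters
#'
#' Runs LOOCV at every combination of the supplied `gamma`, `sigma` and
#' `alpha` values on the configured inputs and tabulates the AUC per grid
#' point. A failing grid point is recorded as `NA` and the sweep continues.
#'
#' @inheritParams run_prioritize
#' @param gamma,sigma,alpha numeric grids.
#' @return data.frame with columns `gamma`, `sigma`, `alpha`, `auc`,
#'   `records`.
#' @export
run_sweep <- function(config, gamma = seq(0.1, 0.9, by = 0.1),
                      sigma = 0.6, alpha = seq(0, 1, by = 0.1),
                      out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% "trwr_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(cfg)
  grid <- expand.grid(gamma = gamma, sigma = sigma, alpha = alpha,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- NA_real_
  grid$records <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    params <- config_params(utils::modifyList(
      cfg, list(gamma = grid$gamma[r], sigma = grid$sigma[r], alpha = grid$alpha[r])))
    out <- tryCatch({
      res <- loocv(inputs$net, inputs$complexes, params)
      list(auc = roc_auc(res)$auc, n = nrow(res$records))
    }, error = function(e) {
      message(sprintf("sweep point gamma=%g sigma=%g alpha=%g failed: %s",
                      grid$gamma[r], grid$sigma[r], grid$alpha[r],
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(out)) { grid$auc[r] <- out$auc; grid$records[r] <- out$n }
  }
  utils::write.table(grid, file.path(out_dir, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grid
}
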