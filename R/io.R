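#' Read and write the plain-text input formats
#'
#' All inputs are tab-separated text: edge lists and association tables are
#' two-column TSVs with a header line; the disease similarity matrix is a TSV
#' whose first row and first column hold disease identifiers; protein
#' complexes are one complex per row, members tab-separated, no header;
#' similarity-network edge lists carry a third `weight` column.
#'
#' @name trwr-io
NULL

read_tsv_ <- function(path, ...) {
  if (!file.exists(path)) stop_(sprintf("input file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @rdname trwr-io
#' @param path file path.
#' @return `read_edge_list`: data.frame with columns `from`, `to` (and
#'   `weight` when present).
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_(path)
  if (ncol(df) < 2L) stop_(sprintf("edge list %s needs at least two columns", path))
  names(df)[1:2] <- c("from", "to")
  if (ncol(df) >= 3L) names(df)[3L] <- "weight"
  df[, seq_len(min(3L, ncol(df))), drop = FALSE]
}

#' @rdname trwr-io
#' @param edges data.frame with columns `from`, `to` and optionally `weight`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trwr-io
#' @return `read_association_table`: two-column data.frame.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_(path)
  if (ncol(df) != 2L) stop_(sprintf("association table %s must have two columns", path))
  if (anyDuplicated(df)) df <- unique(df)
  df
}

#' @rdname trwr-io
#' @param assoc two-column association data.frame.
#' @export
write_association_table <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trwr-io
#' @return `read_disease_similarity`: named square numeric matrix.
#' @export
read_disease_similarity <- function(path) {
  df <- read_tsv_(path, row.names = 1L)
  m <- as.matrix(df)
  dimnames(m) <- list(rownames(df), colnames(df))
  validate_dsim(m)
  m
}

#' @rdname trwr-io
#' @param sim named square similarity matrix.
#' @export
write_disease_similarity <- function(sim, path) {
  df <- data.frame(disease = rownames(sim), sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trwr-io
#' @return `read_complexes`: list of member identifier vectors.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop_(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(x) x[nzchar(x)])
}

#' @rdname trwr-io
#' @param complexes list of member identifier vectors.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Write a fixture bundle as a directory of TSV inputs
#'
#' Produces exactly the files the pipeline consumes: `ppi.tsv`,
#' `pathway.tsv`, six association TSVs, `disease_similarity.tsv`,
#' `complexes.tsv`, the ground-truth `ledger.tsv` (when present) and a
#' `manifest.json` echoing the generator configuration.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_edge_list(bundle$ppi, p("ppi.tsv"))
  write_edge_list(bundle$pathway, p("pathway.tsv"))
  write_association_table(bundle$gene_cancer, p("gene_cancer.tsv"))
  write_association_table(bundle$mirna_cancer, p("mirna_cancer.tsv"))
  write_association_table(bundle$lncrna_cancer, p("lncrna_cancer.tsv"))
  write_association_table(bundle$mirna_gene, p("mirna_gene.tsv"))
  write_association_table(bundle$lncrna_gene, p("lncrna_gene.tsv"))
  write_association_table(bundle$mirna_lncrna, p("mirna_lncrna.tsv"))
  write_disease_similarity(bundle$dsim, p("disease_similarity.tsv"))
  write_complexes(bundle$complexes, p("complexes.tsv"))
  if (!is.null(bundle$ledger))
    write_association_table(bundle$ledger, p("ledger.tsv"))
  ids <- bundle[c("gene_ids", "mirna_ids", "lncrna_ids", "cancer_ids")]
  jsonlite::write_json(list(config = unclass(bundle$config), ids = ids),
                       p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir directory written by [write_fixture()].
#' @return a `fixture_bundle`.
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  cfg <- do.call(fixture_config, manifest$config)
  ledger <- if (file.exists(p("ledger.tsv"))) read_association_table(p("ledger.tsv"))
  structure(list(gene_ids = manifest$ids$gene_ids,
                 mirna_ids = manifest$ids$mirna_ids,
                 lncrna_ids = manifest$ids$lncrna_ids,
                 cancer_ids = manifest$ids$cancer_ids,
                 ppi = read_edge_list(p("ppi.tsv")),
                 pathway = read_edge_list(p("pathway.tsv")),
                 gene_cancer = read_association_table(p("gene_cancer.tsv")),
                 mirna_cancer = read_association_table(p("mirna_cancer.tsv")),
                 lncrna_cancer = read_association_table(p("lncrna_cancer.tsv")),
                 mirna_gene = read_association_table(p("mirna_gene.tsv")),
                 lncrna_gene = read_association_table(p("lncrna_gene.tsv")),
                 mirna_lncrna = read_association_table(p("mirna_lncrna.tsv")),
                 dsim = read_disease_similarity(p("disease_similarity.tsv")),
                 complexes = read_complexes(p("complexes.tsv")),
                 ledger = ledger, config = cfg),
            class = "fixture_bundle")
}

#' Export a transition matrix as a sparse triplet TSV
#'
#' One line per nonzero entry: `row_id`, `col_id`, `prob`.
#'
#' @param tm a `transition_matrix` (or sparse matrix with dimnames).
#' @param path output file.
#' @export
write_transition_matrix <- function(tm, path) {
  W <- if (inherits(tm, "transition_matrix")) tm$W else tm
  T3 <- as(as(W, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(row_id = rownames(W)[T3@i + 1L],
                   col_id = colnames(W)[T3@j + 1L],
                   prob = T3@x, stringsAsFactors = FALSE)
  df <- df[order(df$row_id, df$col_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an assembled heterogeneous network to a directory bundle
#'
#' Writes the four intra-layer and six inter-layer blocks as weighted edge
#' TSVs plus a `manifest.json` listing the layer identifier vectors.
#'
#' @param net a `het_network`.
#' @param dir output directory.
#' @export
write_network_bundle <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tri <- function(A, sym) {
    T3 <- as(as(A, "CsparseMatrix"), "TsparseMatrix")
    df <- data.frame(from = rownames(A)[T3@i + 1L], to = colnames(A)[T3@j + 1L],
                     weight = T3@x, stringsAsFactors = FALSE)
    if (sym) df <- df[df$from < df$to, , drop = FALSE]
    df[order(df$from, df$to), , drop = FALSE]
  }
  for (s in names(net$intra))
    write_edge_list(tri(net$intra[[s]], sym = TRUE), file.path(dir, paste0(s, ".tsv")))
  for (s in names(net$inter))
    write_edge_list(tri(net$inter[[s]], sym = FALSE), file.path(dir, paste0(s, ".tsv")))
  jsonlite::write_json(
    list(gene = net$index$gene, mirna = net$index$mirna,
         lncrna = net$index$lncrna, cancer = net$index$cancer),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
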