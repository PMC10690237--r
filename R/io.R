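#' Read a 10x-style Matrix Market count matrix
#'
#' Expects `matrix.mtx`, `genes.tsv` (or `features.tsv`) and
#' `barcodes.tsv` in a directory, or explicit file paths. Genes are rows.
#'
#' @param dir directory containing the three files, or `NULL` when paths
#'   are given.
#' @param mtx,genes,barcodes explicit file paths (override `dir`).
#' @return dense genes x cells numeric matrix with dimnames.
#' @export
read_counts_mtx <- function(dir = NULL, mtx = NULL, genes = NULL,
                            barcodes = NULL) {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    gcand <- c(file.path(dir, "genes.tsv"), file.path(dir, "features.tsv"))
    genes <- genes %||% gcand[file.exists(gcand)][1]
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
  }
  m <- as.matrix(Matrix::readMM(mtx))
  g <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)
  b <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  # 10x gene files carry id + symbol; use the last name-like column
  rownames(m) <- if (ncol(g) >= 2) g[[2]] else g[[1]]
  colnames(m) <- b[[1]]
  assert_count_matrix(m)
}

#' Write a count matrix in Matrix Market + gene/barcode lists
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- assert_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense CSV/TSV count matrix
#'
#' @param path file path; delimiter inferred from the extension.
#' @param transpose set `TRUE` when the file stores cells as rows.
#' @return genes x cells numeric matrix.
#' @export
read_counts_csv <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  assert_count_matrix(m)
}

#' Write a dense CSV count matrix
#'
#' @param counts genes x cells matrix.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  utils::write.table(counts, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' End-to-end senescence scoring pipeline
#'
#' Read (or take) a count matrix, optionally denoise, normalize, subset
#' to the signature, standardize, train the autoencoder, score every
#' cell, and optionally binarize. When `out_prefix` is given, a per-cell
#' TSV (`<prefix>_scores.tsv`) and a JSON run report
#' (`<prefix>_report.json`) are written.
#'
#' @param counts genes x cells count matrix, or a path (directory with
#'   10x MTX files, or a dense CSV/TSV).
#' @param geneset scoring signature (default [default_signature()]).
#' @param denoise run the denoising autoencoder first (default `TRUE`).
#' @param binarize also call senescent cells (default `FALSE`).
#' @param anchor sign-anchor gene.
#' @param config [train_config()] for the scoring model; its seed drives
#'   every stochastic stage.
#' @param n_perm permutation replicates for binarization.
#' @param transpose passed to [read_counts_csv()] for dense files.
#' @param out_prefix optional output path prefix.
#' @return list with `scores` (the `sen_scores` tibble, plus
#'   `uncertainty`/`senescent` columns when binarizing), `fit`, and
#'   `report` (named list of run metadata).
#' @export
run_pipeline <- function(counts, geneset = default_signature(),
                         denoise = TRUE, binarize = FALSE,
                         anchor = "CDKN1A", config = train_config(),
                         n_perm = 50L, transpose = FALSE,
                         out_prefix = NULL) {
  if (is.character(counts)) {
    counts <- if (dir.exists(counts)) read_counts_mtx(counts)
              else read_counts_csv(counts, transpose = transpose)
  }
  counts <- assert_count_matrix(counts)
  dcfg <- config; dcfg$lambda <- 0
  inp <- prepare_inputs(counts, geneset, denoise = denoise,
                        denoise_config = dcfg)
  fit <- sen_train(inp$X, inp$Xp, inp$s, config)
  scores <- score_cells(fit, inp$Xp, anchor = anchor)
  if (binarize)
    scores <- binarize_scores(fit, inp$Xp, scores, n_perm = n_perm,
                              seed = config$seed)
  sig_genes <- if (inherits(geneset, "gene_set")) geneset$genes else geneset
  report <- list(
    seed = config$seed,
    n_cells = ncol(counts),
    n_genes = nrow(counts),
    signature_size = length(sig_genes),
    genes_used = fit$genes,
    denoise = denoise,
    neuron_index = attr(scores, "neuron_index"),
    flipped = attr(scores, "flipped"),
    anchor = anchor,
    stop_epoch = fit$stop_epoch,
    stop_reason = fit$stop_reason,
    cutoff = attr(scores, "cutoff"),
    mixture_K = attr(scores, "mixture")$K,
    package_version = as.character(utils::packageVersion("senoscore"))
  )
  if (!is.null(out_prefix)) {
    utils::write.table(as.data.frame(scores),
                       paste0(out_prefix, "_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(scores = scores, fit = fit, report = report)
}
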