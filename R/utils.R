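# internal numerical helpers

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# clip bounds for the exp/sigmoid output heads; keeps the likelihood finite
.Z_CLIP <- log(1e8)          # |linear predictor| bound for exp heads
.PI_EPS <- 1e-6              # dropout probability kept in [eps, 1-eps]

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation that treats a constant vector as "no correlation"
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("`%s` must be a numeric matrix (genes x cells)", arg)
  if (any(counts < 0)) stopf("`%s` contains negative entries", arg)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stopf("`%s` has duplicated gene identifiers", arg)
  counts
}
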