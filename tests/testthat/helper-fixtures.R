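# Shared fixture builders. Everything is generated in code; no files.

# 5-cell x 4-gene count matrix with one mitochondrial gene. Cells 4 and 5
# are the planted QC failures: cell 4 is 50% mito, cell 5 detects only one
# gene.
toy_qc_counts <- function() {
  m <- rbind(
    c(20, 5, 4, 1),   # ok (mito 1/30 = 3.3%)
    c(8, 2, 6, 0),    # ok (3 genes detected, no mito)
    c(10, 4, 5, 0),   # ok
    c(2, 1, 1, 4),    # 50% mito
    c(0, 0, 9, 0)     # 1 gene detected
  )
  colnames(m) <- c("Actb", "Gapdh", "Ifit2", "mt-Nd1")
  m
}

make_dataset <- function(m, timepoint = NULL, replicate = NULL,
                         state = "raw") {
  meta <- data.frame(row.names = seq_len(nrow(m)))
  if (!is.null(timepoint)) meta$timepoint <- timepoint
  if (!is.null(replicate)) meta$replicate <- replicate
  expression_dataset(m, cell_meta = meta, state = state)
}

# Two well-separated Gaussian blobs in `dims` dimensions.
blob_embedding <- function(n_per_blob = 50, dims = 2, sep = 20, sd = 1,
                           seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, dims), c(sep, rep(0, dims - 1)))
  emb <- rbind(
    matrix(stats::rnorm(n_per_blob * dims, sd = sd), ncol = dims) +
      rep(centers[1, ], each = n_per_blob),
    matrix(stats::rnorm(n_per_blob * dims, sd = sd), ncol = dims) +
      rep(centers[2, ], each = n_per_blob)
  )
  list(embedding = emb, blob = rep(c("A", "B"), each = n_per_blob))
}

# Exhaustive-scan k-nearest-neighbour label vote with the package's stated
# tie rule, written independently (plain loops) as an oracle.
oracle_knn_labels <- function(query, ref, ref_labels, k) {
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(ref))
    for (j in seq_len(nrow(ref))) d[j] <- sqrt(sum((query[i, ] - ref[j, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    votes <- ref_labels[nn]
    tab <- table(votes)
    winners <- names(tab)[tab == max(tab)]
    out[i] <- if (length(winners) == 1) winners else
      votes[which(votes %in% winners)[1]]
  }
  out
}

# Normal-equations solution of the pseudotime regression (Eq-5 style
# explicit inversion), the independent oracle for the QR-based fit.
oracle_normal_equations <- function(X, T_codes) {
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% T_codes)
}

# Population-standardize columns of a matrix (mean 0, variance 1, 1/N).
std_cols <- function(m) {
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  sweep(sweep(m, 2, mu, "-"), 2, sqrt(v), "/")
}
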