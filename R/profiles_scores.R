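#' Per-cell gene-set score
#'
#' Mean expression over a gene set minus the mean over a matched random
#' reference pool, the standard control-gene-pool scoring scheme: all genes
#' are partitioned into \code{n_bins} equal-size bins by mean expression
#' across cells, and for each set gene one reference gene is drawn uniformly
#' from the same bin (excluding set genes), so the reference matches the
#' set's expression-level distribution.
#'
#' @param dataset \code{expression_dataset}, normally standardized-state
#'   (L2 then per-gene z-score).
#' @param gene_set character vector of gene names; genes missing from the
#'   dataset are dropped with a warning.
#' @param n_bins number of expression bins (default 25).
#' @param seed RNG seed (mandatory: the reference pool is a random draw).
#' @param set_name label for the score.
#' @param reference_pool optional character vector restricting reference
#'   candidates (default: all genes not in the set).
#' @return A \code{gene_set_score}: list with \code{score} (per cell),
#'   \code{set_name}, \code{genes_used}, \code{reference}, \code{seed}.
#' @export
score_gene_set <- function(dataset, gene_set, n_bins = 25, seed = 0L,
                           set_name = "score", reference_pool = NULL) {
  m <- dense_matrix(dataset)
  present <- intersect(gene_set, dataset$gene_names)
  if (length(present) == 0) {
    stop("no gene-set members found in the dataset")
  }
  if (length(present) < length(gene_set)) {
    warning(length(gene_set) - length(present),
            " gene-set members missing from the dataset; dropped")
  }
  gmeans <- colMeans(m)
  # equal-size bins by rank of mean expression
  bins <- ceiling(rank(gmeans, ties.method = "first") /
                    (length(gmeans) / n_bins))
  names(bins) <- dataset$gene_names
  candidates <- if (is.null(reference_pool)) {
    setdiff(dataset$gene_names, present)
  } else {
    intersect(reference_pool, dataset$gene_names)
  }
  if (length(candidates) == 0) stop("empty reference candidate pool")
  set.seed(seed)
  reference <- vapply(present, function(g) {
    pool <- candidates[bins[candidates] == bins[g]]
    if (length(pool) == 0) pool <- candidates
    pool[sample.int(length(pool), 1)]
  }, character(1))
  set_idx <- match(present, dataset$gene_names)
  ref_idx <- match(reference, dataset$gene_names)
  score <- rowMeans(m[, set_idx, drop = FALSE]) -
    rowMeans(m[, ref_idx, drop = FALSE])
  structure(list(score = as.numeric(score), set_name = set_name,
                 genes_used = present, reference = unname(reference),
                 seed = seed),
            class = "gene_set_score")
}

# Centered rolling mean over an ordered vector (internal). Returns the
# windowed means and the mean rank-fraction position of each window, so a
# signal linear in position is reproduced exactly.
rolling_mean_positions <- function(x, pos, window) {
  n <- length(x)
  h1 <- floor((window - 1) / 2)
  h2 <- window - 1 - h1
  lo <- pmax(seq_len(n) - h1, 1)
  hi <- pmin(seq_len(n) + h2, n)
  keep <- (hi - lo + 1) == window           # full windows only
  cx <- c(0, cumsum(x)); cp <- c(0, cumsum(pos))
  list(mean = (cx[hi + 1] - cx[lo]) [keep] / window,
       pos = (cp[hi + 1] - cp[lo]) [keep] / window)
}

profile_curve <- function(grid, curves, reps, window = NA, span = NA) {
  mean_curve <- colMeans(curves)
  se <- apply(curves, 2, stats::sd) / sqrt(reps)
  structure(list(grid = grid, mean = mean_curve,
                 lower = mean_curve - 1.96 * se,
                 upper = mean_curve + 1.96 * se,
                 window = window, span = span, reps = reps),
            class = "profile_curve")
}

#' @exportS3Method base::print
print.profile_curve <- function(x, ...) {
  cat("profile_curve: ", length(x$grid), " grid points, ", x$reps,
      " replicates\n", sep = "")
  invisible(x)
}

#' Bootstrap bin-smoothed expression profile along pseudotime
#'
#' Expression profile of one gene over the pseudotime axis with a 95%
#' confidence band: in each of \code{reps} replicates, a fraction
#' \code{frac} of the cells is sampled without replacement, kept in
#' pseudotime order, smoothed with a centered rolling mean of
#' \code{window} cells (sliding by one cell), and interpolated onto a
#' common rank-fraction grid in [0, 1]. The band is the across-replicate
#' mean plus/minus 1.96 standard errors.
#'
#' @param expr numeric per-cell expression of one gene.
#' @param order integer cell permutation from \code{order_cells}.
#' @param window rolling-window size in cells (default 600 for whole-dataset
#'   profiles; 50 suits single clusters with few cells).
#' @param reps bootstrap replicates (default 20).
#' @param frac subsample fraction (default 0.5).
#' @param seed RNG seed.
#' @param grid_n grid resolution (default 200).
#' @return A \code{profile_curve}: \code{grid}, \code{mean}, \code{lower},
#'   \code{upper}.
#' @export
bootstrap_gene_profile <- function(expr, order, window = 600, reps = 20,
                                   frac = 0.5, seed = 0L, grid_n = 200) {
  expr <- as.numeric(expr)
  n <- length(expr)
  m <- floor(frac * n)
  if (window > m) {
    stop("window (", window, ") exceeds the subsample size (", m,
         "); choose a smaller window")
  }
  ordered <- expr[order]
  pos_all <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  grid <- seq(0, 1, length.out = grid_n)
  set.seed(seed)
  curves <- t(vapply(seq_len(reps), function(r) {
    idx <- sort(sample.int(n, m))
    rm <- rolling_mean_positions(ordered[idx], pos_all[idx], window)
    stats::approx(rm$pos, rm$mean, xout = grid, rule = 2)$y
  }, numeric(grid_n)))
  profile_curve(grid, curves, reps, window = window)
}

#' Bootstrap LOESS profile of a gene-set score along pseudotime
#'
#' LOESS with a first-order (locally linear) model is fitted to the score
#' against pseudotime rank fraction on a \code{frac} subsample, evaluated
#' on a common grid; repeated \code{reps} times; the profile is the mean
#' with a 1.96-standard-error band. First-order LOESS reproduces a signal
#' exactly linear in rank.
#'
#' @param score a \code{gene_set_score} or numeric per-cell vector.
#' @param order integer cell permutation from \code{order_cells}.
#' @param reps replicates (default 30).
#' @param frac subsample fraction (default 0.5).
#' @param degree local polynomial degree (default 1).
#' @param span LOESS span (default 0.3, tricube weights).
#' @param seed RNG seed.
#' @param grid_n grid resolution (default 200).
#' @return A \code{profile_curve}.
#' @export
loess_score_profile <- function(score, order, reps = 30, frac = 0.5,
                                degree = 1, span = 0.3, seed = 0L,
                                grid_n = 200) {
  y_all <- if (inherits(score, "gene_set_score")) score$score else
    as.numeric(score)
  n <- length(y_all)
  m <- floor(frac * n)
  if (m < 10) stop("need at least 10 cells per replicate")
  ordered <- y_all[order]
  pos_all <- (seq_len(n) - 1) / (n - 1)
  grid <- seq(0, 1, length.out = grid_n)
  set.seed(seed)
  curves <- t(vapply(seq_len(reps), function(r) {
    idx <- sort(sample.int(n, m))
    df <- data.frame(x = pos_all[idx], y = ordered[idx])
    fit <- stats::loess(y ~ x, data = df, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
  }, numeric(grid_n)))
  profile_curve(grid, curves, reps, span = span)
}
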