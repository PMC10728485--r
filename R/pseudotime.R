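#' Fit response pseudotime by least squares on experimental time labels
#'
#' The semi-supervised pseudotime at the core of the toolkit: find the gene
#' weight vector W (size G) whose linear projection of the standardized
#' expression matrix X (N cells x G response genes) best reconstructs the
#' per-cell experimental time codes T,
#' \deqn{X W = T + \epsilon,}
#' with the closed-form least-squares solution
#' \eqn{W = (X^T X)^{-1} X^T T} and per-cell pseudotime \eqn{PT = X W}.
#' No intercept is fitted (X is standardized per gene, so columns are
#' centered and an intercept would only absorb the mean of T). The system
#' is solved by QR decomposition, not explicit inversion; if X is rank
#' deficient (e.g. duplicated genes) the minimum-norm solution is returned
#' with a warning. Identifiability requires more cells than genes (N > G).
#'
#' @param X standardized cells x genes numeric matrix (per-gene mean 0,
#'   variance 1), restricted to the response genes.
#' @param T_codes numeric per-cell time codes (e.g. 0, 1, 2, 3 for control,
#'   3 h, 24 h, 72 h).
#' @param intercept fit an intercept term (default FALSE, the reference
#'   choice; the intercept variant is equally justifiable and exposed for
#'   comparison).
#' @return A \code{pseudotime_model}: list with \code{W} (named gene
#'   weights), \code{PT}, \code{residuals} (\eqn{\epsilon = PT - T}),
#'   \code{T}, \code{genes}, \code{intercept} (coefficient or NULL).
#' @export
fit_response_pseudotime <- function(X, T_codes, intercept = FALSE) {
  X <- as.matrix(X)
  T_codes <- as.numeric(T_codes)
  n <- nrow(X); g <- ncol(X)
  if (length(T_codes) != n) stop("T length does not match cell count")
  if (g >= n) {
    stop("G = ", g, " genes but only N = ", n, " cells; the fit is ",
         "over-parametrized. Reduce the response gene set so that N > G.")
  }
  A <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("design is rank deficient (rank ", qrA$rank, " < ", ncol(A),
            "); returning the minimum-norm least-squares solution")
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    coefs <- sv$v %*% (dinv * crossprod(sv$u, T_codes))
  } else {
    coefs <- qr.coef(qrA, T_codes)
  }
  coefs <- as.numeric(coefs)
  w <- if (intercept) coefs[-1] else coefs
  b0 <- if (intercept) coefs[1] else NULL
  names(w) <- colnames(X)
  pt <- as.numeric(X %*% w) + if (intercept) b0 else 0
  structure(list(W = w, PT = pt, residuals = pt - T_codes, T = T_codes,
                 genes = colnames(X), intercept = b0),
            class = "pseudotime_model")
}

#' @exportS3Method base::print
print.pseudotime_model <- function(x, ...) {
  cat("pseudotime_model: ", length(x$PT), " cells, ", length(x$W),
      " genes", if (!is.null(x$intercept)) ", with intercept", "\n",
      sep = "")
  cat("  residual SS: ", format(sum(x$residuals^2)), "\n", sep = "")
  invisible(x)
}

#' Order cells along pseudotime
#'
#' Stable ascending sort by PT; exact ties keep the original cell order.
#'
#' @param model a \code{pseudotime_model}, or a numeric PT vector.
#' @return Integer permutation of cell indices.
#' @export
order_cells <- function(model) {
  pt <- if (inherits(model, "pseudotime_model")) model$PT else
    as.numeric(model)
  order(pt, seq_along(pt))
}

#' Bin-smoothed pseudotemporal expression matrix
#'
#' Cells are sorted along pseudotime and partitioned into consecutive,
#' non-overlapping bins of \code{bin_size} cells; each gene's per-bin mean
#' is computed and the resulting profile min-max scaled to [0, 1]. A final
#' partial bin is kept as its own bin if it holds at least half of
#' \code{bin_size} cells and merged into the previous bin otherwise
#' (avoiding both dropped cells and a noisy tiny last bin).
#'
#' @param X cells x genes numeric matrix (typically l2-normalized
#'   response-gene expression).
#' @param order integer cell permutation from \code{order_cells}.
#' @param bin_size cells per bin (default 100).
#' @return List with \code{smoothed} (genes x bins matrix in [0, 1]),
#'   \code{bin_means} (unscaled), \code{degenerate} (per-gene flag for
#'   constant profiles, set to 0).
#' @export
smooth_pattern_matrix <- function(X, order, bin_size = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < bin_size) {
    warning("fewer cells (", n, ") than bin_size (", bin_size,
            "); using a single bin")
  }
  Xo <- X[order, , drop = FALSE]
  n_full <- n %/% bin_size
  rem <- n %% bin_size
  if (n_full == 0) {
    bin_id <- rep(1L, n)
  } else {
    bin_id <- rep(seq_len(n_full), each = bin_size)
    if (rem > 0) {
      bin_id <- c(bin_id,
                  rep(if (rem >= bin_size / 2) n_full + 1L else n_full,
                      rem))
    }
  }
  sums <- rowsum(Xo, bin_id)
  counts <- as.numeric(table(bin_id))
  means <- sums / counts                       # bins x genes
  lo <- apply(means, 2, min)
  hi <- apply(means, 2, max)
  rng <- hi - lo
  degenerate <- rng == 0
  rng[degenerate] <- 1
  scaled <- t((t(means) - lo) / rng)
  scaled[, degenerate] <- 0
  list(smoothed = t(scaled), bin_means = t(means),
       degenerate = stats::setNames(degenerate, colnames(X)))
}

#' Cluster genes into pseudotemporal expression patterns
#'
#' Agglomerative clustering of the smoothed, scaled gene profiles with a
#' flat cut at a cophenetic-distance threshold; pattern ids renumbered by
#' descending size.
#'
#' @param smoothed genes x bins matrix (from \code{smooth_pattern_matrix}).
#' @param threshold cut height (default 5.2).
#' @param linkage \code{hclust} method (default \code{"ward.D2"}).
#' @param k optional number of patterns; overrides \code{threshold}.
#' @return List with \code{pattern} (named integer vector), \code{tree}
#'   (\code{hclust}), \code{smoothed}, \code{threshold}.
#' @export
cluster_patterns <- function(smoothed, threshold = 5.2,
                             linkage = "ward.D2", k = NULL) {
  if (nrow(smoothed) < 2) stop("need at least 2 genes")
  tree <- stats::hclust(stats::dist(smoothed), method = linkage)
  raw <- if (is.null(k)) stats::cutree(tree, h = threshold) else
    stats::cutree(tree, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  pattern <- stats::setNames(as.integer(relabel[as.character(raw)]),
                             rownames(smoothed))
  list(pattern = pattern, tree = tree, smoothed = smoothed,
       threshold = if (is.null(k)) threshold else NA_real_)
}

#' Fit response pseudotime on a simulated dataset
#'
#' Convenience wrapper tying the simulator to the pseudotime fit:
#' standardizes the simulated expression per gene, uses the capture-label
#' indices (0..m) as time codes, fits, and orients PT so that it correlates
#' positively with the capture labels (the fit determines PT only up to the
#' regression's own scale; orientation by the known design makes recovery
#' statistics comparable across runs).
#'
#' @param sim a \code{simulated_dataset}.
#' @param intercept passed to \code{fit_response_pseudotime}.
#' @return The \code{pseudotime_model}, with \code{rho} (Spearman
#'   correlation of PT with the hidden true time) attached.
#' @export
pseudotime_from_simulation <- function(sim, intercept = FALSE) {
  stopifnot(inherits(sim, "simulated_dataset"))
  ds <- expression_dataset(sim$expression)
  std <- standardize_genes(ds)$dataset
  model <- fit_response_pseudotime(dense_matrix(std),
                                   as.numeric(sim$capture_label),
                                   intercept = intercept)
  if (stats::cor(model$PT, sim$capture_label,
                 method = "spearman") < 0) {
    model$PT <- -model$PT
    model$W <- -model$W
  }
  model$rho <- evaluate_order_recovery(sim$true_time, model$PT)
  model
}
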