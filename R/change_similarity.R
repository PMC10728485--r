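#' Per-cluster, per-timepoint mean expression tensor
#'
#' For every gene i, cluster j and timepoint t, the arithmetic mean (zeros
#' included) of the L2-normalized expression over the cells of cluster j
#' captured at t. A pseudo-cluster \code{"all"} holds the global profile
#' (mean over every cell at t), which the similarity score compares each
#' cluster against.
#'
#' @param dataset l2-state \code{expression_dataset} with a
#'   \code{timepoint} metadata column.
#' @param labels per-cell cluster labels (vector or
#'   \code{cluster_labeling}).
#' @param design a \code{timepoint_design}.
#' @return A \code{cluster_time_means}: list with \code{mu} (3-d array
#'   genes x clusters x timepoints, cluster dimension including
#'   \code{"all"}), \code{clusters}, \code{timepoints}.
#' @export
cluster_time_means <- function(dataset, labels, design) {
  if (inherits(labels, "cluster_labeling")) labels <- labels$labels
  labels <- as.character(labels)
  m <- dense_matrix(dataset)
  stopifnot(length(labels) == nrow(m))
  tp <- as.character(dataset$cell_meta$timepoint)
  clusters <- sort(unique(labels))
  n_t <- length(design$labels)
  mu <- array(NA_real_,
              dim = c(ncol(m), length(clusters) + 1, n_t),
              dimnames = list(dataset$gene_names, c(clusters, "all"),
                              design$labels))
  empty <- character()
  for (ti in seq_len(n_t)) {
    t_mask <- tp == design$labels[ti]
    for (ci in seq_along(clusters)) {
      idx <- t_mask & labels == clusters[ci]
      if (!any(idx)) {
        empty <- c(empty, paste0("(", clusters[ci], ", ",
                                 design$labels[ti], ")"))
        next
      }
      mu[, ci, ti] <- colMeans(m[idx, , drop = FALSE])
    }
    if (!any(t_mask)) {
      empty <- c(empty, paste0("(all, ", design$labels[ti], ")"))
    } else {
      mu[, length(clusters) + 1, ti] <- colMeans(m[t_mask, , drop = FALSE])
    }
  }
  if (length(empty)) {
    stop("empty (cluster, timepoint) groups: ",
         paste(unique(empty), collapse = "; "))
  }
  structure(list(mu = mu, clusters = clusters,
                 timepoints = design$labels),
            class = "cluster_time_means")
}

#' Change score per gene and cluster
#'
#' Total movement of a gene's cluster-mean profile over the time course:
#' \eqn{c_{i,j} = \sum_{t=1}^{m} |\mu_{i,j,t+1} - \mu_{i,j,t}|} with m =
#' n_timepoints - 1 intervals. Zero iff the profile is constant; invariant
#' to adding a constant.
#'
#' @param means a \code{cluster_time_means}.
#' @param include_all keep the \code{"all"} pseudo-cluster column
#'   (default FALSE).
#' @return genes x clusters numeric matrix of nonnegative scores.
#' @export
change_score <- function(means, include_all = FALSE) {
  mu <- means$mu
  if (dim(mu)[3] < 2) stop("need at least 2 timepoints")
  d <- abs(mu[, , -1, drop = FALSE] - mu[, , -dim(mu)[3], drop = FALSE])
  c_ij <- apply(d, c(1, 2), sum)
  if (!include_all) c_ij <- c_ij[, colnames(c_ij) != "all", drop = FALSE]
  c_ij
}

#' Group genes by their change-score vectors
#'
#' Agglomerative clustering of the gene rows of the change-score matrix,
#' with flat groups cut at a cophenetic-distance threshold. Group ids are
#' renumbered 1..K by descending size so output is stable across runs.
#'
#' @param scores genes x clusters change-score matrix.
#' @param threshold cophenetic-distance cut height (default 3).
#' @param linkage \code{hclust} method (default \code{"ward.D2"}; the
#'   linkage is a free choice, see the methods vignette).
#' @return List with \code{group} (named integer vector, 1-based),
#'   \code{tree} (the \code{hclust} object) and \code{threshold}.
#' @export
group_by_change <- function(scores, threshold = 3, linkage = "ward.D2") {
  if (nrow(scores) < 2) stop("need at least 2 genes")
  tree <- stats::hclust(stats::dist(scores), method = linkage)
  raw <- stats::cutree(tree, h = threshold)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  group <- stats::setNames(as.integer(relabel[as.character(raw)]),
                           rownames(scores))
  list(group = group, tree = tree, threshold = threshold)
}

#' Min-max scale cluster profiles to [0, 1]
#'
#' \eqn{x_{i,j,t} = (\mu_{i,j,t} - \min_t \mu) / (\max_t \mu - \min_t \mu)}
#' per (gene, cluster) profile. Constant profiles cannot be scaled; they are
#' set to 0 at all timepoints and flagged degenerate rather than dropped, so
#' every gene keeps a similarity row.
#'
#' @param means a \code{cluster_time_means}.
#' @return List with \code{x} (genes x clusters x timepoints array in
#'   [0, 1]) and \code{degenerate} (genes x clusters logical matrix).
#' @export
pattern_minmax <- function(means) {
  mu <- means$mu
  lo <- apply(mu, c(1, 2), min)
  hi <- apply(mu, c(1, 2), max)
  rng <- hi - lo
  degenerate <- rng == 0
  rng[degenerate] <- 1
  x <- sweep(mu, c(1, 2), lo, "-")
  x <- sweep(x, c(1, 2), rng, "/")
  for (t in seq_len(dim(x)[3])) x[, , t][degenerate] <- 0
  list(x = x, degenerate = degenerate)
}

#' Similarity of cluster profiles to the global profile
#'
#' \eqn{s_{i,j} = 1 - \sum_{t=1}^{n} |x_{i,all,t} - x_{i,j,t}| / n} on the
#' min-max scaled profiles: 1 means the cluster follows the dataset-wide
#' pattern exactly, 0 maximal disagreement at every timepoint. Bounded in
#' [0, 1] since each scaled difference is at most 1.
#'
#' @param patterns output of \code{pattern_minmax} (must include the
#'   \code{"all"} pseudo-cluster).
#' @return genes x clusters numeric matrix (the \code{"all"} column,
#'   identically 1, is dropped).
#' @export
similarity_score <- function(patterns) {
  x <- patterns$x
  cl <- dimnames(x)[[2]]
  if (!"all" %in% cl) stop("patterns must include the 'all' pseudo-cluster")
  n <- dim(x)[3]
  x_all <- x[, cl == "all", , drop = FALSE]
  s <- vapply(which(cl != "all"), function(j) {
    1 - apply(abs(x_all[, 1, , drop = FALSE] - x[, j, , drop = FALSE]),
              1, sum) / n
  }, numeric(dim(x)[1]))
  s <- matrix(s, nrow = dim(x)[1],
              dimnames = list(dimnames(x)[[1]], cl[cl != "all"]))
  s
}
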