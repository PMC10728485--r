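#' Cluster labeling
#'
#' Per-cell categorical labels plus provenance. Transferred labelings only
#' ever use labels from the control vocabulary, which is what makes
#' annotation robust to treatment-induced marker shifts: identity is defined
#' on unperturbed cells and propagated, not re-derived per timepoint.
#'
#' @param labels per-cell label vector (coerced to character).
#' @param source \code{"direct"} (clustered) or \code{"transferred"}.
#' @param vocabulary allowed label set; defaults to the labels seen.
#' @return A \code{cluster_labeling} object.
#' @export
cluster_labeling <- function(labels, source = c("direct", "transferred"),
                             vocabulary = NULL) {
  source <- match.arg(source)
  labels <- as.character(labels)
  if (is.null(vocabulary)) vocabulary <- sort(unique(labels))
  if (!all(labels %in% vocabulary)) {
    stop("labels outside the vocabulary: ",
         paste(utils::head(setdiff(labels, vocabulary), 5), collapse = ", "))
  }
  structure(list(labels = labels, source = source, vocabulary = vocabulary),
            class = "cluster_labeling")
}

#' @exportS3Method base::print
print.cluster_labeling <- function(x, ...) {
  cat("cluster_labeling (", x$source, "): ", length(x$labels), " cells, ",
      length(x$vocabulary), " labels\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

# Exact k-nearest-neighbour search by brute-force Euclidean distance
# (internal). Returns k ref indices per query row, nearest first; distance
# ties broken by lower ref index.
knn_indices <- function(query, ref, k) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (k > nrow(ref)) stop("k (", k, ") exceeds reference size (",
                          nrow(ref), ")")
  d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) +
    outer(rep(1, nrow(query)), rowSums(ref^2)) -
    2 * tcrossprod(query, ref)
  d2[d2 < 0] <- 0
  idx <- apply(d2, 1, function(row) order(row, seq_along(row))[seq_len(k)])
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}

#' Cluster the control subset
#'
#' Standard graph-based clustering of unperturbed cells: PCA (up to 50
#' components), a k-nearest-neighbour graph on the first \code{n_pcs}
#' components, and Leiden community detection (modularity objective) at the
#' given resolution. Labels are integers \code{0..K-1}, numbered by
#' descending cluster size.
#'
#' @param dataset l2-state \code{expression_dataset} restricted to HVGs
#'   (control cells only).
#' @param n_pcs number of principal components for the graph (default 10).
#' @param k neighbours per cell (default 15).
#' @param resolution Leiden resolution (default 0.8).
#' @param seed RNG seed for the Leiden refinement.
#' @param n_pcs_total components computed by PCA (default 50).
#' @return A \code{cluster_labeling} with source \code{"direct"}. The PCA
#'   scores are attached as attribute \code{"pca"}.
#' @export
cluster_control <- function(dataset, n_pcs = 10, k = 15, resolution = 0.8,
                            seed = 0L, n_pcs_total = 50) {
  m <- dense_matrix(dataset)
  if (k >= nrow(m)) stop("k must be smaller than the cell count")
  rank <- min(n_pcs_total, nrow(m) - 1, ncol(m))
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = rank)
  scores <- pca$x[, seq_len(min(n_pcs, rank)), drop = FALSE]
  nn <- knn_indices(scores, scores, k + 1)[, -1, drop = FALSE]  # drop self
  edges <- cbind(rep(seq_len(nrow(nn)), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- relabel[as.character(memb)]
  out <- cluster_labeling(labels, source = "direct")
  attr(out, "pca") <- pca$x
  out
}

#' Transfer control labels to treated cells by k-nearest neighbours
#'
#' Each non-control cell adopts the label most common among its \code{k}
#' nearest control cells by Euclidean distance in the shared embedding.
#' Majority ties are broken by the label of the single nearest neighbour
#' carrying a tied label, which makes the vote deterministic.
#'
#' @param embedding cells x dims numeric matrix covering ALL cells
#'   (typically an integrated/batch-corrected space; used only for transfer,
#'   never for downstream statistics).
#' @param control_labels a \code{cluster_labeling} for the control cells, in
#'   the order they appear in \code{embedding}.
#' @param control_mask logical per-row flag, TRUE for control cells.
#' @param k neighbours (default 15).
#' @return A \code{cluster_labeling} (source \code{"transferred"}) for the
#'   non-control cells, in embedding row order; vocabulary is the control
#'   vocabulary.
#' @export
transfer_labels <- function(embedding, control_labels, control_mask,
                            k = 15) {
  embedding <- as.matrix(embedding)
  stopifnot(length(control_mask) == nrow(embedding))
  ctrl <- embedding[control_mask, , drop = FALSE]
  qry <- embedding[!control_mask, , drop = FALSE]
  if (nrow(ctrl) < k) {
    stop("fewer than k = ", k, " control cells (", nrow(ctrl), ")")
  }
  lab <- control_labels$labels
  if (length(lab) != nrow(ctrl)) {
    stop("control_labels length does not match number of control cells")
  }
  nn <- knn_indices(qry, ctrl, k)
  out <- apply(nn, 1, function(idx) {
    votes <- lab[idx]
    counts <- table(votes)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) return(winners)
    votes[match(TRUE, votes %in% winners)]  # nearest among tied labels
  })
  cluster_labeling(out, source = "transferred",
                   vocabulary = control_labels$vocabulary)
}

#' Joint PCA fallback embedding
#'
#' A deliberately simple stand-in for an external integration method (NOT a
#' reimplementation of panorama-stitching integrators): genes are centered
#' within each timepoint batch to remove additive batch/treatment shifts,
#' then a joint PCA is computed over all cells. Adequate for label transfer
#' on desk-scale data; real batch structure warrants a dedicated integrator
#' whose embedding can be passed straight to \code{transfer_labels}.
#'
#' @param dataset l2-state \code{expression_dataset} over all timepoints.
#' @param batch per-cell batch/timepoint factor.
#' @param n_dims components to keep (default 50).
#' @return cells x n_dims score matrix.
#' @export
joint_pca_embedding <- function(dataset, batch, n_dims = 50) {
  m <- dense_matrix(dataset)
  batch <- as.factor(batch)
  stopifnot(length(batch) == nrow(m))
  for (b in levels(batch)) {
    idx <- batch == b
    m[idx, ] <- sweep(m[idx, , drop = FALSE], 2,
                      colMeans(m[idx, , drop = FALSE]), "-")
  }
  rank <- min(n_dims, nrow(m) - 1, ncol(m))
  stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = rank)$x
}
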