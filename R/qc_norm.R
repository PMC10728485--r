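#' Cell-level QC thresholds
#'
#' Defaults follow common mouse 10x practice: drop cells with more than 5%
#' mitochondrial counts or fewer than 700 unique detected genes.
#' Mitochondrial genes are recognised by a case-insensitive name prefix
#' (\code{"mt-"} for mouse).
#'
#' @param max_mito_fraction maximum mitochondrial count fraction (0..1).
#' @param min_unique_genes minimum number of detected (nonzero) genes.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return A \code{qc_thresholds} object.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.05, min_unique_genes = 700,
                          mito_prefix = "mt-") {
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must be in [0, 1]")
  }
  if (min_unique_genes < 0) stop("min_unique_genes must be >= 0")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_unique_genes = min_unique_genes,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells whose mitochondrial count fraction is at most
#' \code{max_mito_fraction} AND whose number of detected genes is at least
#' \code{min_unique_genes}. If no gene name matches the mitochondrial prefix
#' the mito filter is skipped with a warning (a non-issue for simulated
#' data).
#'
#' @param dataset raw-state \code{expression_dataset}.
#' @param thresholds a \code{qc_thresholds}.
#' @return List with \code{dataset} (filtered) and \code{report}, a
#'   data.frame with one row per input cell: \code{cell}, \code{mito_frac},
#'   \code{n_genes}, \code{keep}, \code{reason} (comma-joined, "" if kept).
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  if (dataset$state != "raw") stop("filter_cells expects raw counts")
  m <- dense_matrix(dataset)
  is_mito <- startsWith(tolower(dataset$gene_names),
                        tolower(thresholds$mito_prefix))
  totals <- rowSums(m)
  if (!any(is_mito)) {
    if (thresholds$max_mito_fraction < 1) {
      warning("no gene names match mito prefix '", thresholds$mito_prefix,
              "'; mito filter skipped")
    }
    mito_frac <- rep(0, nrow(m))
  } else {
    mito_frac <- rowSums(m[, is_mito, drop = FALSE]) / pmax(totals, 1)
  }
  n_genes <- rowSums(m > 0)
  fail_mito <- any(is_mito) & mito_frac > thresholds$max_mito_fraction
  fail_genes <- n_genes < thresholds$min_unique_genes
  keep <- !(fail_mito | fail_genes)
  reason <- character(nrow(m))
  reason[fail_mito] <- "mito"
  reason[fail_genes] <- ifelse(fail_mito[fail_genes], "mito,genes", "genes")
  report <- data.frame(
    cell = seq_len(nrow(m)),
    mito_frac = mito_frac, n_genes = n_genes,
    keep = keep, reason = reason, stringsAsFactors = FALSE
  )
  out <- dataset
  out$matrix <- dataset$matrix[keep, , drop = FALSE]
  out$cell_meta <- dataset$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  if (!is.null(dataset$embedding)) {
    out$embedding <- dataset$embedding[keep, , drop = FALSE]
  }
  list(dataset = out, report = report)
}

#' L2-normalize cells
#'
#' Scales each cell's expression vector to unit Euclidean norm. Preferred
#' here over library-size (L1) normalization because downstream statistics
#' (standardization, dot products) then operate on comparable unit vectors.
#'
#' @param dataset an \code{expression_dataset}.
#' @return The dataset with state \code{"l2"}.
#' @export
l2_normalize_cells <- function(dataset) {
  m <- dense_matrix(dataset)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop("all-zero cells cannot be L2-normalized: ",
         paste(utils::head(which(norms == 0), 10), collapse = ", "))
  }
  out <- dataset
  out$matrix <- m / norms
  out$state <- "l2"
  out
}

#' Rank highly variable genes by analytic Pearson residuals
#'
#' Computes per-entry analytic Pearson residuals of the raw counts under a
#' null of constant gene expression across cells,
#' \eqn{r_{cg} = (x_{cg} - \mu_{cg}) / \sqrt{\mu_{cg} + \mu_{cg}^2/\theta}}
#' with \eqn{\mu_{cg} = (\mathrm{rowsum}_c \cdot \mathrm{colsum}_g)/total},
#' clips residuals to \eqn{\pm\sqrt{N}}, and ranks genes by residual
#' variance.
#'
#' @param dataset raw-state \code{expression_dataset}.
#' @param n_top number of genes to return (default 500).
#' @param theta negative-binomial overdispersion (default 100).
#' @return data.frame with \code{gene} and \code{residual_variance},
#'   descending, first \code{n_top} rows.
#' @export
pearson_residual_hvgs <- function(dataset, n_top = 500, theta = 100) {
  if (dataset$state != "raw") stop("HVG selection expects raw counts")
  if (n_top > length(dataset$gene_names)) {
    stop("n_top (", n_top, ") exceeds gene count (",
         length(dataset$gene_names), ")")
  }
  x <- dense_matrix(dataset)
  n <- nrow(x)
  rs <- rowSums(x)
  cs <- colSums(x)
  total <- sum(rs)
  mu <- outer(rs, cs) / total
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  r[mu == 0] <- 0
  clip <- sqrt(n)
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  v <- apply(r, 2, stats::var)
  ord <- order(-v, dataset$gene_names)
  data.frame(gene = dataset$gene_names[ord], residual_variance = v[ord],
             stringsAsFactors = FALSE)[seq_len(n_top), ]
}

#' Standardize genes to mean 0, variance 1
#'
#' Per-gene z-scoring using the population (1/N) variance convention; the
#' convention only rescales downstream regression weights per gene but must
#' be fixed for reproducibility. Zero-variance genes are dropped and
#' reported.
#'
#' @param dataset an \code{expression_dataset}, normally in \code{"l2"}
#'   state (the standard pipeline standardizes after per-cell L2).
#' @return List with \code{dataset} (state \code{"standardized"}) and
#'   \code{dropped}, the names of zero-variance genes removed.
#' @export
standardize_genes <- function(dataset) {
  m <- dense_matrix(dataset)
  n <- nrow(m)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2  # population variance
  v[v < 0] <- 0
  zero <- v <= .Machine$double.eps * 100
  if (all(zero)) stop("all genes have zero variance")
  dropped <- dataset$gene_names[zero]
  m <- m[, !zero, drop = FALSE]
  m <- sweep(m, 2, mu[!zero], "-")
  m <- sweep(m, 2, sqrt(v[!zero]), "/")
  out <- dataset
  out$matrix <- m
  out$gene_names <- dataset$gene_names[!zero]
  out$state <- "standardized"
  list(dataset = out, dropped = dropped)
}

#' Subset a dataset to named genes
#'
#' @param dataset an \code{expression_dataset}.
#' @param genes character vector of gene names (order preserved).
#' @return The dataset restricted to those genes.
#' @export
subset_genes <- function(dataset, genes) {
  idx <- match(genes, dataset$gene_names)
  if (anyNA(idx)) {
    stop("genes not in dataset: ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  }
  out <- dataset
  out$matrix <- dataset$matrix[, idx, drop = FALSE]
  out$gene_names <- dataset$gene_names[idx]
  out
}

#' Subset a dataset to selected cells
#'
#' @param dataset an \code{expression_dataset}.
#' @param cells logical mask or integer indices.
#' @return The dataset restricted to those cells.
#' @export
subset_cells <- function(dataset, cells) {
  out <- dataset
  out$matrix <- dataset$matrix[cells, , drop = FALSE]
  out$cell_meta <- dataset$cell_meta[cells, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  if (!is.null(dataset$embedding)) {
    out$embedding <- dataset$embedding[cells, , drop = FALSE]
  }
  out
}
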