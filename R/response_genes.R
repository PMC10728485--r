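#' Per-cluster, per-timepoint differential expression versus control
#'
#' Identifies treatment-response genes by testing each (cluster, timepoint)
#' treated group against the control cells of the same cluster. Two engines:
#'
#' \describe{
#'   \item{\code{builtin_pseudobulk}}{Counts are summed per (replicate,
#'     cluster, timepoint) pseudobulk, converted to CPM, and each gene is
#'     tested with a two-sided Welch t-test on log2(CPM + 1) across
#'     replicates. Log2 fold change is computed on mean CPM + 1.
#'     Benjamini-Hochberg adjustment is applied within each (cluster,
#'     timepoint) contrast. This is a documented stand-in for a
#'     replicate-aware negative-binomial engine, adequate for planted-effect
#'     checks, not a clone of one.}
#'   \item{\code{external_table}}{Reads a precomputed results CSV with
#'     columns \code{gene,cluster,timepoint,adj_p,log_fc} (e.g. exported
#'     from an edgeR likelihood-ratio pipeline) and passes it through.}
#' }
#'
#' @param dataset raw-state \code{expression_dataset}; \code{cell_meta}
#'   must carry \code{replicate} and \code{timepoint} columns.
#' @param labels per-cell cluster label vector (or \code{cluster_labeling}).
#' @param design a \code{timepoint_design}; its first label is the control.
#' @param engine \code{"builtin_pseudobulk"} or \code{"external_table"}.
#' @param table_path CSV path for the external engine.
#' @return A \code{de_result}: data.frame with columns \code{gene},
#'   \code{cluster}, \code{timepoint}, \code{adj_p}, \code{log_fc}.
#'   Contrasts with fewer than 2 replicates on either side are skipped with
#'   a warning.
#' @export
run_de <- function(dataset, labels, design,
                   engine = c("builtin_pseudobulk", "external_table"),
                   table_path = NULL) {
  engine <- match.arg(engine)
  if (engine == "external_table") {
    if (is.null(table_path)) stop("external_table engine needs table_path")
    tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
    need <- c("gene", "cluster", "timepoint", "adj_p", "log_fc")
    if (!all(need %in% colnames(tab))) {
      stop("external table must have columns: ", paste(need, collapse = ","))
    }
    return(structure(tab[, need], class = c("de_result", "data.frame")))
  }
  if (inherits(labels, "cluster_labeling")) labels <- labels$labels
  labels <- as.character(labels)
  meta <- dataset$cell_meta
  stopifnot(length(labels) == nrow(meta),
            all(c("replicate", "timepoint") %in% colnames(meta)))
  m <- dense_matrix(dataset)
  tp <- as.character(meta$timepoint)
  rep_id <- as.character(meta$replicate)
  control_lab <- design$labels[1]
  treat_labs <- design$labels[-1]

  # pseudobulk: sum counts per (replicate, cluster, timepoint)
  grp <- paste(rep_id, labels, tp, sep = "\r")
  pb <- rowsum(m, grp)
  key <- do.call(rbind, strsplit(rownames(pb), "\r", fixed = TRUE))
  pb_rep <- key[, 1]; pb_cl <- key[, 2]; pb_tp <- key[, 3]
  cpm <- pb / rowSums(pb) * 1e6
  logcpm <- log2(cpm + 1)

  res <- list()
  for (cl in sort(unique(labels))) {
    ctrl_idx <- which(pb_cl == cl & pb_tp == control_lab)
    for (t1 in treat_labs) {
      trt_idx <- which(pb_cl == cl & pb_tp == t1)
      if (length(ctrl_idx) < 2 || length(trt_idx) < 2) {
        warning("contrast (", cl, ", ", t1, ") skipped: fewer than 2 ",
                "replicates on one side")
        next
      }
      lfc <- log2(colMeans(cpm[trt_idx, , drop = FALSE]) + 1) -
        log2(colMeans(cpm[ctrl_idx, , drop = FALSE]) + 1)
      p <- vapply(seq_len(ncol(logcpm)), function(g) {
        a <- logcpm[trt_idx, g]; b <- logcpm[ctrl_idx, g]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
        stats::t.test(a, b)$p.value
      }, numeric(1))
      res[[length(res) + 1]] <- data.frame(
        gene = dataset$gene_names, cluster = cl, timepoint = t1,
        adj_p = stats::p.adjust(p, method = "BH"), log_fc = lfc,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), cluster = character(),
               timepoint = character(), adj_p = numeric(),
               log_fc = numeric())
  structure(out, class = c("de_result", "data.frame"))
}

#' Select response genes from DE results
#'
#' A gene qualifies if at least one of its (cluster, timepoint) records has
#' adjusted p-value at most \code{alpha} AND absolute log fold change above
#' \code{min_lfc}. Each gene's summary p-value is the minimum adjusted p
#' over all its records.
#'
#' @param de a \code{de_result}.
#' @param alpha significance threshold (default 0.05).
#' @param min_lfc absolute log2 fold-change threshold, exclusive
#'   (default 1).
#' @return A \code{response_gene_set}: data.frame with \code{gene},
#'   \code{min_adj_p}, \code{max_abs_lfc}, sorted ascending by
#'   \code{min_adj_p}; thresholds stored as attributes.
#' @export
select_response_genes <- function(de, alpha = 0.05, min_lfc = 1) {
  if (nrow(de) == 0) stop("empty DE result")
  hit <- de$adj_p <= alpha & abs(de$log_fc) > min_lfc
  genes <- unique(de$gene[hit])
  sub <- de[de$gene %in% genes, ]
  min_p <- tapply(sub$adj_p, sub$gene, min)
  max_lfc <- tapply(abs(sub$log_fc), sub$gene, max)
  out <- data.frame(gene = names(min_p),
                    min_adj_p = as.numeric(min_p),
                    max_abs_lfc = as.numeric(max_lfc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$min_adj_p, -out$max_abs_lfc, out$gene), ]
  rownames(out) <- NULL
  structure(out, alpha = alpha, min_lfc = min_lfc,
            class = c("response_gene_set", "data.frame"))
}

#' Keep the top-k most significant response genes
#'
#' First \code{k} genes by minimum adjusted p; boundary ties resolved by
#' larger maximum |log fold change|, then lexicographic gene name.
#'
#' @param set a \code{response_gene_set}.
#' @param k number of genes to keep (default 500); \code{k} larger than the
#'   set returns the whole set.
#' @return A \code{response_gene_set} with at most \code{k} rows.
#' @export
top_k_response_genes <- function(set, k = 500) {
  ord <- order(set$min_adj_p, -set$max_abs_lfc, set$gene)
  out <- set[ord[seq_len(min(k, nrow(set)))], ]
  rownames(out) <- NULL
  structure(out, alpha = attr(set, "alpha"), min_lfc = attr(set, "min_lfc"),
            class = c("response_gene_set", "data.frame"))
}
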