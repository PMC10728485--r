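#' Expression dataset container
#'
#' The container shared by every stage of the toolkit: a cells x genes
#' numeric matrix plus per-cell metadata and gene names. A state flag tracks
#' which transform the matrix currently holds: \code{"raw"} counts,
#' \code{"l2"} (per-cell unit Euclidean norm) or \code{"standardized"}
#' (per-gene mean 0, variance 1). An optional low-dimensional embedding
#' (e.g. an externally integrated space) rides along for label transfer.
#'
#' @param matrix numeric cells x genes matrix (base or \code{Matrix} sparse).
#' @param cell_meta data.frame with one row per cell. Conventional columns:
#'   \code{timepoint} (experimental label), \code{replicate} (hashtag id),
#'   \code{cluster}, \code{pseudotime}. May be omitted; an empty frame is
#'   created.
#' @param gene_names character vector of unique gene identifiers, length
#'   \code{ncol(matrix)}. Defaults to the matrix column names.
#' @param embedding optional numeric cells x dims matrix.
#' @param state one of \code{"raw"}, \code{"l2"}, \code{"standardized"}.
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(matrix, cell_meta = NULL, gene_names = NULL,
                               embedding = NULL, state = "raw") {
  state <- match.arg(state, c("raw", "l2", "standardized"))
  if (is.null(gene_names)) gene_names <- colnames(matrix)
  if (is.null(gene_names)) {
    gene_names <- paste0("gene", seq_len(ncol(matrix)))
  }
  gene_names <- as.character(gene_names)
  if (length(gene_names) != ncol(matrix)) {
    stop("gene_names length (", length(gene_names),
         ") does not match gene count (", ncol(matrix), ")")
  }
  if (anyDuplicated(gene_names)) {
    dup <- unique(gene_names[duplicated(gene_names)])
    stop("duplicate gene names: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = seq_len(nrow(matrix)))
  }
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(cell_meta) != nrow(matrix)) {
    stop("cell_meta has ", nrow(cell_meta), " rows but matrix has ",
         nrow(matrix), " cells")
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nrow(matrix)) {
      stop("embedding row count does not match cell count")
    }
  }
  colnames(matrix) <- gene_names
  structure(
    list(matrix = matrix, cell_meta = cell_meta, gene_names = gene_names,
         embedding = embedding, state = state),
    class = "expression_dataset"
  )
}

#' @exportS3Method base::print
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$matrix), " cells x ",
      length(x$gene_names), " genes [state: ", x$state, "]\n", sep = "")
  if (ncol(x$cell_meta) > 0) {
    cat("  cell_meta: ", paste(colnames(x$cell_meta), collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$embedding)) {
    cat("  embedding: ", ncol(x$embedding), " dims\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Number of cells in a dataset
#' @param dataset an \code{expression_dataset}.
#' @return integer cell count.
#' @export
n_cells <- function(dataset) nrow(dataset$matrix)

# Dense numeric copy of the expression matrix (internal).
dense_matrix <- function(dataset) {
  m <- dataset$matrix
  if (inherits(m, "Matrix")) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

#' Read a count matrix into an expression dataset
#'
#' Supports the 10x-style MatrixMarket triplet layout (\code{matrix.mtx} +
#' \code{barcodes.tsv} + \code{genes.tsv} in a directory) and a dense CSV
#' with a header row of gene names. Cells are returned as rows regardless of
#' the on-disk orientation: for MTX the orientation is resolved against the
#' barcodes/genes file lengths.
#'
#' @param path directory (mtx_triplet) or file (csv).
#' @param format \code{"mtx_triplet"} or \code{"csv"}.
#' @return An \code{expression_dataset} in \code{"raw"} state. If the MTX
#'   directory contains a \code{cell_meta.csv} it is attached.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx_file <- file.path(path, "matrix.mtx")
    bc_file <- file.path(path, "barcodes.tsv")
    gn_file <- file.path(path, "genes.tsv")
    for (f in c(mtx_file, bc_file, gn_file)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- Matrix::readMM(mtx_file)
    barcodes <- readLines(bc_file)
    genes_tab <- utils::read.delim(gn_file, header = FALSE,
                                   stringsAsFactors = FALSE)
    genes <- genes_tab[[1]]
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      m <- Matrix::t(m)           # genes x cells on disk (10x convention)
    } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
      # already cells x genes
    } else {
      stop("matrix dims ", nrow(m), "x", ncol(m),
           " match neither barcodes (", length(barcodes),
           ") nor genes (", length(genes), ") orientation")
    }
    meta_file <- file.path(path, "cell_meta.csv")
    cell_meta <- if (file.exists(meta_file)) {
      utils::read.csv(meta_file, stringsAsFactors = FALSE)
    } else NULL
    rownames(m) <- barcodes
    ds <- expression_dataset(m, cell_meta = cell_meta, gene_names = genes)
    ds$cell_meta$barcode <- barcodes
    ds
  } else {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    first_is_id <- !is.numeric(tab[[1]])
    barcodes <- if (first_is_id) as.character(tab[[1]]) else
      as.character(seq_len(nrow(tab)))
    if (first_is_id) tab <- tab[, -1, drop = FALSE]
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    rownames(m) <- barcodes
    ds <- expression_dataset(m, gene_names = colnames(tab))
    ds$cell_meta$barcode <- barcodes
    ds
  }
}

#' Write an expression dataset as an MTX triplet directory
#'
#' Writes \code{matrix.mtx} (genes x cells, 10x convention),
#' \code{barcodes.tsv}, \code{genes.tsv} and \code{cell_meta.csv}.
#'
#' @param dataset an \code{expression_dataset}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_counts <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- dataset$matrix
  if (!inherits(m, "sparseMatrix")) {
    m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  }
  Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
  meta <- dataset$cell_meta
  if (is.null(meta$barcode)) {
    meta$barcode <- paste0("cell", seq_len(nrow(m)))
  }
  writeLines(as.character(meta$barcode), file.path(dir, "barcodes.tsv"))
  writeLines(dataset$gene_names, file.path(dir, "genes.tsv"))
  utils::write.csv(meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Experimental timepoint design
#'
#' Maps ordered timepoint labels (e.g. control, 3 h, 24 h, 72 h) to
#' consecutive integer codes 0..m. Equally spaced ordinal codes weight the
#' separation of every pair of adjacent timepoints equally; supply
#' \code{codes} to use alternative numeric codes (e.g. log-scaled hours).
#'
#' @param labels character vector of timepoint labels, in temporal order.
#' @param codes optional numeric codes, same length as \code{labels};
#'   defaults to \code{0:(m-1)}.
#' @return A \code{timepoint_design} object.
#' @export
timepoint_design <- function(labels, codes = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate timepoint labels")
  if (is.null(codes)) codes <- seq_along(labels) - 1
  if (length(codes) != length(labels)) {
    stop("codes length must match labels length")
  }
  structure(list(labels = labels, codes = as.numeric(codes)),
            class = "timepoint_design")
}

#' @exportS3Method base::print
print.timepoint_design <- function(x, ...) {
  cat("timepoint_design:",
      paste0(x$labels, "=", x$codes, collapse = ", "), "\n")
  invisible(x)
}

#' Convert per-cell timepoint labels to numeric time codes
#'
#' @param dataset an \code{expression_dataset} whose \code{cell_meta} has a
#'   \code{timepoint} column.
#' @param design a \code{timepoint_design}.
#' @param column metadata column holding the label (default
#'   \code{"timepoint"}).
#' @return Numeric vector T, one code per cell, aligned with the dataset's
#'   cell order.
#' @export
assign_time_codes <- function(dataset, design, column = "timepoint") {
  if (!column %in% colnames(dataset$cell_meta)) {
    stop("cell_meta has no column '", column, "'")
  }
  lab <- as.character(dataset$cell_meta[[column]])
  idx <- match(lab, design$labels)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("cells with labels outside the design: ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (labels: ", paste(unique(lab[bad]), collapse = ", "), ")")
  }
  design$codes[idx]
}
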