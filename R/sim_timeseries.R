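#' Sigmoid gene dynamics specification
#'
#' Describes one simulated gene's trajectory over (hidden) time. A
#' \code{monotonic} gene follows a single sigmoid
#' \eqn{S(t | \alpha, \beta) = 1 / (1 + e^{-(t-\alpha)/\beta})} with
#' midpoint \eqn{\alpha} and width \eqn{\beta}; a \code{complex} gene is
#' activated and then deactivated after a switching delay,
#' \eqn{S(t | \alpha, \beta) - S(t - t_{switch} | \alpha, \beta)}, which
#' models genes that relax back to baseline during recovery. Direction
#' \code{"down"} mirrors the trajectory (\eqn{1 - value}) so down-regulated
#' genes appear as well.
#'
#' @param kind \code{"monotonic"} or \code{"complex"}.
#' @param alpha sigmoid offset (time units).
#' @param beta sigmoid width (time units, must be > 0).
#' @param t_switch deactivation delay; required iff \code{kind = "complex"}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return A \code{gene_dynamics} object.
#' @export
gene_dynamics <- function(kind = c("monotonic", "complex"), alpha, beta,
                          t_switch = NULL, direction = c("up", "down")) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (kind == "complex" && is.null(t_switch)) {
    stop("complex genes require t_switch")
  }
  if (kind == "monotonic" && !is.null(t_switch)) {
    stop("t_switch is only meaningful for complex genes")
  }
  structure(list(kind = kind, alpha = alpha, beta = beta,
                 t_switch = t_switch, direction = direction),
            class = "gene_dynamics")
}

#' Evaluate a gene's sigmoid trajectory at given times
#'
#' Pre-noise, pre-scaling trajectory value. Monotonic genes return
#' \eqn{S(t|\alpha,\beta)} (0.5 at \eqn{t = \alpha}); complex genes return
#' \eqn{S(t|\alpha,\beta) - S(t - t_{switch}|\alpha,\beta)}, which is
#' identically 0 when \eqn{t_{switch} = 0}. \code{direction = "down"}
#' returns \eqn{1 - value}.
#'
#' @param t numeric vector of times.
#' @param spec a \code{gene_dynamics} object.
#' @return Numeric vector, same length as \code{t}.
#' @export
sigmoid_value <- function(t, spec) {
  stopifnot(inherits(spec, "gene_dynamics"))
  if (spec$beta <= 0) stop("beta must be > 0")
  s <- function(x) 1 / (1 + exp(-(x - spec$alpha) / spec$beta))
  v <- if (spec$kind == "monotonic") s(t) else s(t) - s(t - spec$t_switch)
  if (spec$direction == "down") 1 - v else v
}

#' Randomly sampled gene dynamics
#'
#' Draws a panel of gene specs with the configured mix of monotonic/complex
#' kinds and up/down directions. Parameter ranges default to alpha ~
#' U(0, 20), beta ~ U(0.5, 3), t_switch ~ U(5, 15) (time units matching the
#' default 0-20 capture range).
#'
#' @param n_genes number of genes.
#' @param prop_complex fraction of complex genes (default 0.5).
#' @param prop_down fraction of down-regulated genes (default 0.5).
#' @param alpha_range,beta_range,t_switch_range uniform sampling ranges.
#' @return List of \code{gene_dynamics}, length \code{n_genes}. Uses the
#'   current RNG state; seed via \code{set.seed} or \code{simulation_spec}.
#' @export
sample_gene_dynamics <- function(n_genes, prop_complex = 0.5,
                                 prop_down = 0.5,
                                 alpha_range = c(0, 20),
                                 beta_range = c(0.5, 3),
                                 t_switch_range = c(5, 15)) {
  n_complex <- round(n_genes * prop_complex)
  n_down <- round(n_genes * prop_down)
  kinds <- sample(c(rep("complex", n_complex),
                    rep("monotonic", n_genes - n_complex)))
  dirs <- sample(c(rep("down", n_down), rep("up", n_genes - n_down)))
  lapply(seq_len(n_genes), function(i) {
    gene_dynamics(
      kind = kinds[i],
      alpha = stats::runif(1, alpha_range[1], alpha_range[2]),
      beta = stats::runif(1, beta_range[1], beta_range[2]),
      t_switch = if (kinds[i] == "complex") {
        stats::runif(1, t_switch_range[1], t_switch_range[2])
      } else NULL,
      direction = dirs[i]
    )
  })
}

#' Simulation specification
#'
#' Defaults follow the reference discrete design: 4 capture timepoints
#' (0, 5, 10, 20), 250 cells each (1,000 total), Gaussian asynchrony of SD
#' 1.5 added to each cell's capture time to produce its hidden continuous
#' time, and Gaussian expression noise of SD 0.05 added after per-gene
#' min-max scaling. \code{sampling = "continuous"} instead draws hidden time
#' uniformly over \code{t_range}.
#'
#' @param n_genes number of genes (used when \code{gene_specs} is NULL).
#' @param gene_specs list of \code{gene_dynamics}; if NULL, sampled with
#'   \code{sample_gene_dynamics} under \code{seed}.
#' @param sampling \code{"discrete"} or \code{"continuous"}.
#' @param timepoints ordered capture times.
#' @param cells_per_timepoint cells drawn per capture time.
#' @param asynchrony_sd SD of the Gaussian capture-time jitter (time units).
#' @param expression_noise_sd SD of the expression noise.
#' @param t_range range of hidden time for continuous sampling.
#' @param seed RNG seed (integer).
#' @param prop_complex,prop_down mix passed to \code{sample_gene_dynamics}.
#' @return A \code{simulation_spec} object.
#' @export
simulation_spec <- function(n_genes = 20, gene_specs = NULL,
                            sampling = c("discrete", "continuous"),
                            timepoints = c(0, 5, 10, 20),
                            cells_per_timepoint = 250,
                            asynchrony_sd = 1.5,
                            expression_noise_sd = 0.05,
                            t_range = c(0, 20), seed = 0L,
                            prop_complex = 0.5, prop_down = 0.5) {
  sampling <- match.arg(sampling)
  if (cells_per_timepoint <= 0) stop("cells_per_timepoint must be > 0")
  if (asynchrony_sd < 0) stop("asynchrony_sd must be >= 0")
  if (expression_noise_sd < 0) stop("expression_noise_sd must be >= 0")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (!is.null(gene_specs)) {
    stopifnot(all(vapply(gene_specs, inherits, TRUE, "gene_dynamics")))
    n_genes <- length(gene_specs)
  }
  if (n_genes < 1) stop("need at least one gene")
  structure(list(n_genes = n_genes, gene_specs = gene_specs,
                 sampling = sampling, timepoints = timepoints,
                 cells_per_timepoint = cells_per_timepoint,
                 asynchrony_sd = asynchrony_sd,
                 expression_noise_sd = expression_noise_sd,
                 t_range = t_range, seed = as.integer(seed),
                 prop_complex = prop_complex, prop_down = prop_down),
            class = "simulation_spec")
}

#' Simulate a post-stimulation time-series dataset
#'
#' Discrete mode draws \code{cells_per_timepoint} cells per capture time and
#' adds Gaussian(0, asynchrony_sd) jitter to obtain each cell's hidden
#' continuous time; continuous mode draws hidden time uniformly over
#' \code{t_range} (capture labels are then assigned to the nearest capture
#' timepoint so supervised fits have time codes). Gene trajectories are
#' evaluated at the hidden times, min-max normalized per gene over the
#' sampled cells, and Gaussian expression noise is added. Hidden time is not
#' clipped after jitter; trajectories are defined on all reals.
#'
#' @param spec a \code{simulation_spec}.
#' @return A \code{simulated_dataset}: list with \code{expression} (cells x
#'   genes), \code{true_time}, \code{capture_label} (0-based timepoint
#'   index), \code{capture_time}, \code{gene_specs} and \code{spec}.
#'   Reproducible given \code{spec$seed}.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  gene_specs <- spec$gene_specs
  if (is.null(gene_specs)) {
    gene_specs <- sample_gene_dynamics(spec$n_genes,
                                       prop_complex = spec$prop_complex,
                                       prop_down = spec$prop_down)
  }
  if (length(gene_specs) == 0) stop("empty gene list")
  n_tp <- length(spec$timepoints)
  if (spec$sampling == "discrete") {
    capture_label <- rep(seq_len(n_tp) - 1L, each = spec$cells_per_timepoint)
    capture_time <- spec$timepoints[capture_label + 1L]
    true_time <- capture_time + stats::rnorm(length(capture_time),
                                             0, spec$asynchrony_sd)
  } else {
    n <- spec$cells_per_timepoint * n_tp
    true_time <- stats::runif(n, spec$t_range[1], spec$t_range[2])
    capture_label <- vapply(true_time, function(t) {
      which.min(abs(spec$timepoints - t)) - 1L
    }, integer(1))
    capture_time <- spec$timepoints[capture_label + 1L]
  }
  n <- length(true_time)
  expr <- vapply(gene_specs, function(g) {
    v <- sigmoid_value(true_time, g)
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
      rep(0, n)
    v + stats::rnorm(n, 0, spec$expression_noise_sd)
  }, numeric(n))
  colnames(expr) <- paste0("gene", seq_along(gene_specs))
  rownames(expr) <- paste0("cell", seq_len(n))
  structure(list(expression = expr, true_time = true_time,
                 capture_label = capture_label,
                 capture_time = capture_time,
                 gene_specs = gene_specs, spec = spec),
            class = "simulated_dataset")
}

#' @exportS3Method base::print
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset: ", nrow(x$expression), " cells x ",
      ncol(x$expression), " genes (", x$spec$sampling, " sampling, seed ",
      x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Convert a simulated dataset to an expression_dataset
#'
#' @param sim a \code{simulated_dataset}.
#' @return An \code{expression_dataset} (raw state) whose \code{cell_meta}
#'   carries \code{timepoint} (capture-time label as character),
#'   \code{capture_label} and \code{true_time}.
#' @export
as_expression_dataset <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  meta <- data.frame(
    barcode = rownames(sim$expression),
    timepoint = as.character(sim$capture_time),
    capture_label = sim$capture_label,
    true_time = sim$true_time,
    replicate = NA_character_,
    stringsAsFactors = FALSE
  )
  expression_dataset(sim$expression, cell_meta = meta)
}

#' Rank-correlation recovery of a known temporal order
#'
#' Spearman rank correlation between a known per-cell time and an inferred
#' pseudotime; the standard summary of how well an ordering method recovers
#' the ground truth of a simulation.
#'
#' @param true_time numeric vector of hidden times.
#' @param pt numeric vector of pseudotimes, same length.
#' @return Spearman's rho.
#' @export
evaluate_order_recovery <- function(true_time, pt) {
  if (length(true_time) != length(pt)) stop("length mismatch")
  if (length(pt) < 3) stop("need at least 3 cells")
  if (stats::sd(true_time) == 0 || stats::sd(pt) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(true_time, pt, method = "spearman")
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix as an MTX triplet (plus barcodes/genes TSV),
#' the cell metadata (capture label, hidden true time) as CSV, and the
#' generating spec as JSON (\code{sim_spec.json}).
#'
#' @param sim a \code{simulated_dataset}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  ds <- as_expression_dataset(sim)
  write_counts(ds, dir)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    sp <- sim$spec
    sp$gene_specs <- lapply(sim$gene_specs, unclass)
    jsonlite::write_json(unclass(sp), file.path(dir, "sim_spec.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
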