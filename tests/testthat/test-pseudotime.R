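test_that("fit_response_pseudotime matches the normal-equations oracle", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(30:60, 1); g <- sample(3:8, 1)
    X <- std_cols(matrix(rnorm(n * g), n, g))
    T_codes <- sample(0:3, n, replace = TRUE)
    model <- fit_response_pseudotime(X, T_codes)
    expect_equal(unname(model$W), oracle_normal_equations(X, T_codes),
                 tolerance = 1e-8)
    expect_equal(model$PT, as.numeric(X %*% model$W), tolerance = 1e-12)
    expect_equal(model$residuals, model$PT - T_codes, tolerance = 1e-12)
    # residual orthogonality: X' eps = 0
    expect_lt(max(abs(crossprod(X, model$residuals))), 1e-8)
  }
})

test_that("pseudotime fit enforces N > G and handles rank deficiency", {
  X <- std_cols(matrix(rnorm(20), 4, 5))
  expect_error(fit_response_pseudotime(X, rep(0:1, 2)), "N > G")
  # duplicated gene column: minimum-norm solution with a warning
  set.seed(1)
  base <- std_cols(matrix(rnorm(40 * 3), 40, 3))
  Xd <- cbind(base, base[, 3])
  T_codes <- rep(0:3, each = 10)
  expect_warning(model <- fit_response_pseudotime(Xd, T_codes),
                 "rank deficient")
  # fit quality equals the full-rank fit on the unique columns
  ref <- fit_response_pseudotime(base, T_codes)
  expect_equal(sum(model$residuals^2), sum(ref$residuals^2),
               tolerance = 1e-8)
  # minimum-norm splits the duplicated weight evenly
  expect_equal(model$W[3], model$W[4], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a single time-tracking gene gives a perfectly ordered PT", {
  T_codes <- rep(0:3, each = 8)
  x <- std_cols(cbind(2 * T_codes + 5))   # positive affine image of T
  model <- fit_response_pseudotime(x, T_codes)
  expect_equal(evaluate_order_recovery(T_codes, model$PT), 1,
               tolerance = 1e-12)
})

test_that("PT is equivariant under gene-column permutation", {
  set.seed(3)
  X <- std_cols(matrix(rnorm(50 * 6), 50, 6))
  colnames(X) <- paste0("g", 1:6)
  T_codes <- rep(0:4, each = 10)
  m1 <- fit_response_pseudotime(X, T_codes)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- fit_response_pseudotime(X[, perm], T_codes)
  expect_equal(m2$PT, m1$PT, tolerance = 1e-10)
  expect_equal(m2$W, m1$W[perm], tolerance = 1e-10)
})

test_that("with intercept the fitted values shift but order is preserved", {
  set.seed(4)
  X <- std_cols(matrix(rnorm(40 * 4), 40, 4))
  T_codes <- rep(0:3, each = 10)
  m0 <- fit_response_pseudotime(X, T_codes)
  m1 <- fit_response_pseudotime(X, T_codes, intercept = TRUE)
  # standardized X has centered columns, so the intercept absorbs mean(T)
  expect_equal(m1$intercept, mean(T_codes), tolerance = 1e-10)
  expect_equal(unname(m1$W), unname(m0$W), tolerance = 1e-10)
})

test_that("order_cells sorts stably with original-index tie-breaks", {
  expect_equal(order_cells(c(1, 2, 3)), 1:3)
  expect_equal(order_cells(rep(0, 5)), 1:5)
  set.seed(5)
  pt <- sample(rep(c(0.1, 0.7, 0.3), 4))
  got <- order_cells(pt)
  # oracle: exhaustive stable comparison sort
  want <- seq_along(pt)[order(rank(pt, ties.method = "first"))]
  expect_equal(got, want)
})

test_that("smooth_pattern_matrix bins, averages and min-max scales", {
  # 200 cells, bin 100: gene is 0 in the first bin, 1 in the second
  x <- cbind(step = rep(c(0, 1), each = 100),
             flat = rep(2, 200))
  sm <- smooth_pattern_matrix(x, order = 1:200, bin_size = 100)
  expect_equal(unname(sm$smoothed["step", ]), c(0, 1))
  expect_true(sm$degenerate["flat"])
  expect_equal(unname(sm$smoothed["flat", ]), c(0, 0))
  # partial final bin: 250 cells -> bins of 100, 100, 50 (>= half kept)
  x2 <- cbind(g = seq_len(250))
  sm2 <- smooth_pattern_matrix(x2, order = 1:250, bin_size = 100)
  expect_equal(unname(sm2$bin_means["g", ]),
               c(mean(1:100), mean(101:200), mean(201:250)))
  # 230 cells -> trailing 30 merges into the second bin
  sm3 <- smooth_pattern_matrix(cbind(g = seq_len(230)), 1:230, 100)
  expect_equal(unname(sm3$bin_means["g", ]),
               c(mean(1:100), mean(101:230)))
  expect_warning(smooth_pattern_matrix(cbind(g = 1:5), 1:5, 100),
                 "single bin")
})

test_that("smoothing respects the pseudotime order and the binning oracle", {
  set.seed(6)
  n <- 400
  pt <- runif(n)
  expr <- cbind(g = pt^2 + rnorm(n, 0, 0.01))
  ord <- order_cells(pt)
  sm <- smooth_pattern_matrix(expr, ord, bin_size = 100)
  # independent per-bin mean recomputation
  want <- vapply(1:4, function(b) {
    mean(expr[ord[((b - 1) * 100 + 1):(b * 100)], "g"])
  }, numeric(1))
  want <- (want - min(want)) / (max(want) - min(want))
  expect_equal(unname(sm$smoothed["g", ]), want, tolerance = 1e-12)
  # monotone signal stays nondecreasing after smoothing
  expect_true(all(diff(sm$smoothed["g", ]) >= 0))
})

test_that("cluster_patterns separates directions and renumbers by size", {
  smoothed <- rbind(
    up1 = c(0, 0.3, 0.7, 1), up2 = c(0, 0.2, 0.8, 1),
    up3 = c(0.1, 0.4, 0.6, 1),
    down1 = c(1, 0.7, 0.3, 0), down2 = c(1, 0.8, 0.2, 0)
  )
  res <- cluster_patterns(smoothed, k = 2)
  expect_equal(length(unique(res$pattern)), 2)
  expect_equal(length(unique(res$pattern[1:3])), 1)
  expect_equal(length(unique(res$pattern[4:5])), 1)
  expect_equal(unname(res$pattern["up1"]), 1L)    # larger pattern is id 1
  # duplicated rows share a pattern at any cut
  dup <- rbind(smoothed, up1b = smoothed["up1", ])
  res2 <- cluster_patterns(dup, threshold = 0.05)
  expect_equal(unname(res2$pattern["up1b"]), unname(res2$pattern["up1"]))
  # cut above the root height collapses to one pattern
  res3 <- cluster_patterns(smoothed,
                           threshold = max(res$tree$height) + 1)
  expect_equal(unique(res3$pattern), 1L)
})
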