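# 6 cells, 2 clusters, 2 timepoints, 2 genes; hand-checkable means.
make_means_fixture <- function() {
  m <- rbind(
    c(0, 1), c(1, 1),      # cluster A, control
    c(2, 3),               # cluster A, 3h
    c(4, 0),               # cluster B, control
    c(0, 2), c(2, 2)       # cluster B, 3h
  )
  colnames(m) <- c("g1", "g2")
  ds <- make_dataset(m, timepoint = c("control", "control", "3h",
                                      "control", "3h", "3h"),
                     state = "l2")
  labels <- c("A", "A", "A", "B", "B", "B")
  list(ds = ds, labels = labels,
       design = timepoint_design(c("control", "3h")))
}

test_that("cluster_time_means matches hand-computed means incl. 'all'", {
  fx <- make_means_fixture()
  cm <- cluster_time_means(fx$ds, fx$labels, fx$design)
  expect_equal(cm$mu["g1", "A", "control"], 0.5)   # mean(0, 1)
  expect_equal(cm$mu["g1", "A", "3h"], 2)          # single cell
  expect_equal(cm$mu["g2", "B", "3h"], 2)
  expect_equal(cm$mu["g1", "all", "control"], mean(c(0, 1, 4)))
  expect_equal(cm$mu["g2", "all", "3h"], mean(c(3, 2, 2)))
  # empty (cluster, timepoint) group is an error naming the group
  bad <- fx
  bad$labels <- c("A", "A", "A", "B", "A", "A")    # B has no 3h cell
  expect_error(cluster_time_means(bad$ds, bad$labels, bad$design),
               "\\(B, 3h\\)")
})

test_that("change_score sums absolute consecutive differences", {
  # profile (0, 1, 0, 2) over 4 timepoints: c = 1 + 1 + 2 = 4, 3 summands
  mu <- array(0, dim = c(1, 2, 4),
              dimnames = list("g", c("cl", "all"), paste0("t", 1:4)))
  mu[1, 1, ] <- c(0, 1, 0, 2)
  mu[1, 2, ] <- c(5, 5, 5, 5)
  cs <- change_score(structure(list(mu = mu), class = "cluster_time_means"),
                     include_all = TRUE)
  expect_equal(cs["g", "cl"], 4)
  expect_equal(cs["g", "all"], 0)         # constant profile => 0
  # invariant to adding a constant
  mu2 <- mu; mu2[1, 1, ] <- mu[1, 1, ] + 7
  cs2 <- change_score(structure(list(mu = mu2),
                                class = "cluster_time_means"),
                      include_all = TRUE)
  expect_equal(cs2["g", "cl"], cs["g", "cl"])
  expect_true(all(cs >= 0))
})

test_that("pattern_minmax scales to [0,1] and flags constant profiles", {
  mu <- array(0, dim = c(2, 2, 4),
              dimnames = list(c("g1", "g2"), c("cl", "all"), NULL))
  mu[1, 1, ] <- c(2, 4, 6, 4)
  mu[1, 2, ] <- c(1, 1, 1, 1)             # degenerate
  mu[2, 1, ] <- c(0, 10, 5, 0)
  mu[2, 2, ] <- c(0, 1, 0, 1)
  pm <- pattern_minmax(structure(list(mu = mu),
                                 class = "cluster_time_means"))
  expect_equal(as.numeric(pm$x[1, 1, ]), c(0, 0.5, 1, 0.5))
  expect_true(pm$degenerate[1, 2])
  expect_equal(as.numeric(pm$x[1, 2, ]), rep(0, 4))
  # positive affine invariance
  mu3 <- mu; mu3[2, 1, ] <- 3 * mu[2, 1, ] + 11
  pm3 <- pattern_minmax(structure(list(mu = mu3),
                                  class = "cluster_time_means"))
  expect_equal(pm3$x[2, 1, ], pm$x[2, 1, ])
  # every non-degenerate profile attains both 0 and 1
  expect_true(all(apply(pm$x, c(1, 2), min)[!pm$degenerate] == 0))
  expect_true(all(apply(pm$x, c(1, 2), max)[!pm$degenerate] == 1))
})

test_that("similarity_score matches term-by-term evaluation", {
  mu <- array(0, dim = c(2, 2, 4),
              dimnames = list(c("g1", "g2"), c("cl", "all"), NULL))
  mu[1, 1, ] <- c(0, 1, 2, 3); mu[1, 2, ] <- c(0, 1, 2, 3)  # identical
  mu[2, 1, ] <- c(1, 0, 1, 0); mu[2, 2, ] <- c(0, 1, 0, 1)  # opposite
  pm <- pattern_minmax(structure(list(mu = mu),
                                 class = "cluster_time_means"))
  s <- similarity_score(pm)
  expect_equal(s["g1", "cl"], 1)
  expect_equal(s["g2", "cl"], 0)
  # random profiles: direct recomputation of the formula, bounds hold
  set.seed(7)
  mu[1, 1, ] <- runif(4); mu[1, 2, ] <- runif(4)
  pm2 <- pattern_minmax(structure(list(mu = mu),
                                  class = "cluster_time_means"))
  s2 <- similarity_score(pm2)
  want <- 1 - sum(abs(pm2$x[1, 2, ] - pm2$x[1, 1, ])) / 4
  expect_equal(unname(s2["g1", "cl"]), want)
  expect_true(all(s2 >= 0 & s2 <= 1))
})

test_that("group_by_change cuts the dendrogram as the oracle predicts", {
  # 5 score rows in 2 tight bunches
  scores <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(0, 0.1),
                  d = c(10, 10), e = c(10.1, 10))
  # oracle for single linkage: connected components of the
  # distance-below-threshold graph
  d <- as.matrix(dist(scores))
  adj <- d < 3
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  res <- group_by_change(scores, threshold = 3, linkage = "single")
  expect_equal(length(unique(res$group)), 2)
  expect_true(all(tapply(res$group, comp, function(x)
    length(unique(x))) == 1))
  # duplicated rows always share a group; cut above the root gives 1 group
  dup <- rbind(scores, a2 = scores["a", ])
  res2 <- group_by_change(dup, threshold = 0.5)
  expect_equal(unname(res2$group["a2"]), unname(res2$group["a"]))
  res3 <- group_by_change(scores, threshold = max(
    group_by_change(scores, 3)$tree$height) + 1)
  expect_equal(unique(res3$group), 1L)
  # group ids are ordered by size descending
  big <- rbind(scores, f = c(0.05, 0.05))
  res4 <- group_by_change(big, threshold = 3)
  expect_equal(unname(res4$group["a"]), 1L)   # the 4-member bunch is group 1
})
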