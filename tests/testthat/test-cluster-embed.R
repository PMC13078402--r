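test_that("k distinct points give singleton clusters with zero inertia", {
  set.seed(2)
  x <- matrix(rnorm(23 * 11, sd = 20), 23, 11)
  rownames(x) <- sprintf("a%02d", 1:23)
  cm <- fit_clusters(x, k = 23, seed = 1, standardize = FALSE)
  expect_identical(sort(unique(cm$assignments)), 1:23)
  expect_lt(cm$inertia, 1e-9)
  expect_error(fit_clusters(x[1:5, ], k = 23), "distinct")
})

test_that("two-group toys match the exhaustive minimal-inertia partition", {
  for (seed in 1:5) {
    set.seed(seed)
    centers <- matrix(c(0, 0, 30, 30), 2, 2, byrow = TRUE)
    x <- rbind(
      sweep(matrix(rnorm(6, sd = 1), 3, 2), 2, centers[1, ], "+"),
      sweep(matrix(rnorm(6, sd = 1), 3, 2), 2, centers[2, ], "+")
    )
    rownames(x) <- sprintf("p%d", 1:6)
    cm <- fit_clusters(x, k = 2, seed = seed, standardize = FALSE)
    oracle <- best_two_partition(x)
    same <- identical(unname(cm$assignments == cm$assignments[1]),
                      oracle$partition == oracle$partition[1])
    expect_true(same)
    expect_equal(cm$inertia, oracle$inertia, tolerance = 1e-9)
  }
})

test_that("duplicating every point leaves the centroids unchanged", {
  set.seed(4)
  x <- matrix(rnorm(40, sd = 10), 20, 2)
  rownames(x) <- sprintf("a%d", 1:20)
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("a%d", 1:40)
  cm1 <- fit_clusters(x, k = 3, seed = 2, standardize = FALSE)
  cm2 <- fit_clusters(x2, k = 3, seed = 2, standardize = FALSE)
  ord1 <- order(cm1$centers[, 1], cm1$centers[, 2])
  ord2 <- order(cm2$centers[, 1], cm2$centers[, 2])
  expect_equal(cm1$centers[ord1, ], cm2$centers[ord2, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stored assignments are each point's nearest centroid", {
  recs <- impute_records(simulate_cohort(default_sim_panel(), 60, seed = 3))
  fl <- otogene:::flatten_records(recs)
  x <- otogene:::feature_matrix(fl$audiograms)
  cm <- fit_clusters(x, k = 23, seed = 9)
  xs <- otogene:::standardize_apply(x, cm$std)
  for (i in seq_len(nrow(xs))) {
    d2 <- colSums((t(cm$centers) - xs[i, ])^2)
    expect_identical(unname(cm$assignments[i]), unname(which.min(d2)))
  }
})

test_that("embedding is 3-dimensional and deterministic", {
  x <- mk_blobs(n_per = 12, seed = 6)
  e1 <- embed3d(x, seed = 42)
  e2 <- embed3d(x, seed = 42)
  expect_identical(dim(e1$coords), c(36L, 3L))
  expect_identical(e1$coords, e2$coords)
  expect_error(embed3d(x[1:5, ]), "at least 10")
})

test_that("the embedding preserves neighbourhoods better than a random projection", {
  x <- mk_blobs(n_per = 20, d = 11, seed = 5)
  em <- embed3d(x, seed = 42)
  t_embed <- trustworthiness(scale(x), em$coords, k = 10)
  set.seed(99)
  proj <- matrix(rnorm(11 * 3), 11, 3)
  t_rand <- trustworthiness(scale(x), scale(x, scale = FALSE) %*% proj,
                            k = 10)
  expect_gt(t_embed, t_rand)
})

test_that("cluster composition counts conserve the dataset", {
  recs <- impute_records(simulate_cohort(default_sim_panel(), 60, seed = 3))
  fl <- otogene:::flatten_records(recs)
  x <- otogene:::feature_matrix(fl$audiograms)
  cm <- fit_clusters(x, k = 23, seed = 9)
  comp <- cluster_composition(cm, stats::setNames(fl$gene, fl$audiogram_id))
  expect_identical(sum(comp), length(fl$audiograms))
  # single-gene dataset: all mass in that gene's column
  one <- cluster_composition(cm, stats::setNames(rep("WFS1", nrow(x)),
                                                 fl$audiogram_id))
  expect_identical(colnames(one), "WFS1")
  expect_identical(sum(one), nrow(x))
  # hand count on a tiny two-cluster toy
  y <- rbind(matrix(0, 3, 2), matrix(50, 2, 2))
  rownames(y) <- sprintf("t%d", 1:5)
  cmy <- fit_clusters(y, k = 2, seed = 1, standardize = FALSE)
  compy <- cluster_composition(cmy, stats::setNames(
    c("A", "A", "B", "B", "B"), rownames(y)))
  low <- cmy$assignments[["t1"]]
  expect_identical(unname(compy[low, c("A", "B")]), c(2L, 1L))
  expect_identical(unname(compy[-low, c("A", "B")]), c(0L, 2L))
})

test_that("out-of-sample placement lands on centroids, twins, and ties", {
  recs <- impute_records(simulate_cohort(default_sim_panel(), 60, seed = 3))
  fl <- otogene:::flatten_records(recs)
  x <- otogene:::feature_matrix(fl$audiograms)
  cm <- fit_clusters(x, k = 23, seed = 9)
  em <- embed3d(x, seed = 42)
  # an audiogram equal to a training point: same cluster, same coordinate
  a1 <- fl$audiograms[[7]]
  pl <- place_patient(cm, em, a1)
  expect_identical(pl$cluster, unname(cm$assignments[[a1$audiogram_id]]))
  expect_equal(pl$coords, unname(em$coords[a1$audiogram_id, ]),
               tolerance = 1e-12)
  # equidistant to two centroids: the lower cluster index wins
  two <- rbind(matrix(0, 4, 2), matrix(10, 4, 2))
  rownames(two) <- sprintf("u%d", 1:8)
  cm2 <- fit_clusters(two, k = 2, seed = 1, standardize = FALSE)
  mid <- colMeans(cm2$centers)
  tie <- otogene:::nearest_centroid(matrix(mid, 1), cm2$centers)
  expect_identical(as.integer(tie), 1L)
})

test_that("Lloyd iterations never increase inertia from the seeded start", {
  set.seed(12)
  x <- matrix(rnorm(200), 50, 4)
  for (r in 1:3) {
    set.seed(100 + r)
    init <- otogene:::kmeanspp_init(x, 5)
    d2 <- function(ctr) {
      sum(apply(x, 1, function(p) min(colSums((t(ctr) - p)^2))))
    }
    km <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 50,
                                         algorithm = "Lloyd"))
    expect_lte(km$tot.withinss, d2(init) + 1e-9)
  }
})
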