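metric_cols <- c("MaxDepth", "DiveDur", "AscRt", "DescRt", "BottDur",
                 "MeanBottDepth", "SDBottDepth", "PDI", "BottFrac",
                 "DistToSeaFlr", "Speed", "TA")

random_metric_frame <- function(n, seed = 1) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, metric_cols)))
}

test_that("PCA retains the minimal component count for the variance target", {
  # one dominant latent axis -> a single component suffices
  set.seed(4)
  latent <- rnorm(300)
  x <- as.data.frame(sapply(seq_len(12), function(j) latent + rnorm(300, 0, 0.05)))
  names(x) <- metric_cols
  p1 <- standardize_and_pca(x, 0.85)
  expect_identical(p1$n_components, 1L)
  expect_gt(p1$variance_fractions[1], 0.95)

  x2 <- random_metric_frame(500, seed = 5)
  p <- standardize_and_pca(x2, 0.85)
  cv <- cumsum(p$variance_fractions)
  expect_gte(cv[p$n_components], 0.85)
  if (p$n_components > 1) expect_lt(cv[p$n_components - 1], 0.85)
  expect_identical(standardize_and_pca(x2, 1.0)$n_components, 12L)
})

test_that("PCA eigenvalues match a dense eigendecomposition oracle", {
  x <- random_metric_frame(2000, seed = 6)
  p <- standardize_and_pca(x, 0.85)
  ev <- eigen(stats::cov(scale(as.matrix(x))), symmetric = TRUE)$values
  expect_lt(max(abs(p$variance_fractions - ev / sum(ev))), 1e-8)
  # scores are centred; variance fractions sum to 1 and are non-increasing
  expect_lt(max(abs(colMeans(p$scores))), 1e-8)
  expect_equal(sum(p$variance_fractions), 1)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
})

test_that("PCA rejects constant columns by name and tiny inputs", {
  x <- random_metric_frame(50, seed = 7)
  x$Speed <- 3
  expect_error(standardize_and_pca(x), "Speed")
  expect_error(standardize_and_pca(random_metric_frame(50)[0, ]), "complete|2")
})

test_that("Ward clustering: point masses, separated blobs, degenerate k", {
  pm <- rbind(matrix(0, 50, 2), matrix(5, 50, 2))
  cl <- ward_cluster(pm, 2)
  expect_identical(length(unique(cl$labels[1:50])), 1L)
  expect_identical(length(unique(cl$labels[51:100])), 1L)
  expect_false(cl$labels[1] == cl$labels[51])
  expect_true(all(diff(cl$tree$height) >= -1e-9))

  for (seed in 1:10) {
    set.seed(seed)
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    truth <- rep(1:3, each = 20)
    x <- centers[truth, ] + matrix(rnorm(120, 0, 0.1), 60, 2)
    got <- ward_cluster(x, 3)$labels
    expect_true(same_partition(truth, got))
  }

  expect_true(all(ward_cluster(pm, 1)$labels == 1L))
  expect_error(ward_cluster(pm[1:3, ], 5), "exceeds")
})

test_that("Ward merges agree with a naive O(n^3) agglomeration oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:50, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    tree <- ward_cluster(x, 3)
    want <- naive_ward(x, 3)
    expect_equal(sort(tree$tree$height), want$heights, tolerance = 1e-8)
    expect_true(same_partition(stats::cutree(tree$tree, 3), want$labels))
  }
})

test_that("bootstrap Jaccard: perfect stability for point masses, instability for a split Gaussian", {
  pm <- rbind(matrix(0, 40, 2), matrix(5, 40, 2))
  rep_pm <- bootstrap_jaccard(pm, 2, B = 100, seed = 3)
  expect_equal(unname(rep_pm$mean_jaccard), c(1, 1))

  set.seed(8)
  gauss <- matrix(rnorm(300 * 2), 300, 2)
  rep_g <- bootstrap_jaccard(gauss, 2, B = 100, seed = 3)
  expect_lt(mean(rep_g$mean_jaccard), 0.75)
})

test_that("a single bootstrap iteration matches a by-hand resample comparison", {
  set.seed(21)
  x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2), matrix(rnorm(30, 4, 0.3), 15, 2))
  got <- bootstrap_jaccard(x, 2, B = 1, seed = 99)$mean_jaccard
  base <- ward_cluster(x, 2)$labels
  set.seed(99)
  idx <- sample.int(30, 30, replace = TRUE)
  lab <- ward_cluster(x[idx, ], 2)$labels
  boot_sets <- lapply(split(seq_along(idx), lab), function(s) unique(idx[s]))
  want <- vapply(split(seq_len(30), base), function(orig) {
    a <- intersect(orig, unique(idx))
    max(vapply(boot_sets, function(b) length(intersect(a, b)) / length(union(a, b)),
               numeric(1)))
  }, numeric(1))
  expect_equal(unname(got), unname(want))
})

test_that("naming rules reproduce the published cluster profiles", {
  mk <- function(MaxDepth, DiveDur, DistToSeaFlr, BottFrac, SDBottDepth, n = 11) {
    data.frame(MaxDepth = MaxDepth, DiveDur = DiveDur,
               DistToSeaFlr = DistToSeaFlr, BottFrac = BottFrac,
               SDBottDepth = SDBottDepth)[rep(1, n), ]
  }
  profiles <- rbind(
    mk(340, 30.3, 388.9, 0.5, 19.4),   # Mid-water
    mk(16, 2.3, 547.1, 0.0, 0.0),      # Short-shallow
    mk(290, 21.4, 458.3, 0.2, 5.9),    # V-shaped
    mk(456.5, 45.8, 0.0, 0.7, 6.9),    # Benthic
    mk(635, 33.1, 80.1, 0.5, 60.3),    # Variable
    mk(21.4, 11.0, 434.8, 0.7, 1.8))   # Long-shallow
  labels <- rep(1:6, each = 11)
  nm <- assign_type_names(labels, profiles)
  expect_identical(as.vector(nm), c("Mid-water", "Short-shallow", "V-shaped",
                                    "Benthic", "Variable", "Long-shallow"))
})

test_that("naming collisions yield provisional names and a warning", {
  df <- data.frame(MaxDepth = rep(340, 20), DiveDur = 30, DistToSeaFlr = 300,
                   BottFrac = 0.5, SDBottDepth = 19)
  expect_warning(nm <- assign_type_names(rep(1:2, each = 10), df), "collision")
  expect_identical(anyDuplicated(nm), 0L)
  expect_s3_class(attr(nm, "medians"), "data.frame")
})

test_that("type quantiles use the linear-interpolation convention and stay ordered", {
  df <- data.frame(MaxDepth = c(10, 20, 30, 40), DiveDur = c(1, 2, 3, 4))
  q <- build_type_quantiles(rep("A", 4), df)
  qd <- q[q$variable == "MaxDepth", ]
  expect_equal(c(qd$q1, qd$median, qd$q3), c(17.5, 25, 32.5))

  one <- build_type_quantiles("B", data.frame(MaxDepth = 100, DiveDur = 10))
  expect_true(all(one$q1 == one$median & one$median == one$q3))

  dep_q <- big_analysis()$model$quantiles
  expect_true(all(dep_q$q1 <= dep_q$median & dep_q$median <= dep_q$q3))
})

test_that("summary-dive classification: windows, Unknown, tie-break", {
  q <- rbind(
    data.frame(type = "Deep", variable = "MaxDepth", q1 = 300, median = 400, q3 = 500),
    data.frame(type = "Deep", variable = "DiveDur", q1 = 20, median = 30, q3 = 40),
    data.frame(type = "Shallow", variable = "MaxDepth", q1 = 10, median = 15, q3 = 25),
    data.frame(type = "Shallow", variable = "DiveDur", q1 = 1, median = 3, q3 = 6))
  expect_identical(classify_summary_dive(400, 30, q)$type, "Deep")
  expect_identical(classify_summary_dive(15, 3, q)$type, "Shallow")
  expect_identical(classify_summary_dive(5000, 1, q)$type, "Unknown")
  expect_identical(classify_summary_dive(400, 3, q)$type, "Unknown")  # split windows

  # overlapping windows: nearest normalized median wins, flagged ambiguous
  q2 <- rbind(q, data.frame(type = "Deep2", variable = c("MaxDepth", "DiveDur"),
                            q1 = c(350, 25), median = c(450, 35), q3 = c(550, 45)))
  got <- classify_summary_dive(405, 30.5, q2)
  expect_identical(got$type, "Deep")
  expect_true(got$ambiguous)
})

test_that("model round-trips through JSON serialization", {
  res <- big_analysis()
  path <- tempfile(fileext = ".json")
  write_dive_type_model(res$model, path)
  back <- read_dive_type_model(path)
  expect_equal(back$n_components, res$model$pca$n_components)
  expect_equal(unlist(back$center), res$model$pca$center, tolerance = 1e-12)
  expect_equal(sort(unname(unlist(back$type_names))),
               sort(as.vector(res$model$type_names)))
  expect_equal(back$quantiles$q1, res$model$quantiles$q1, tolerance = 1e-12)
  unlink(path)
})
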