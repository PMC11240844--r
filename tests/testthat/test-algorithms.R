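test_that("fcm recovers the two block means of a noiseless step image", {
  img <- two_block_image(12, 12, 0, 1)
  res <- run_fcm(img, clustering_config("fcm", n_clusters = 2, seed = 1))
  expect_true(res$converged)
  expect_equal(sort(res$centers), c(0, 1), tolerance = 1e-3)
  ev <- evaluate_segmentation(res, two_block_labels(12, 12))
  expect_equal(ev$overall_accuracy, 1)
})

test_that("fcm with a single cluster returns the image mean", {
  img <- matrix(runif(36), 6, 6)
  res <- run_fcm(img, clustering_config("fcm", n_clusters = 1, seed = 1))
  expect_equal(res$centers, mean(img), tolerance = 1e-9)
})

test_that("the fcm objective is non-increasing along iterations", {
  set.seed(5)
  img <- matrix(runif(400), 20, 20)
  res <- run_fcm(img, clustering_config("fcm", n_clusters = 3, seed = 5))
  expect_true(all(diff(res$trace$objective) <= 1e-9))
})

test_that("all four drivers are reproducible from a fixed seed", {
  set.seed(77)
  img <- matrix(runif(100), 10, 10)
  for (alg in c("fcm", "ifcm", "csfcm", "csifcm")) {
    cfg <- clustering_config(alg, n_clusters = 3, seed = 42, max_iter = 20)
    r1 <- segment_image(img, cfg)
    r2 <- segment_image(img, cfg)
    expect_identical(r1$membership, r2$membership)
    expect_identical(r1$labels, r2$labels)
    expect_identical(r1$centers, r2$centers)
  }
})

test_that("every driver recovers a noiseless two-block image exactly", {
  img <- two_block_image(10, 10, 0.2, 0.8)
  img <- normalize_intensities(img)
  truth <- two_block_labels(10, 10)
  for (alg in c("fcm", "ifcm", "csfcm", "csifcm")) {
    res <- segment_image(img, clustering_config(alg, n_clusters = 2, seed = 3))
    expect_equal(evaluate_segmentation(res, truth)$overall_accuracy, 1,
                 info = alg)
  }
})

test_that("final weighted membership columns sum to one for every driver", {
  set.seed(8)
  img <- matrix(runif(144), 12, 12)
  for (alg in c("fcm", "ifcm", "csfcm", "csifcm")) {
    res <- segment_image(img, clustering_config(alg, n_clusters = 3, seed = 8,
                                                max_iter = 15))
    expect_equal(colSums(res$membership), rep(1, 144), tolerance = 1e-9,
                 info = alg)
    expect_true(all(res$membership >= 0 & res$membership <= 1 + 1e-12))
  }
})

test_that("csifcm at alpha = 1 reproduces csfcm's weighted membership", {
  set.seed(21)
  img <- matrix(runif(196), 14, 14)
  for (iters in c(2L, 9L)) {
    a <- run_csfcm(img, clustering_config("csfcm", n_clusters = 3, seed = 4,
                                          max_iter = iters, epsilon = 1e-15))
    b <- run_csifcm(img, clustering_config("csifcm", n_clusters = 3, alpha = 1,
                                           seed = 4, max_iter = iters,
                                           epsilon = 1e-15))
    expect_equal(b$membership, a$membership, tolerance = 1e-14)
    expect_equal(b$centers, a$centers, tolerance = 1e-14)
  }
})

test_that("ifcm at alpha = 1 follows the fcm trajectory", {
  set.seed(22)
  img <- matrix(runif(196), 14, 14)
  for (iters in c(3L, 10L)) {
    f <- run_fcm(img, clustering_config("fcm", n_clusters = 3, seed = 5,
                                        max_iter = iters, epsilon = 1e-15))
    i <- run_ifcm(img, clustering_config("ifcm", n_clusters = 3, alpha = 1,
                                         seed = 5, max_iter = iters,
                                         epsilon = 1e-15))
    expect_equal(i$membership, f$membership, tolerance = 1e-12)
    expect_equal(i$centers, f$centers, tolerance = 1e-12)
  }
})

test_that("csifcm with window 1, alpha 1, p = q yields fcm labels on crisp data", {
  img <- two_block_image(8, 8, 0, 1)
  f <- run_fcm(img, clustering_config("fcm", n_clusters = 2, seed = 6))
  cs <- run_csifcm(img, clustering_config("csifcm", n_clusters = 2, alpha = 1,
                                          window = 1, p = 2, q = 2, seed = 6))
  map <- match_clusters(cs$labels, f$labels, 2)
  expect_equal(matrix(map[cs$labels], 8, 8), f$labels)
  # w is a normalized power of mu: columns sum to 1 and preserve argmax
  expect_equal(colSums(cs$membership), rep(1, 64), tolerance = 1e-9)
})

test_that("permuting the initial partition permutes output labels consistently", {
  set.seed(30)
  img <- matrix(runif(100), 10, 10)
  init <- initialize_partition(100, 3, seed = 13)
  perm <- c(3L, 1L, 2L)
  for (alg in c("fcm", "csifcm")) {
    cfg <- clustering_config(alg, n_clusters = 3, max_iter = 25)
    r1 <- segment_image(img, cfg, init = init)
    r2 <- segment_image(img, cfg, init = init[perm, ])
    expect_equal(r2$membership, r1$membership[perm, ], tolerance = 1e-12)
    expect_equal(r2$centers, r1$centers[perm], tolerance = 1e-12)
  }
})

test_that("non-convergence is flagged, not raised", {
  set.seed(9)
  img <- matrix(runif(400), 20, 20)
  res <- run_fcm(img, clustering_config("fcm", n_clusters = 4, seed = 2,
                                        max_iter = 2))
  expect_false(res$converged)
  expect_equal(res$n_iterations, 2L)
})

test_that("defuzzification takes the per-pixel argmax with first-index ties", {
  expect_equal(defuzzify(cbind(c(0.98, 0.02))), 1L)
  expect_equal(defuzzify(cbind(c(0.5, 0.5))), 1L)
  expect_equal(defuzzify(cbind(c(0.2, 0.5, 0.3))), 2L)
  expect_equal(defuzzify(rbind(c(0.1, 0.6), c(0.9, 0.4))), c(2L, 1L))
})

test_that("spatial conditioning rectifies isolated noise-flipped pixels", {
  # noisy two-block fixture whose class gap (0.3) overlaps the noise tails,
  # so plain FCM flips isolated interior pixels that conditioning can fix
  img <- two_block_image(20, 20, 0.35, 0.65)
  truth <- two_block_labels(20, 20)
  interior <- matrix(FALSE, 20, 20); interior[2:19, c(2:9, 12:19)] <- TRUE
  miss_fcm <- 0L; miss_cs <- 0L
  for (s in 1:10) {
    noisy <- add_gaussian_noise(img, 0.01, seed = s)
    f <- run_fcm(noisy, clustering_config("fcm", n_clusters = 2, seed = s))
    cs <- run_csifcm(noisy, clustering_config("csifcm", n_clusters = 2,
                                              seed = s))
    mf <- match_clusters(f$labels, truth, 2)
    mc <- match_clusters(cs$labels, truth, 2)
    miss_fcm <- miss_fcm + sum((mf[f$labels] != truth)[interior])
    miss_cs <- miss_cs + sum((mc[cs$labels] != truth)[interior])
  }
  expect_lt(miss_cs, miss_fcm)
})

test_that("drivers reject unnormalized images and mismatched configs", {
  expect_error(run_fcm(matrix(c(-1, 2, 3, 4), 2),
                       clustering_config("fcm")), "normalized")
  expect_error(run_fcm(matrix(runif(4), 2),
                       clustering_config("csifcm")), "algorithm")
})
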