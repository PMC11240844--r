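test_that("neighborhood conditioning averages memberships over the window", {
  # constant membership stays constant
  memb <- matrix(0.7, 2, 25)
  expect_equal(spatial_condition(memb, c(5, 5), 3), memb)
  # window 1 is the identity
  u <- initialize_partition(25, 3, seed = 2)
  expect_identical(spatial_condition(u, c(5, 5), 1), u)
  # interior 3x3 window: eight neighbors at 0.9, center 0 -> mean 0.8
  m <- matrix(0.9, 1, 9); m[1, 5] <- 0  # pixel 5 = center of a 3x3 image
  h <- spatial_condition(m, c(3, 3), 3)
  expect_equal(h[1, 5], 7.2 / 9)
  expect_error(spatial_condition(u, c(5, 5), 4), "odd")
})

test_that("shrinking-window conditioning matches the loop oracle at borders", {
  for (w in c(3, 5)) {
    u <- initialize_partition(120, 3, seed = w)
    expect_equal(spatial_condition(u, c(10, 12), w),
                 oracle_spatial_condition(u, c(10, 12), w), tolerance = 1e-12)
  }
})

test_that("conditioning preserves unit column sums away from borders", {
  u <- initialize_partition(100, 4, seed = 9)
  h <- spatial_condition(u, c(10, 10), 3)
  interior <- as.vector(t(matrix(seq_len(100), 10, 10,
                                 byrow = TRUE)[2:9, 2:9]))
  expect_equal(colSums(h)[interior], rep(1, length(interior)),
               tolerance = 1e-9)
})

test_that("conditional membership rescales the fcm membership by h", {
  # h = 1 reduces to plain FCM membership
  mu <- fcm_membership(c(0.25, 0.6), c(0, 1), 2)
  expect_equal(conditional_membership(c(0.25, 0.6), c(0, 1),
                                      matrix(1, 2, 2), 2), mu)
  # a zero h row zeroes that cluster
  h0 <- rbind(c(0, 0), c(1, 1))
  expect_equal(conditional_membership(c(0.25, 0.6), c(0, 1), h0, 2)[1, ],
               c(0, 0))
  # x = 0.25, centers {0, 1}, h = {0.5, 1} -> u* = {0.45, 0.1}
  ustar <- conditional_membership(0.25, c(0, 1), cbind(c(0.5, 1)), 2)
  expect_equal(ustar, cbind(c(0.45, 0.1)))
  expect_true(all(colSums(ustar) <= 1 + 1e-12))
})

test_that("yager complement hits its closed-form and boundary values", {
  expect_equal(yager_nonmembership(0.3, 1), 0.7)
  expect_equal(yager_nonmembership(c(0, 1), 0.7), c(1, 0))
  # alpha = 0.5, u = 0.25: (1 - 0.5)^2 = 0.25
  expect_equal(yager_nonmembership(0.25, 0.5), 0.25)
  expect_error(yager_nonmembership(0.5, 0), "alpha")
  expect_error(yager_nonmembership(0.5, 1.2), "restricted")
  expect_error(yager_nonmembership(1.5, 0.5), "\\[0, 1\\]")
})

test_that("membership, non-membership and hesitation sum to one exactly", {
  u_grid <- matrix(seq(0, 1, length.out = 101), 1)
  for (alpha in c(0.2, 0.5, 0.85, 1)) {
    lam <- yager_nonmembership(u_grid, alpha)
    p <- hesitation_degree(u_grid, lam)
    expect_true(all(p >= -1e-12))
    expect_equal(as.vector(u_grid + lam + p), rep(1, 101), tolerance = 1e-12)
    expect_true(all(lam <= 1 - u_grid + 1e-12))  # IFS constraint u + lam <= 1
  }
})

test_that("hesitation collapses at alpha = 1 and at full non-membership", {
  u <- matrix(runif(20), 2)
  expect_equal(hesitation_degree(u, yager_nonmembership(u, 1)),
               matrix(0, 2, 10))
  expect_equal(hesitation_degree(0, yager_nonmembership(0, 0.85)), 0)
  # alpha = 0.5, u = 0.25: pi = 1 - 0.25 - 0.25 = 0.5
  expect_equal(hesitation_degree(0.25, yager_nonmembership(0.25, 0.5)), 0.5)
  expect_error(hesitation_degree(0.8, 0.5), "exceeds 1")
})

test_that("intuitionistic membership adds hesitation and is monotone in u", {
  u <- seq(0, 1, length.out = 51)
  for (alpha in c(0.3, 0.85, 1)) {
    p <- hesitation_degree(u, yager_nonmembership(u, alpha))
    mustar <- intuitionistic_membership(u, p)
    expect_true(all(mustar >= u - 1e-12))
    expect_true(all(diff(mustar) >= -1e-12))  # non-decreasing in u
    expect_true(all(mustar >= 0 & mustar <= 1 + 1e-12))
  }
  expect_equal(intuitionistic_membership(
    0.25, hesitation_degree(0.25, yager_nonmembership(0.25, 0.5))), 0.75)
  u1 <- hesitation_degree(1, yager_nonmembership(1, 0.6))
  expect_equal(intuitionistic_membership(1, u1), 1)
})

test_that("weighted membership normalizes the p-q product per pixel", {
  # c = 1: always 1
  expect_equal(weighted_membership(matrix(0.4, 1, 3), matrix(0.2, 1, 3), 1, 2),
               matrix(1, 1, 3))
  # p = 0, q = 1: secondary renormalized
  sec <- rbind(c(0.4, 0.1), c(0.1, 0.3))
  w <- weighted_membership(matrix(0.9, 2, 2), sec, 0, 1)
  expect_equal(w, sweep(sec, 2, colSums(sec), "/"))
  # hand-computed: products {0.151875, 0.003}, normalized
  w2 <- weighted_membership(cbind(c(0.75, 0.30)), cbind(c(0.45, 0.10)), 1, 2)
  expect_equal(w2, cbind(c(0.151875, 0.003) / 0.154875), tolerance = 1e-12)
  expect_equal(as.vector(round(w2, 5)), c(0.98063, 0.01937))
  expect_error(weighted_membership(sec, sec, 0, 0), "not both zero")
})

test_that("an all-zero product column falls back to uniform membership", {
  prim <- rbind(c(0, 0.5), c(0, 0.5))
  expect_warning(w <- weighted_membership(prim, prim, 1, 1), "all-zero")
  expect_equal(w[, 1], c(0.5, 0.5))
  expect_equal(colSums(w), c(1, 1))
})

test_that("weighted membership matches the brute-force loop oracle", {
  for (s in 1:10) {
    set.seed(200 + s)
    a <- matrix(runif(40), 4); b <- matrix(runif(40), 4)
    p <- sample(0:3, 1); q <- sample(1:3, 1)
    expect_equal(weighted_membership(a, b, p, q),
                 oracle_weighted_membership(a, b, p, q), tolerance = 1e-12)
  }
})
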