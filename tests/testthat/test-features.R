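# Feature engine: Morlet band power, permutation statistics, cluster-mass
# correction, feature assembly.

test_that("band power localizes a pure oscillation and scales quadratically", {
  fs <- 250; n_t <- 300
  tt <- (0:(n_t - 1)) / fs
  arr <- array(0, c(2, 2, n_t))
  arr[1, 1, ] <- sin(2 * pi * 10 * tt)        # alpha at channel 1, trial 1
  arr[2, 1, ] <- 2 * sin(2 * pi * 10 * tt)    # doubled amplitude, trial 2
  ep <- structure(list(data = arr, times_ms = tt * 1000,
                       labels = c("a", "b"), kept = c(TRUE, TRUE),
                       channel_labels = c("C1", "C2"), sampling_rate = fs),
                  class = "epoch_set")
  bp <- band_power(ep)
  mid <- which(bp$times_ms > 400 & bp$times_ms < 800)
  by_band <- vapply(seq_along(bp$band_names),
                    function(b) mean(bp$power[1, 1, b, mid]), 1)
  names(by_band) <- bp$band_names
  expect_true(all(by_band["alpha"] >= 10 * by_band[-1]))
  expect_true(all(bp$power[, 2, , ] < 1e-12))  # silent channel -> zero
  ratio <- mean(bp$power[2, 1, 1, mid]) / mean(bp$power[1, 1, 1, mid])
  expect_lt(abs(ratio - 4) / 4, 0.01)          # amplitude x2 -> power x4
  expect_true(all(bp$power >= 0))
})

test_that("band power rejects bands at the Nyquist frequency", {
  ep <- make_test_epochs(n_s = 2, n_n = 2, n_t = 300)
  bad <- band_set(); bad$high[5] <- 130
  expect_error(band_power(ep, bad), "Nyquist")
})

test_that("4+4 permutation p-values equal exhaustive enumeration", {
  withr::with_seed(9, {
    s <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
    n <- array(rnorm(4 * 2 * 5, mean = 0.8), c(4, 2, 5))
  })
  map <- pointwise_permutation(s, n, n_perm = 100, seed = 1)
  expect_true(map$exact)
  expect_equal(map$n_perm, 70)
  # brute-force oracle: enumerate all 70 splits of the 8 trials, Welch t
  X <- rbind(matrix(s, 4, 10), matrix(n, 4, 10))
  welch <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  sets <- combn(8, 4)
  for (pt in 1:10) {
    tobs <- abs(welch(X[1:4, pt], X[5:8, pt]))
    count <- sum(vapply(seq_len(ncol(sets)), function(j) {
      g1 <- sets[, j]
      abs(welch(X[g1, pt], X[-g1, pt])) >= tobs - 1e-12
    }, TRUE))
    expect_equal(map$p[pt], count / 70)
  }
  # and the observed t equals the direct formula
  expect_equal(map$t[1], welch(X[1:4, 1], X[5:8, 1]))
})

test_that("pointwise flag rate under the null matches alpha", {
  # Monte-Carlo null oracle, scaled down: 200 simulated 2x10 maps
  rates <- vapply(1:200, function(i) {
    withr::with_seed(1000 + i, {
      a <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
      b <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
    })
    map <- pointwise_permutation(a, b, n_perm = 200, seed = i)
    mean(map$sig_mask)
  }, 1)
  se <- sqrt(0.05 * 0.95 / (200 * 20))
  expect_lt(abs(mean(rates) - 0.05), 3 * se)
})

test_that("a planted 3-SD shift is detected pointwise", {
  hits <- vapply(1:50, function(i) {
    ep <- make_test_epochs(n_s = 15, n_n = 15, n_ch = 2, n_t = 10,
                           shift = 3, shift_ch = 1, shift_t = 5,
                           seed = 3000 + i)
    map <- pointwise_permutation(ep$data[1:15, , , drop = FALSE],
                                 ep$data[16:30, , , drop = FALSE],
                                 n_perm = 500, seed = i)
    map$sig_mask[1, 5]
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("degenerate zero-variance points yield t = 0, p = 1", {
  a <- array(1, c(5, 1, 3)); b <- array(1, c(5, 1, 3))
  map <- pointwise_permutation(a, b, n_perm = 50, seed = 1, exact = FALSE)
  expect_true(all(map$t == 0))
  expect_true(all(map$p == 1))
})

test_that("cluster decomposition matches the flood-fill oracle", {
  labs <- model60_labels()[1:6]
  adj <- montage_adjacency(labs)
  withr::with_seed(12, {
    a <- array(rnorm(25 * 6 * 20), c(25, 6, 20))
    b <- array(rnorm(25 * 6 * 20), c(25, 6, 20))
  })
  a[, 2, 5:9] <- a[, 2, 5:9] + 1.2
  b[, 5, 14:16] <- b[, 5, 14:16] + 1.2
  map <- pointwise_permutation(a, b, n_perm = 200, seed = 4,
                               channel_labels = labs)
  cfs <- cluster_mass(map, adj, alpha = 0.05)
  oracle <- oracle_clusters(map$t, map$sig_mask, adj)
  expect_equal(length(cfs$clusters), length(oracle$mass))
  got <- sort(vapply(cfs$clusters, function(cl) cl$mass, 1))
  expect_equal(got, sort(oracle$mass))
  # member sets agree cluster by cluster (matched by mass)
  for (cl in cfs$clusters) {
    oid <- which(abs(oracle$mass - cl$mass) < 1e-10)
    omem <- which(oracle$labels == oid, arr.ind = TRUE)
    expect_setequal(paste(cl$members$channel, cl$members$time),
                    paste(omem[, 1], omem[, 2]))
    expect_equal(sum(map$t[as.matrix(cl$members[, c("channel", "time")])]),
                 cl$mass)
    # sign consistency
    expect_identical(cl$sign,
                     if (cl$mass > 0) "smoking>neutral" else "smoking<neutral")
  }
  # corrected p matches an independent R replay of the same permutations
  res <- cueloop:::perm_t_matrix(map$X, map$n1, map$n_perm, map$seed,
                                 map$exact)
  null_max <- vapply(seq_len(nrow(res$t)), function(j) {
    tm <- matrix(res$t[j, ], 6, 20)
    mk <- matrix(res$p[j, ], 6, 20) < map$alpha
    oc <- oracle_clusters(tm, mk, adj)
    if (length(oc$mass)) max(abs(oc$mass)) else 0
  }, 1)
  for (cl in cfs$clusters)
    expect_equal(cl$corrected_p, mean(null_max >= abs(cl$mass)))
})

test_that("trivial cluster shapes behave per the adjacency contract", {
  labs <- model60_labels()[1:3]
  adj <- montage_adjacency(labs)
  tmap <- matrix(0, 3, 10)
  mask <- matrix(FALSE, 3, 10)
  tmap[2, 4] <- 3.1; mask[2, 4] <- TRUE           # isolated point
  found <- cueloop:::cpp_find_clusters(tmap, mask, cueloop:::adjacency_to_list(adj, 3))
  expect_equal(found$mass, 3.1)
  tmap[2, 5] <- 2.5; mask[2, 5] <- TRUE           # time-adjacent point
  found <- cueloop:::cpp_find_clusters(tmap, mask, cueloop:::adjacency_to_list(adj, 3))
  expect_equal(found$mass, 5.6)                   # one merged cluster
  # opposite signs do not merge
  tmap[2, 6] <- -2.0; mask[2, 6] <- TRUE
  found <- cueloop:::cpp_find_clusters(tmap, mask, cueloop:::adjacency_to_list(adj, 3))
  expect_equal(sort(found$mass), c(-2.0, 5.6))
})

test_that("empty suprathreshold masks yield an empty cluster set", {
  a <- make_test_epochs(n_s = 10, n_n = 10, n_ch = 2, n_t = 8, seed = 5)
  map <- pointwise_permutation(a$data[1:10, , , drop = FALSE],
                               a$data[11:20, , , drop = FALSE],
                               n_perm = 100, seed = 1)
  map$sig_mask[] <- FALSE
  cfs <- cluster_mass(map, NULL)
  expect_length(cfs$clusters, 0)
})

test_that("feature assembly averages cluster members per trial", {
  ep <- make_test_epochs(n_s = 4, n_n = 4, n_ch = 3, n_t = 10, seed = 6)
  mk_cluster <- function(members) {
    structure(list(clusters = list(list(
      domain = "amplitude", sign = "smoking>neutral",
      members = members, mass = 1, corrected_p = 0.01, keep = TRUE)),
      alpha = 0.05, domain = "amplitude"),
      class = "cluster_feature_set")
  }
  one <- mk_cluster(data.frame(channel = 2L, time = 7L,
                               time_ms = ep$times_ms[7]))
  f <- assemble_features(ep, one)
  expect_equal(dim(f), c(8, 1))
  expect_equal(f[, 1], ep$data[, 2, 7])           # single point passthrough
  # mean over members, and linearity in the data
  two <- mk_cluster(data.frame(channel = c(1L, 2L), time = c(3L, 7L),
                               time_ms = ep$times_ms[c(3, 7)]))
  f2 <- assemble_features(ep, two)
  expect_equal(f2[, 1], (ep$data[, 1, 3] + ep$data[, 2, 7]) / 2)
  ep2 <- ep; ep2$data <- 2 * ep$data + 0
  expect_equal(assemble_features(ep2, two), 2 * f2)
  # empty recipe is a hard error
  empty <- structure(list(clusters = list(), alpha = 0.05),
                     class = "cluster_feature_set")
  expect_error(assemble_features(ep, empty), "no discriminative features")
})

test_that("online windows map onto the post-stimulus timebase", {
  fx <- compact_pipeline()
  # a window equal to a kept smoking epoch (0..1000 ms part) scores like
  # that epoch: template-separation with positive margin
  tpl <- smoking_template(fx$spec, 250)
  midx <- match(fx$model_labels, fx$spec$channels)
  f_smk <- assemble_features(tpl[midx, , drop = FALSE], fx$featset,
                             fs = 250)
  f_neu <- assemble_features(matrix(0, length(midx), 250,
                                    dimnames = list(fx$model_labels, NULL)),
                             fx$featset, fs = 250)
  d_smk <- cueloop:::decision_value(fx$decoder, f_smk)
  d_neu <- cueloop:::decision_value(fx$decoder, f_neu)
  expect_gt(d_smk - d_neu, 0)
  expect_equal(ncol(f_smk), length(fx$featset$clusters))
  # pre-stimulus members are dropped for window input
  pre <- structure(list(clusters = list(list(
    domain = "amplitude", sign = "smoking>neutral",
    members = data.frame(channel = 1L, time = 1L, time_ms = -200),
    mass = 1, corrected_p = 0.01, keep = TRUE)), alpha = 0.05),
    class = "cluster_feature_set")
  w <- matrix(rnorm(length(midx) * 250), length(midx))
  expect_equal(assemble_features(w, pre, fs = 250)[1, 1], 0)
})
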