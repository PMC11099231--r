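test_that("cluster extraction matches known masks", {
  expect_equal(find_clusters(c(T, T, T, F, F, F), 3), list(c(1L, 3L)))
  expect_equal(find_clusters(c(T, T, F, T, T, T), 3), list(c(4L, 6L)))
  expect_equal(find_clusters(rep(FALSE, 6), 3), list())
})

test_that("cluster extraction equals a brute-force scan on all length-10 masks", {
  brute <- function(mask, min_len) {
    out <- list()
    i <- 1
    while (i <= length(mask)) {
      if (mask[i]) {
        j <- i
        while (j < length(mask) && mask[j + 1]) j <- j + 1
        if (j - i + 1 >= min_len) out[[length(out) + 1]] <- c(i, j)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    out
  }
  for (code in 0:1023) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:9), 1))
    for (min_len in c(1, 3)) {
      expect_equal(find_clusters(mask, min_len),
                   lapply(brute(mask, min_len), as.integer))
    }
  }
})

test_that("two planted topographies cluster into two temporal regimes", {
  set.seed(30)
  topoA <- rnorm(20)
  topoB <- rnorm(20)
  fm <- rbind(
    t(replicate(25, topoA + rnorm(20, sd = 0.2))),
    t(replicate(25, topoB + rnorm(20, sd = 0.2))))
  centers <- seq(0, by = 10, length.out = 50)
  rep1 <- cluster_topographies(fm, centers, k_range = 2:6, seed = 31)
  expect_equal(rep1$k_selected, 2)
  expect_equal(nrow(rep1$component_windows), 2)
  expect_equal(rep1$component_windows$end_idx[1], 25)
  expect_length(rep1$transition_points_ms, 1)
  rep2 <- cluster_topographies(fm, centers, k_range = 2:6, seed = 31)
  expect_identical(rep1$labels, rep2$labels)
  expect_error(
    cluster_topographies(matrix(1, 30, 4), k_range = 2:3, seed = 1),
    class = "driftdecode_degenerate_error")
})

test_that("normalization clusters by topography direction, not strength", {
  set.seed(33)
  topoA <- rnorm(16)
  topoA <- topoA / sqrt(sum(topoA^2))
  topoB <- rnorm(16)
  topoB <- topoB - topoA * sum(topoA * topoB)
  topoB <- topoB / sqrt(sum(topoB^2))
  # raised-cosine-like magnitude ramp within each temporal regime
  gains <- 0.3 + 0.7 * sin(seq(0.1, pi - 0.1, length.out = 15))
  fm <- rbind(t(sapply(gains, function(g) g * topoA + rnorm(16, 0, 0.04))),
              t(sapply(gains, function(g) g * topoB + rnorm(16, 0, 0.04))))
  normalized <- cluster_topographies(fm, k_range = 2:6, seed = 34)
  expect_equal(normalized$k_selected, 2)
  expect_equal(normalized$component_windows$end_idx[1], 15)
  # the raw-intensity route stays available and returns a valid report
  raw <- cluster_topographies(fm, k_range = 2:6, seed = 34,
                              normalize = FALSE)
  expect_true(raw$k_selected %in% 2:6)
})

test_that("the paired bootstrap flags exact equality as null", {
  set.seed(32)
  az <- matrix(runif(10 * 20, 0.4, 0.6), 10, 20)
  res <- bootstrap_az_difference(az, az, n_boot = 200, seed = 33)
  expect_true(all(res$mean_diff == 0))
  expect_false(any(res$sig_mask))
})

test_that("a strong constant offset is significant everywhere", {
  set.seed(34)
  base <- matrix(0.5 + rnorm(20 * 15, sd = 0.01), 20, 15)
  res <- bootstrap_az_difference(base + 0.2, base, n_boot = 400,
                                 seed = 35)
  expect_true(all(res$sig_mask))
  expect_true(all(res$ci_low > 0.15))
  expect_error(bootstrap_az_difference(base[1:3, ], base[1:3, ]),
               class = "driftdecode_data_error")
})

test_that("bootstrap CIs shrink with more subjects", {
  width_at <- function(n_subj) {
    set.seed(36)
    a <- matrix(rnorm(n_subj * 10, 0, 0.05), n_subj, 10)
    b <- matrix(rnorm(n_subj * 10, 0, 0.05), n_subj, 10)
    res <- bootstrap_az_difference(a, b, n_boot = 400, seed = 37)
    mean(res$ci_high - res$ci_low)
  }
  expect_lt(width_at(40), width_at(10))
})

test_that("the window-level bootstrap test is roughly calibrated", {
  set.seed(38)
  n_sims <- 60
  frac_sig <- vapply(seq_len(n_sims), function(i) {
    a <- matrix(rnorm(20 * 25, 0, 0.05), 20, 25)
    b <- matrix(rnorm(20 * 25, 0, 0.05), 20, 25)
    mean(bootstrap_az_difference(a, b, n_boot = 300,
                                 seed = 1000 + i)$sig_mask)
  }, numeric(1))
  se <- sd(frac_sig) / sqrt(n_sims)
  expect_lte(mean(frac_sig), 0.05 + 2 * se + 0.02)
})

test_that("the cluster criterion is floored at three samples", {
  set.seed(39)
  a <- matrix(rnorm(12 * 40, 0, 0.05), 12, 40)
  b <- matrix(rnorm(12 * 40, 0, 0.05), 12, 40)
  crit1 <- max_cluster_null(a, b, n_perm = 100, n_boot = 100, seed = 40)
  crit2 <- max_cluster_null(a, b, n_perm = 100, n_boot = 100, seed = 40)
  expect_identical(crit1, crit2)
  expect_gte(crit1, 3)
  expect_lte(crit1, 6) # null data: small criterion
  expect_length(attr(crit1, "null_max_sizes"), 100)
})

test_that("participant consistency counts sign agreement with the group", {
  d_all <- matrix(0.1, 10, 8)
  expect_equal(participant_consistency(d_all, c(2, 5)), 1)
  # 29 of 39 subjects positive with a positive group mean
  d_mix <- matrix(rep(c(0.2, -0.1), c(29, 10)), 39, 4)
  expect_equal(participant_consistency(d_mix, c(1, 4)), 29 / 39,
               tolerance = 1e-12)
  # antisymmetric set: group mean exactly zero -> undefined
  d_anti <- matrix(rep(c(0.3, -0.3), each = 5), 10, 4)
  expect_true(is.na(participant_consistency(d_anti, c(1, 4))))
  expect_error(participant_consistency(d_all, c(5, 20)),
               class = "driftdecode_range_error")
})

test_that("group inference is invariant to subject ordering", {
  set.seed(41)
  a <- matrix(rnorm(10 * 12, 0.05, 0.04), 10, 12)
  b <- matrix(rnorm(10 * 12, 0.00, 0.04), 10, 12)
  res <- group_inference(a, b, n_boot = 150, n_perm = 60, seed = 42)
  perm <- sample(10)
  res_p <- group_inference(a[perm, ], b[perm, ], n_boot = 150,
                           n_perm = 60, seed = 42)
  expect_equal(res_p$mean_diff, res$mean_diff)
  expect_equal(res_p$consistency, res$consistency)
  # surviving significance is exactly cluster membership
  in_cluster <- rep(FALSE, 12)
  for (cl in res$clusters) in_cluster[cl[1]:cl[2]] <- TRUE
  expect_equal(res$sig_mask, in_cluster)
})
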