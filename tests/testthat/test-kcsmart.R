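test_that("kernel weights follow the truncated Gaussian", {
  sp <- kernel_spec(20)
  sigma <- sp$sigma_mb * 1e6
  expect_equal(kernel_weight(0, sp), 1)
  expect_equal(kernel_weight(sigma, sp), exp(-1 / 2))
  expect_equal(kernel_weight(-sigma, sp), kernel_weight(sigma, sp))
  expect_equal(kernel_weight(2 * sigma, sp), exp(-2))
  expect_equal(kernel_weight(2 * sigma + 1, sp), 0)
  expect_equal(sp$sigma_mb, 5)
})

test_that("smoothing a constant profile returns the constant", {
  map <- small_map()
  cohort <- noise_cohort(map, 2, 2, noise = 0, seed = 1)
  cohort$values[] <- 0.7
  ks <- kse_matrix(cohort, kernel_spec(20), 1e6)
  expect_true(all(abs(ks$values - 0.7) < 1e-12))
})

test_that("a single spike decays monotonically away from its probe", {
  map <- make_probe_map(c(chr1 = 60e6), 1e6)
  vals <- matrix(0, nrow(map), 2,
                 dimnames = list(map$probe_id, c("s1", "s2")))
  vals[30, ] <- 1
  cohort <- acgh_cohort(map, vals,
                        data.frame(sample_id = c("s1", "s2"), group = "G",
                                   platform = "p"))
  cv <- kse_profile(cohort, "s1", kernel_spec(20), 1e6)
  x0 <- map$midpos[30]
  at0 <- cv$values[which.min(abs(cv$grid$pos - x0))]
  expect_lt(at0, 1)
  expect_gt(at0, 0)
  # strictly decreasing over the first 5 Mb to the right
  right <- cv$values[cv$grid$pos >= x0 & cv$grid$pos <= x0 + 5e6]
  expect_true(all(diff(right) < 0))
})

test_that("the smoother equals a brute-force kernel sum on random chromosomes", {
  sp <- kernel_spec(20)
  set.seed(99)
  for (rep in 1:5) {
    map <- make_probe_map(c(chr1 = 50e6), 250000, jitter_bp = 1e5,
                          seed = rep)
    stopifnot(nrow(map) == 200)
    vals <- matrix(rnorm(200), 200, 1, dimnames = list(map$probe_id, "s1"))
    cohort <- acgh_cohort(map, vals,
                          data.frame(sample_id = "s1", group = "G",
                                     platform = "p"))
    ks <- kse_matrix(cohort, sp, 1e6)
    brute <- vapply(ks$grid$pos, function(x) {
      w <- kernel_weight(x - map$midpos, sp)
      sum(w * vals[, 1]) / sum(w)
    }, numeric(1))
    expect_lt(max(abs(brute - ks$values[, 1])), 1e-12)
  }
})

test_that("smoothing is scale-equivariant and chromosome-local", {
  map <- small_map()
  cohort <- noise_cohort(map, 3, 2, noise = 0.5, seed = 12)
  ks1 <- kse_matrix(cohort, kernel_spec(20), 1e6)
  scaled <- cohort
  scaled$values <- 3 * scaled$values
  ks3 <- kse_matrix(scaled, kernel_spec(20), 1e6)
  expect_equal(ks3$values, 3 * ks1$values, tolerance = 1e-12)
  # perturbing chr1 probes leaves chr2 bit-identical
  pert <- cohort
  pert$values[pert$map$chrom == "chr1", ] <-
    pert$values[pert$map$chrom == "chr1", ] + 5
  ks_p <- kse_matrix(pert, kernel_spec(20), 1e6)
  i2 <- ks1$grid$chrom == "chr2"
  expect_identical(ks_p$values[i2, ], ks1$values[i2, ])
  expect_false(isTRUE(all.equal(ks_p$values[!i2, ], ks1$values[!i2, ])))
})

test_that("signed KSE decomposes into gains and losses components", {
  map <- small_map()
  cohort <- noise_cohort(map, 4, 2, noise = 0.5, seed = 13)
  sp <- kernel_spec(20)
  ks <- kse_matrix(cohort, sp, 1e6)
  gains <- kse_matrix(cohort, sp, 1e6, values = pmax(cohort$values, 0))
  losses <- kse_matrix(cohort, sp, 1e6, values = pmin(cohort$values, 0))
  expect_equal(ks$values, gains$values + losses$values, tolerance = 1e-12)
})

test_that("group curves respect sign constraints and gain/loss symmetry", {
  map <- small_map()
  cohort <- noise_cohort(map, 5, 3, noise = 0.4, seed = 14)
  gk <- group_kse(cohort, "A", kernel_spec(20), 1e6)
  expect_true(all(gk$gains$values >= 0))
  expect_true(all(gk$losses$values <= 0))
  neg <- cohort
  neg$values <- -neg$values
  gk_neg <- group_kse(neg, "A", kernel_spec(20), 1e6)
  expect_equal(gk_neg$gains$values, -gk$losses$values, tolerance = 1e-12)
  # all-zero group
  z <- cohort
  z$values[] <- 0
  gz <- group_kse(z, "B", kernel_spec(20), 1e6)
  expect_true(all(gz$gains$values == 0) && all(gz$losses$values == 0))
  # single all-positive tumor: gains curve is the signed curve
  one <- cohort
  one$values[, 1] <- abs(one$values[, 1]) + 0.1
  g1 <- kse_matrix(one, kernel_spec(20), 1e6,
                   values = pmax(one$values[, 1, drop = FALSE], 0))
  s1 <- kse_matrix(one, kernel_spec(20), 1e6,
                   values = one$values[, 1, drop = FALSE])
  expect_equal(g1$values, s1$values, tolerance = 1e-12)
  expect_error(group_kse(cohort, "nope"), "unknown")
})

test_that("single-group thresholds hit the alpha = 1 limit and recover a spike", {
  map <- small_map()
  spike <- spike_cohort(map, 8, 2, amplitude = 1, noise = 0.2, seed = 15)
  res <- single_group_threshold(spike$cohort, "A", kernel_spec(20), 1e6,
                                alpha = 0.05, n_perm = 50, seed = 7)
  gain_regs <- res$regions[res$regions$direction == "gain", ]
  expect_gte(interval_jaccard(gain_regs, "chr1", 20e6, 40e6, 1e6), 0.5)
  # alpha = 1: threshold at the null minimum, everything positive significant
  res1 <- single_group_threshold(spike$cohort, "A", kernel_spec(20), 1e6,
                                 alpha = 1, n_perm = 20, seed = 7)
  expect_lte(res1$gain_threshold, res$gain_threshold)
  expect_gt(nrow(res1$regions), 0)
})

test_that("single-group genome-wide error rate is near alpha on pure noise", {
  map <- small_map(n_chr = 2, chr_mb = 60)
  alpha <- 0.25
  hits <- 0L
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    cohort <- noise_cohort(map, 6, 2, noise = 0.3, seed = 100 + r)
    res <- single_group_threshold(cohort, "A", kernel_spec(20), 2e6,
                                  alpha = alpha, n_perm = 60,
                                  seed = 200 + r)
    hits <- hits + as.integer(nrow(res$regions[res$regions$direction ==
                                                 "gain", ]) > 0)
  }
  rate <- hits / n_rep
  # binomial 99.7% band around alpha for n = 30
  expect_gte(rate, alpha - 3 * sqrt(alpha * (1 - alpha) / n_rep))
  expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
})
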