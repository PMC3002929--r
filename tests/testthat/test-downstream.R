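test_that("aberration counting matches a brute-force summit scan", {
  # flat and plateau cases
  expect_equal(count_cna_segments(rep(0, 100), 0.3), 0)
  v <- rep(0, 100); v[30:59] <- 0.5
  expect_equal(count_cna_segments(v, 0.3), 1)
  expect_equal(count_cna_segments(v, 0.6), 0)
  v[40] <- -0.4 # a dip splits the plateau into two summits
  expect_equal(count_cna_segments(v, 0.3), 3)
  # random curves vs an independent element-wise scan oracle
  set.seed(61)
  brute_count <- function(v, chrom, t) {
    total <- 0L
    for (ch in unique(chrom)) {
      for (sgn in c(1, -1)) {
        x <- sgn * v[chrom == ch]
        n <- length(x)
        for (i in seq_len(n)) {
          if (x[i] <= t) next
          # strict rise on the left (skipping the plateau), fall on right
          l <- i - 1L
          while (l >= 1 && x[l] == x[i]) l <- l - 1L
          r <- i + 1L
          while (r <= n && x[r] == x[i]) r <- r + 1L
          left_ok <- l < 1 || x[l] < x[i]
          right_ok <- r > n || x[r] < x[i]
          # count each plateau once, at its first element
          first_of_plateau <- i == 1L || x[i - 1L] != x[i]
          if (left_ok && right_ok && first_of_plateau)
            total <- total + 1L
        }
      }
    }
    total
  }
  for (rep in 1:20) {
    chrom <- rep(c("c1", "c2"), each = 50)
    v <- rnorm(100, sd = 0.5)
    t <- runif(1, 0.05, 1)
    expect_equal(count_cna_segments(v, t, chrom), brute_count(v, chrom, t))
  }
  # exact monotonicity in the cutoff on random curves
  for (rep in 1:10) {
    v <- rnorm(200, sd = 0.5)
    counts <- vapply(seq(0.05, 1, by = 0.05), count_cna_segments,
                     integer(1), curve = v)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("burden counts are monotone in the cutoff and medians separate burden levels", {
  map <- small_map(n_chr = 4, chr_mb = 100)
  segs <- list()
  for (k in 1:4) {
    segs[[k]] <- cna_segment(paste0("chr", k), 10e6, 30e6,
                             if (k %% 2) "gain" else "loss",
                             if (k %% 2) 0.8 else -0.8, 0,
                             penetrance = c(high = 1,
                                            low = if (k <= 1) 1 else 0))
    segs[[k + 4]] <- cna_segment(paste0("chr", k), 60e6, 80e6, "gain", 0.8,
                                 0, penetrance = c(high = 1,
                                                   low = if (k <= 1) 1 else 0))
  }
  spec <- cohort_spec(c(high = 10, low = 10), segs, probe_noise_sd = 0.2,
                      tumor_fraction_range = c(1, 1), seed = 62)
  sim <- simulate_cohort(map, spec)
  bt <- burden_table(sim$cohort, c("high", "low"), kernel_spec(20), 1e6,
                     cutoffs = seq(0.05, 1, by = 0.05))
  expect_true(all(apply(bt$counts, 1, function(r) all(diff(r) <= 0))))
  mid <- bt$cutoffs >= 0.1 & bt$cutoffs <= 0.6
  expect_true(all(bt$medians["high", mid] > bt$medians["low", mid]))
})

test_that("the burden group test matches the Welch closed form on a 3-vs-3 example", {
  # noise-free cohort engineered so tumor j carries exactly k_j aberrations
  map <- small_map(n_chr = 4, chr_mb = 100)
  slots <- list()
  for (ch in paste0("chr", 1:4)) {
    slots[[length(slots) + 1]] <- map$chrom == ch & map$midpos >= 10e6 &
      map$midpos < 30e6
    slots[[length(slots) + 1]] <- map$chrom == ch & map$midpos >= 60e6 &
      map$midpos < 80e6
  }
  k_high <- c(4, 6, 8); k_low <- c(1, 2, 3)
  vals <- matrix(0, nrow(map), 6,
                 dimnames = list(map$probe_id, paste0("s", 1:6)))
  for (j in 1:6) {
    k <- c(k_high, k_low)[j]
    for (s in seq_len(k)) vals[slots[[s]], j] <- 1
  }
  cohort <- acgh_cohort(map, vals,
                        data.frame(sample_id = paste0("s", 1:6),
                                   group = rep(c("high", "low"), each = 3),
                                   platform = "p"))
  bt <- burden_table(cohort, c("high", "low"), kernel_spec(20), 1e6,
                     cutoffs = 0.5)
  expect_equal(unname(bt$counts[, 1]), c(k_high, k_low))
  x <- k_high; y <- k_low
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  df <- (var(x) / 3 + var(y) / 3)^2 /
    ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_manual <- 2 * pt(-abs(tstat), df)
  expect_equal(bt$p_value[1], p_manual, tolerance = 1e-12)
})

test_that("two identical groups rarely reach significance in the burden sweep", {
  map <- small_map(n_chr = 2, chr_mb = 80)
  n_sig <- 0L
  for (r in 1:15) {
    cohort <- noise_cohort(map, 6, 6, noise = 0.25, seed = 300 + r)
    bt <- burden_table(cohort, c("A", "B"), kernel_spec(20), 2e6,
                       cutoffs = seq(0.02, 0.3, by = 0.04))
    n_sig <- n_sig + as.integer(any(bt$p_value < 0.01, na.rm = TRUE))
  }
  expect_lte(n_sig, 3) # ~5% per-cutoff chance; allow generous slack
})

test_that("region means equal a direct masked mean", {
  map <- small_map()
  cohort <- noise_cohort(map, 3, 2, noise = 0.4, seed = 63)
  ks <- kse_matrix(cohort, kernel_spec(20), 1e6)
  regs <- region_table(c("chr1", "chr2"), c(10.0, 40.0), c(30.0, 80.0),
                       c("gain", "loss"), "G")
  rm <- region_mean_matrix(ks, regs)
  for (i in 1:2) {
    idx <- ks$grid$chrom == regs$chrom[i] &
      ks$grid$pos >= regs$start_mb[i] * 1e6 &
      ks$grid$pos < regs$end_mb[i] * 1e6
    expect_equal(rm[, i], colMeans(ks$values[idx, , drop = FALSE]))
  }
  # constant curve -> every region mean equals the constant
  kc <- ks; kc$values[] <- 0.42
  expect_true(all(region_mean_matrix(kc, regs) == 0.42))
  # unknown chromosome errors
  bad <- region_table("chr9", 1, 2, "gain", "G")
  expect_error(region_mean_matrix(ks, bad), "chr9")
})

test_that("clustering separates groups, keeps twins together, ignores input order", {
  set.seed(64)
  # architectures must differ in shape: Pearson distance ignores offset/scale
  base_a <- c(rep(1, 5), rep(0, 5))
  base_b <- c(rep(0, 5), rep(-1, 2), rep(1, 3))
  mk <- function(base, n, tag) {
    m <- t(replicate(n, base + rnorm(10, sd = 0.2)))
    rownames(m) <- paste0(tag, seq_len(n))
    m
  }
  mat <- rbind(mk(base_a, 8, "a"), mk(base_b, 8, "b"))
  colnames(mat) <- paste0("r", 1:10)
  groups <- rep(c("A", "B"), each = 8)
  res <- cluster_tumors(mat, 2, groups)
  purity <- sum(apply(res$composition, 2, max)) / length(groups)
  expect_gte(purity, 15 / 16)
  # duplicated sample lands with its twin
  mat2 <- rbind(mat, twin = mat["a1", ])
  res2 <- cluster_tumors(mat2, 2)
  expect_equal(unname(res2$branches["twin"]), unname(res2$branches["a1"]))
  # permutation invariance of the branch partition
  perm <- sample(nrow(mat))
  res_p <- cluster_tumors(mat[perm, ], 2, groups[perm])
  agree <- outer(res$branches, res$branches, "==")
  agree_p <- outer(res_p$branches[rownames(mat)],
                   res_p$branches[rownames(mat)], "==")
  expect_true(all(agree == agree_p))
  # distance matrix properties
  d <- as.matrix(1 - cor(t(mat)))
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) < 1e-12))
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
  # zero-variance sample is named in the error
  mat3 <- rbind(mat, flatliner = rep(1, 10))
  expect_error(cluster_tumors(mat3, 2), "flatliner")
})

test_that("dendrograms export to Newick", {
  set.seed(65)
  mat <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("r", 1:5)))
  res <- cluster_tumors(mat, 2)
  path <- tempfile(fileext = ".nwk")
  export_newick(res, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(mat))
})
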