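test_that("cross-section features capture offsets and localized dips", {
  s <- seq(0, 1, length.out = 120)
  base <- 5000 + 0 * s
  # group B has a constant offset; some animals carry a localized dip
  profiles <- c(
    lapply(1:5, function(i) base + 40 * i),
    lapply(1:5, function(i) base + 900 + 40 * i))
  cf <- cs_features(profiles)
  # component 1 is (close to) a constant vector
  c1 <- cf$components$value[cf$components$component == "cs_feature_1"]
  expect_lt(sd(c1) / abs(mean(c1)), 0.05)
  expect_gt(cf$variance_fraction[1], 0.9)

  dip <- exp(-0.5 * ((s - 0.8) / 0.03)^2)
  profiles2 <- c(
    lapply(1:5, function(i) base + 30 * rnorm(1)),
    lapply(1:5, function(i) base + 30 * rnorm(1) - 1500 * dip))
  cf2 <- cs_features(profiles2)
  loc <- sapply(paste0("cs_feature_", 1:2), function(cc) {
    sub <- cf2$components[cf2$components$component == cc, ]
    sub$s[which.max(abs(sub$value))]
  })
  expect_true(any(abs(loc - 0.8) < 0.05))

  expect_error(cs_features(profiles[1:4]), class = "gazestab_rank_error")
  expect_error(cs_features(lapply(1:8, function(i) base)),
               class = "gazestab_rank_error")
})

test_that("resampling preserves observed entries and imputes from donors", {
  coh <- make_cohort()
  rs <- resample_cohorts(coh, n_reps = 60, seed = 3)
  # observed entries identical across replicates (after undoing the
  # per-replicate normalization)
  raw <- sweep(sweep(rs$normalized[, , "v2"], 1, rs$scales[, "v2"], "*"),
               1, rs$centers[, "v2"], "+")
  expect_equal(raw[1, ], raw[37, ], tolerance = 1e-12)
  expect_equal(unname(raw[5, ]), coh$v2, tolerance = 1e-12)

  # z-scoring per replicate
  expect_equal(max(abs(apply(rs$normalized, c(1, 3), mean))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(apply(rs$normalized, c(1, 3), sd) - 1)), 0,
               tolerance = 1e-12)

  # singleton donor pool: that value imputed everywhere
  coh1 <- make_cohort(n_per = 2, missing = FALSE)
  coh1$v1[1] <- NA                       # donor pool = the other xenopus
  rs1 <- resample_cohorts(coh1, n_reps = 25, seed = 1)
  raw1 <- sweep(sweep(rs1$normalized[, , "v1"], 1, rs1$scales[, "v1"], "*"),
                1, rs1$centers[, "v1"], "+")
  expect_equal(unname(raw1[, 1]), rep(coh1$v1[2], 25), tolerance = 1e-12)

  # imputed marginal matches the donor pool mean (law of large numbers)
  coh2 <- make_cohort(n_per = 10)
  rs2 <- resample_cohorts(coh2, n_reps = 4000, seed = 8)
  raw2 <- sweep(sweep(rs2$normalized[, , "v1"], 1, rs2$scales[, "v1"], "*"),
                1, rs2$centers[, "v1"], "+")
  pool <- coh2$v1[coh2$species == "xenopus" & !is.na(coh2$v1)]
  imput <- raw2[, 2]                     # animal 2 is missing v1
  se <- sd(pool) / sqrt(length(imput))
  expect_lt(abs(mean(imput) - mean(pool)), 2 * se + 1e-9)

  bad <- make_cohort(n_per = 3, missing = FALSE)
  bad$v5[bad$species == "axolotl"] <- NA
  expect_error(resample_cohorts(bad, n_reps = 5),
               class = "gazestab_coverage_error")
  expect_no_error(resample_cohorts(bad, n_reps = 5, donor = "all"))
})

test_that("averaged components are orthonormal and species-separating", {
  coh <- make_cohort()
  rs <- resample_cohorts(coh, n_reps = 80, seed = 5)
  av <- average_components(rs)
  G <- crossprod(av$rotation)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(av$variance_fraction >= 0))
  expect_lte(sum(av$variance_fraction), 1 + 1e-9)

  rep1 <- representative_dataset(rs)
  sc <- project_cohort(rep1, av)
  x1 <- sc$PC1[sc$species == "xenopus"]
  a1 <- sc$PC1[sc$species == "axolotl"]
  # species separate on PC1 with no overlap, but not on PC2
  expect_true(max(x1) < min(a1) || max(a1) < min(x1))
  x2 <- sc$PC2[sc$species == "xenopus"]
  a2 <- sc$PC2[sc$species == "axolotl"]
  expect_false(max(x2) < min(a2) || max(a2) < min(x2))
})

test_that("sign alignment makes averaging over replicates well defined", {
  coh <- make_cohort(missing = FALSE)
  rs <- resample_cohorts(coh, n_reps = 10, seed = 2)
  # identical replicates (no missing data): average equals single PCA
  av <- average_components(rs)
  single <- prcomp(rs$normalized[1, , ], center = FALSE)
  k <- ncol(av$rotation)
  ref <- gazestab:::align_signs(single$rotation[, seq_len(k)])
  expect_equal(unname(av$rotation), unname(ref), tolerance = 1e-8)

  # manually flipped loadings realign rather than cancel
  flipped <- ref
  flipped[, 1] <- -flipped[, 1]
  expect_equal(gazestab:::align_signs(flipped)[, 1], ref[, 1])
})

test_that("the representative replicate minimizes the distance exhaustively", {
  coh <- make_cohort()
  rs <- resample_cohorts(coh, n_reps = 100, seed = 7)
  rep1 <- representative_dataset(rs)
  mean_rep <- apply(rs$normalized, c(2, 3), mean)
  dists <- vapply(1:100, function(r) sum((rs$normalized[r, , ] - mean_rep)^2),
                  numeric(1))
  expect_equal(rep1$replicate, which.min(dists))
  expect_true(all(dists[rep1$replicate] <= dists))

  # identical replicates: the first wins the tie
  rs0 <- resample_cohorts(make_cohort(missing = FALSE), n_reps = 8, seed = 1)
  expect_equal(representative_dataset(rs0)$replicate, 1L)

  # same seed, same selection
  rsA <- resample_cohorts(coh, n_reps = 50, seed = 33)
  rsB <- resample_cohorts(coh, n_reps = 50, seed = 33)
  expect_equal(representative_dataset(rsA)$replicate,
               representative_dataset(rsB)$replicate)
  expect_identical(rsA$normalized, rsB$normalized)
})

test_that("projection is the plain dot product with shape checks", {
  coh <- make_cohort(missing = FALSE)
  rs <- resample_cohorts(coh, n_reps = 4, seed = 2)
  av <- average_components(rs)
  X <- matrix(0, 2, nrow(av$rotation))
  X[1, ] <- av$rotation[, 1]
  sc <- project_cohort(X, av)
  expect_equal(sc$PC1[1], 1, tolerance = 1e-9)
  expect_equal(unname(unlist(sc[1, paste0("PC", 2:ncol(av$rotation))])),
               rep(0, ncol(av$rotation) - 1), tolerance = 1e-9)
  expect_equal(unname(unlist(sc[2, -1])), rep(0, ncol(av$rotation)),
               tolerance = 1e-12)
  expect_error(project_cohort(X[, -1, drop = FALSE], av),
               class = "gazestab_input_error")
})

test_that("loading maps scale by variance and keep signs", {
  coh <- make_cohort()
  rs <- resample_cohorts(coh, n_reps = 30, seed = 9)
  av <- average_components(rs)
  lm1 <- loading_map(av)
  expect_equal(sign(lm1$scaled[lm1$scaled != 0]),
               sign(lm1$loading[lm1$scaled != 0]))
  merged <- dplyr::left_join(
    lm1,
    tibble(component = colnames(av$rotation), vf = av$variance_fraction),
    by = "component")
  expect_equal(merged$scaled, merged$loading * merged$vf, tolerance = 1e-12)

  # the dominant species-difference variable tops component 1
  pc1 <- lm1[lm1$component == "PC1", ]
  expect_true(pc1$variable[which.max(abs(pc1$scaled))] %in%
                c("v1", "v2", "v3"))
})

test_that("with no missing data the pipeline reduces to plain PCA", {
  coh <- make_cohort(missing = FALSE)
  rs <- resample_cohorts(coh, n_reps = 12, seed = 4)
  av <- average_components(rs)
  rep1 <- representative_dataset(rs)
  sc <- project_cohort(rep1, av)

  M <- as.matrix(coh[paste0("v", 1:6)])
  Z <- scale(M)
  pc <- prcomp(Z, center = FALSE)
  ref_rot <- gazestab:::align_signs(pc$rotation[, seq_len(ncol(av$rotation))])
  expect_equal(unname(av$rotation), unname(ref_rot), tolerance = 1e-8)
  expect_equal(unname(sc$PC1), unname((Z %*% ref_rot)[, 1]), tolerance = 1e-8)
})
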