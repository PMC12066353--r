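test_that("Hill ENS satisfies its identities and matches brute force", {
  # perfectly even community: ENS equals richness
  expect_equal(hill_ens(c(5, 5, 5, 5)), 4)
  expect_equal(hill_ens(7), 1)
  # direct entropy oracle for an uneven community
  x <- c(10, 1, 1)
  p <- x / sum(x)
  expect_equal(hill_ens(x), exp(-sum(p * log(p))), tolerance = 1e-12)
  # vegan cross-check
  expect_equal(hill_ens(x), exp(vegan::diversity(x)), tolerance = 1e-12)
  expect_true(is.na(hill_ens(numeric(0))))
})

test_that("Hill number is continuous at q = 1 and decreasing in q", {
  x <- c(12, 5, 3, 1, 1)
  lim <- vapply(c(0.999, 1.001), function(q) hill_ens(x, q), numeric(1))
  expect_equal(hill_ens(x, 1), mean(lim), tolerance = 1e-4)
  qs <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(qs, function(q) hill_ens(x, q), numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_equal(vals[1], 5)   # q = 0 is richness
})

test_that("diversity profile excludes targets and flags empty samples", {
  des <- toy_design(n_blocks = 2)
  ab <- rbind(c(5, 5, 5, 2), c(10, 1, 1, 0), c(0, 0, 0, 7), c(0, 0, 0, 0))
  dimnames(ab) <- list(des$sample_id, c("s1", "s2", "s3", "tgt"))
  cm <- community_matrix(ab, des, targets = "tgt")
  prof <- diversity_profile(cm)
  expect_equal(prof$S, c(3, 3, 0, 0))
  expect_equal(prof$N, c(15, 12, 0, 0))
  expect_equal(prof$ENS[1], 3)
  expect_true(all(is.na(prof$ENS[3:4])))
  profT <- diversity_profile(cm, exclude_targets = FALSE)
  expect_equal(profT$S, c(4, 3, 1, 0))
})

test_that("Raup-Crick matches exhaustive enumeration on micro-instances", {
  # two identical single-species communities from an equal-frequency pool:
  # hand enumeration gives RC = 2 * (0 + 0.5 * 0.5) - 1 = -0.5
  des <- toy_design(n_blocks = 1)[1:2, ]
  ab <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(des$sample_id, c("spA", "spB")))
  cm <- community_matrix(ab, des)
  u <- raup_crick_uniqueness(cm, method = "exact", freq = c(0.5, 0.5))
  expect_equal(attr(u, "rc")[1, 2], -0.5)

  # richer micro-instance: package enumeration vs the independent recursive
  # oracle over ordered weighted draws
  des4 <- toy_design(n_blocks = 2)
  ab4 <- rbind(c(1, 1, 0, 0, 1), c(0, 1, 1, 0, 0),
               c(1, 0, 1, 1, 0), c(0, 0, 0, 1, 1))
  dimnames(ab4) <- list(des4$sample_id, paste0("s", 1:5))
  cm4 <- community_matrix(ab4, des4)
  u4 <- raup_crick_uniqueness(cm4, method = "exact")
  RC <- attr(u4, "rc")
  X <- 1 * (ab4 > 0); freq <- colMeans(X); k <- rowSums(X)
  O <- tcrossprod(X)
  for (i in 1:3) for (j in (i + 1):4) {
    dist <- oracle_shared_dist(k[i], k[j], freq)
    obs <- O[i, j]
    p_gt <- if (obs + 2 <= length(dist)) sum(dist[(obs + 2):length(dist)]) else 0
    p_eq <- dist[obs + 1]
    expect_equal(RC[i, j], 2 * (p_gt + 0.5 * p_eq) - 1, tolerance = 1e-8)
  }

  # Monte-Carlo agrees with the exact values
  um <- raup_crick_uniqueness(cm4, n_null = 4999, seed = 42)
  expect_equal(attr(um, "rc")[1, 2], RC[1, 2], tolerance = 0.05)
})

test_that("reversing the tail convention flips the Raup-Crick sign", {
  freq <- c(0.4, 0.3, 0.2, 0.1)
  for (kk in list(c(1, 1), c(2, 1), c(2, 2))) {
    dist <- oracle_shared_dist(kk[1], kk[2], freq)
    for (obs in 0:min(kk)) {
      p_gt <- if (obs + 2 <= length(dist)) sum(dist[(obs + 2):length(dist)]) else 0
      p_lt <- if (obs >= 1) sum(dist[1:obs]) else 0
      p_eq <- dist[obs + 1]
      rc_ge <- 2 * (p_gt + 0.5 * p_eq) - 1
      rc_le <- 2 * (p_lt + 0.5 * p_eq) - 1
      expect_equal(rc_ge, -rc_le, tolerance = 1e-12)
    }
  }
})

test_that("uniqueness is bounded, excludes self, and is seed-reproducible", {
  set.seed(8)
  des <- toy_design(n_blocks = 3, plots_per_zone = 2)
  ab <- matrix(rpois(nrow(des) * 10, 2), nrow(des), 10,
               dimnames = list(des$sample_id, paste0("s", 1:10)))
  cm <- community_matrix(ab, des)
  u1 <- raup_crick_uniqueness(cm, n_null = 199, seed = 3)
  u2 <- raup_crick_uniqueness(cm, n_null = 199, seed = 3)
  expect_identical(u1$uniqueness, u2$uniqueness)
  expect_true(all(u1$uniqueness >= -1 & u1$uniqueness <= 1))
  expect_true(all(is.na(diag(attr(u1, "rc")))))
})

test_that("treatment tests use the nested mixed model and flag degeneracy", {
  scn <- gen_scenario(scenario_config(seed = 2))
  prof <- diversity_profile(scn$community)

  # planted positive richness response under suppression
  eff <- treatment_effect(prof, "S")
  expect_equal(eff$family, "poisson")
  expect_gt(eff$z, 1.96)
  expect_match(eff$random, "block/plot")

  effE <- treatment_effect(prof, "ENS")
  expect_equal(effE$family, "gaussian")
  expect_true(is.finite(effE$p) && effE$p >= 0 && effE$p <= 1)

  # constant response: zero estimate with a degeneracy flag
  prof$const <- 3
  effc <- treatment_effect(prof, "const")
  expect_equal(effc$estimate, 0)
  expect_match(effc$flags, "degenerate")
})

test_that("overdispersed counts trigger the observation-level intercept", {
  scn <- gen_scenario(scenario_config(seed = 4))
  prof <- diversity_profile(scn$community)
  eff <- treatment_effect(prof, "N", family = "poisson")
  expect_match(paste(eff$flags, collapse = ";"), "observation-level")
})
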