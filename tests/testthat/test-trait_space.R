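mixed_traits <- function() {
  df <- data.frame(
    species = c("spA", "spB", "spC"),
    weber = c(1.0, 2.0, 3.0),        # continuous, range 2
    spines = c(0, 1, 1),             # binary
    pilosity = c("sparse", "dense", "sparse"),  # categorical
    incidence = c(0.5, 0.3, 0.8))
  attr(df, "trait_types") <- c(weber = "continuous", spines = "binary",
                               pilosity = "categorical")
  df
}

test_that("Gower distance follows the mixed-type definition", {
  tr <- mixed_traits()
  D <- gower_matrix(tr)
  # hand computation: AB = (0.5 + 1 + 1)/3; AC = (1 + 1 + 0)/3; BC = (0.5+0+1)/3
  expect_equal(D["spA", "spB"], (0.5 + 1 + 1) / 3)
  expect_equal(D["spA", "spC"], (1 + 1 + 0) / 3)
  expect_equal(D["spB", "spC"], (0.5 + 0 + 1) / 3)
  expect_equal(diag(D), setNames(rep(0, 3), tr$species))
  expect_true(isSymmetric(unname(D)))

  # identical rows are at distance zero
  tr2 <- tr; tr2[2, 2:4] <- tr2[1, 2:4]
  expect_equal(gower_matrix(tr2)["spA", "spB"], 0)

  # two species differing in 1 of 10 binary traits -> 0.1
  tr10 <- data.frame(species = c("s1", "s2"),
                     matrix(0, 2, 10, dimnames = list(NULL, paste0("b", 1:10))),
                     incidence = c(0.1, 0.2))
  tr10$b10[2] <- 1
  types <- setNames(rep("binary", 10), paste0("b", 1:10))
  D10 <- gower_matrix(tr10, types = types)
  expect_equal(D10["s1", "s2"], 0.1)
})

test_that("Gower matches a brute-force oracle and cluster::daisy", {
  set.seed(42)
  df <- data.frame(species = sprintf("s%02d", 1:7),
                   a = rnorm(7), b = runif(7), c = rbinom(7, 1, 0.5),
                   d = sample(c("x", "y", "z"), 7, TRUE),
                   incidence = runif(7))
  types <- c(a = "continuous", b = "continuous", c = "binary", d = "categorical")
  attr(df, "trait_types") <- types
  D <- gower_matrix(df)
  expect_equal(D, oracle_gower(df, types), tolerance = 1e-10)
  # daisy agrees on the continuous-only subset
  dfc <- df[, c("species", "a", "b", "incidence")]
  attr(dfc, "trait_types") <- types[1:2]
  Dd <- as.matrix(cluster::daisy(df[, c("a", "b")], metric = "gower"))
  expect_equal(unname(gower_matrix(dfc)), unname(Dd), tolerance = 1e-10)
})

test_that("Gower degenerate traits are excluded or rejected", {
  tr <- mixed_traits()
  tr$weber <- 1                       # constant continuous trait
  expect_warning(D <- gower_matrix(tr), "constant trait")
  expect_equal(D["spA", "spB"], 1)    # remaining: spines mismatch + pilosity
  tr$spines <- 0; tr$pilosity <- "sparse"
  expect_error(suppressWarnings(gower_matrix(tr)), "all traits constant")
})

test_that("weighted PCoA reproduces Euclidean geometry", {
  # collinear points: the first axis carries all the variance
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  pc <- trait_pcoa(D)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-10)

  # equilateral triangle: two equal positive eigenvalues
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  Dt <- as.matrix(dist(tri)); dimnames(Dt) <- list(1:3, 1:3)
  pt <- trait_pcoa(Dt)
  pos <- pt$eigvals[pt$eigvals > 1e-10]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # random 6-point Euclidean configuration, incidence-weighted: embedded
  # coordinates reproduce the distances; eigenvalues match brute force
  set.seed(7)
  pts <- matrix(rnorm(18), 6, 3)
  D6 <- as.matrix(dist(pts)); dimnames(D6) <- list(1:6, 1:6)
  w <- runif(6, 0.2, 1)
  pc6 <- trait_pcoa(D6, weights = w)
  expect_false(pc6$corrected)
  expect_equal(as.matrix(dist(pc6$coords)), D6, ignore_attr = TRUE,
               tolerance = 1e-8)
  orc <- oracle_wpcoa(D6, w)
  expect_equal(as.matrix(dist(orc$coords)), D6, ignore_attr = TRUE,
               tolerance = 1e-8)
  # relative axis importance agrees with the brute-force spectrum
  pos_o <- orc$eig[orc$eig > 1e-10]
  expect_equal(unname(pc6$var_explained), pos_o / sum(pos_o), tolerance = 1e-8)
  expect_error(trait_pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("non-Euclidean Gower input triggers the Cailliez correction", {
  tr <- gen_traits(scenario_config(seed = 5))
  D <- gower_matrix(tr)
  pc <- trait_pcoa(D, weights = setNames(tr$incidence, tr$species))
  expect_true(pc$corrected)
  expect_true(all(pc$var_explained >= 0))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_equal(sum(pc$var_explained), 1)
})

test_that("trait-group clustering recovers planted groups and handles edges", {
  rec <- vapply(1:5, function(s) {
    tr <- gen_traits(scenario_config(seed = s, group_separation = 5))
    g <- cluster_trait_groups(gower_matrix(tr), 5)
    tab <- table(g, attr(tr, "groups"))
    sum(apply(tab, 2, max)) / sum(tab)
  }, numeric(1))
  expect_gte(mean(rec), 0.9)

  rec0 <- vapply(1:5, function(s) {
    tr <- gen_traits(scenario_config(seed = s, group_separation = 0))
    g <- cluster_trait_groups(gower_matrix(tr), 5)
    tab <- table(g, attr(tr, "groups"))
    sum(apply(tab, 2, max)) / sum(tab)
  }, numeric(1))
  expect_lt(mean(rec0), 0.6)  # near-chance when no structure is planted

  D <- gower_matrix(mixed_traits())
  expect_equal(unname(cluster_trait_groups(D, 1)), rep(1L, 3))
  expect_equal(unname(cluster_trait_groups(D, 3)), 1:3)
  expect_error(cluster_trait_groups(D, 0), ">= 1")
  expect_error(cluster_trait_groups(D, 4), "exceeds")
})

test_that("dominant selection maximizes incidence with deterministic ties", {
  g <- c(A = 1L, B = 1L, C = 2L)
  expect_equal(unname(select_dominants(g, c(A = 0.9, B = 0.3, C = 0.5))),
               c("A", "C"), ignore_attr = TRUE)
  tied <- select_dominants(g, c(A = 0.5, B = 0.5, C = 0.2))
  expect_equal(unname(tied), c("A", "C"), ignore_attr = TRUE)
  expect_equal(attr(tied, "ties"), "A")
  expect_error(select_dominants(g, c(A = 0.5, B = 0.5)), "incidence missing")

  # planted scenario: the configured targets are the selected dominants of
  # their groups
  cfg <- scenario_config(seed = 13)
  scn <- gen_scenario(cfg)
  ts <- build_trait_space(scn$traits, k_groups = 5)
  doms <- select_dominants(attr(scn$traits, "groups"),
                           setNames(scn$traits$incidence, scn$traits$species))
  expect_true(all(scn$community$targets %in% doms))
})

test_that("FRic is the convex-hull area with documented degenerate cases", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(0.2, 0.2),
                  e = c(3, 0))
  colnames(coords) <- c("A1", "A2")
  expect_equal(fric(c(a = 1, b = 2, c = 1), coords), 0.5)
  # interior point leaves the hull unchanged
  expect_equal(fric(c(a = 1, b = 2, c = 1, d = 5), coords), 0.5)
  # fewer points than axes + 1, or collinear points, give zero
  expect_equal(fric(c(a = 1, b = 1), coords), 0)
  expect_equal(fric(c(a = 1, b = 1, e = 1), coords), 0)
  expect_error(fric(c(a = 1, b = 1, c = 1), coords, n_axes = 3), "n_axes = 2")

  # random point sets match the gift-wrapping oracle
  for (s in 1:5) {
    set.seed(s)
    xy <- matrix(rnorm(16), 8, 2,
                 dimnames = list(paste0("s", 1:8), c("A1", "A2")))
    expect_equal(fric(setNames(rep(1, 8), rownames(xy)), xy),
                 oracle_hull_area(xy), tolerance = 1e-10)
  }
})

test_that("FRic is monotone under species addition", {
  set.seed(31)
  xy <- matrix(rnorm(24), 12, 2,
               dimnames = list(paste0("s", 1:12), c("A1", "A2")))
  for (r in 1:10) {
    ab <- setNames(rbinom(12, 1, 0.5), rownames(xy))
    f0 <- fric(ab, xy)
    absent <- names(ab)[ab == 0]
    if (!length(absent)) next
    ab[sample(absent, 1)] <- 1
    expect_gte(fric(ab, xy) + 1e-12, f0)
  }
})

test_that("FDis is the abundance-weighted mean distance to the centroid", {
  coords <- rbind(a = c(0, 0), b = c(2, 0), c = c(1, 1), d = c(0, 3))
  colnames(coords) <- c("A1", "A2")
  expect_equal(fdis(c(a = 5), coords), 0)
  expect_true(is.na(fdis(c(a = 0, b = 0), coords)))
  # two species, equal abundance, distance 2 -> FDis = 1
  expect_equal(fdis(c(a = 1, b = 1), coords), 1)
  # 4-species weighted hand computation
  ab <- c(a = 2, b = 1, c = 1, d = 4)
  ctr <- colSums(coords * ab) / sum(ab)
  hand <- sum(ab * sqrt(rowSums((coords - matrix(ctr, 4, 2, TRUE))^2))) / sum(ab)
  expect_equal(fdis(ab, coords), hand)
})

test_that("Gower satisfies the triangle inequality on mixed traits", {
  set.seed(9)
  df <- data.frame(species = sprintf("s%d", 1:8),
                   a = rnorm(8), b = rbinom(8, 1, 0.5),
                   d = sample(c("x", "y"), 8, TRUE), incidence = runif(8))
  attr(df, "trait_types") <- c(a = "continuous", b = "binary", d = "categorical")
  D <- gower_matrix(df)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})
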