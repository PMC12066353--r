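std_from_rates <- function(rates_by_fn, n_offered = 100) {
  # build a function-observation table whose rates are exactly as given
  do.call(rbind, lapply(names(rates_by_fn), function(f) {
    r <- rates_by_fn[[f]]
    data.frame(sample_id = paste0("smp", seq_along(r)), function_id = f,
               n_offered = n_offered, n_success = round(r * n_offered),
               assessment_window = NA_real_, stringsAsFactors = FALSE)
  }))
}

test_that("standardization uses the mean of the top 5% of rates", {
  # 10 observations: top-5% set collapses to the single maximum (flagged)
  obs <- std_from_rates(list(scavenging = seq(0.1, 1, by = 0.1)))
  std <- standardize_functions(obs)
  expect_equal(unique(std$F_max), 1.0)
  expect_match(attr(std, "flags"), "fewer than 20")

  # 40 observations: ceil(0.05 * 40) = 2 largest -> (0.9 + 0.8) / 2
  r40 <- c(0.9, 0.8, runif(38, 0.05, 0.7))
  obs40 <- std_from_rates(list(granivory = r40))
  std40 <- standardize_functions(obs40)
  expect_equal(unique(std40$F_max), 0.85)
  # rates above F_max are clipped at 1
  expect_equal(max(std40$F_std), 1)
  expect_true(all(std40$F_std >= 0 & std40$F_std <= 1))

  # an all-zero function is an error naming the function
  bad <- std_from_rates(list(myrmecochory = rep(0, 30)))
  expect_error(standardize_functions(bad), "myrmecochory")
})

test_that("effective multifunctionality obeys its identities", {
  obs <- std_from_rates(lapply(setNames(nm = fns4), function(f) rep(0.5, 25)))
  std <- standardize_functions(obs)
  # F_max = 0.5 everywhere so F_std = 1: even functions give qN = N_f, M = A
  emf <- effective_mf(std)
  expect_equal(emf$qN, rep(4, nrow(emf)))
  expect_equal(emf$M, emf$A)

  # hand-constructed standardized values (1, 0, 0, 0)
  std1 <- data.frame(sample_id = "x", function_id = fns4,
                     rate = c(1, 0, 0, 0), F_max = 1, F_std = c(1, 0, 0, 0))
  class(std1) <- c("std_functions", "data.frame")
  e1 <- effective_mf(std1)
  expect_equal(e1$A, 0.25)
  expect_equal(e1$qN, 1)
  expect_equal(e1$M, 0.25 * (1 / 4))

  # all-zero sample: flagged, M = 0
  std0 <- std1; std0$F_std <- 0; std0$rate <- 0
  e0 <- effective_mf(std0)
  expect_equal(e0$M, 0)
  expect_match(e0$flag, "all-zero")

  # qN is non-increasing in the Hill order q
  stdu <- std1; stdu$F_std <- c(0.9, 0.5, 0.3, 0.1)
  qs <- vapply(c(0, 1, 2, 4), function(q) effective_mf(stdu, q = q)$qN,
               numeric(1))
  expect_true(all(diff(qs) <= 1e-9))
  # M never exceeds the arithmetic mean
  expect_lte(effective_mf(stdu)$M, mean(stdu$F_std))
})

test_that("threshold counts are non-increasing and the sweep is coherent", {
  scn <- gen_scenario(scenario_config(seed = 21))
  std <- standardize_functions(scn$functions)
  prof <- diversity_profile(scn$community)

  # per-sample m_t is non-increasing across the full 5..95 sweep
  w <- merge(prof["sample_id"], as.data.frame(std), by = "sample_id")
  for (sid in unique(w$sample_id)[1:12]) {
    Fv <- w$F_std[w$sample_id == sid]
    m <- vapply(5:95, function(t) sum(Fv >= t / 100), numeric(1))
    expect_true(all(diff(m) <= 0))
  }

  sw <- threshold_sweep(std, prof, thresholds = seq(10, 90, 10), nAGQ = 0L)
  for (arm in c("control", "suppression")) {
    cv <- sw[[arm]]$curve
    expect_equal(nrow(cv), 9)
    expect_true(all(cv$lo <= cv$hi, na.rm = TRUE))
    if (!is.na(sw[[arm]]$T_min)) {
      expect_lte(sw[[arm]]$T_min, sw[[arm]]$T_mde)
      expect_lte(sw[[arm]]$T_mde, sw[[arm]]$T_max)
      # exact reciprocal relation
      expect_equal(sw[[arm]]$species_per_function * sw[[arm]]$R_mde, 1)
    }
  }
})

test_that("the mean-R_mde threshold test detects the planted treatment shift", {
  scn <- gen_scenario(scenario_config(seed = 8))
  std <- standardize_functions(scn$functions)
  prof <- diversity_profile(scn$community)
  sw <- threshold_sweep(std, prof, thresholds = seq(10, 90, 10), nAGQ = 0L)
  mt <- mde_test(std, prof, sw)
  expect_true(is.finite(mt$z))
  expect_equal(mt$t_star, mean(c(sw$control$T_mde, sw$suppression$T_mde)))
  # the same test with an explicit threshold
  mt2 <- mde_test(std, prof, 50)
  expect_equal(mt2$t_star, 50)
})

test_that("function covariance recovers planted signs and handles edge cases", {
  # planted negative granivory-protection noise correlation, estimated at
  # the plot-by-event scale where it acts (performer effects silenced so the
  # between-function noise dominates the rate variance)
  fc <- default_function_cov()
  fc["granivory", "plant_protection"] <- -0.6
  fc["plant_protection", "granivory"] <- -0.6
  signs <- vapply(1:6, function(s) {
    scn <- gen_scenario(scenario_config(seed = 40 + s, fn_noise_sd = 0.8,
                                        function_cov = fc,
                                        performer_effect = named4(0)))
    std <- standardize_functions(scn$functions)
    cv <- function_covariance(std, scn$design, n_perm = 99, seed = s,
                              unit = "plot_event")
    cv$control$cor["granivory", "plant_protection"]
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.9)

  scn <- gen_scenario(scenario_config(seed = 46))
  std <- standardize_functions(scn$functions)
  cv <- function_covariance(std, scn$design, n_perm = 99, seed = 1)
  expect_equal(unname(diag(cv$control$cor)), rep(1, 4))
  expect_true(isSymmetric(cv$control$cor))
  expect_true(all(abs(cv$control$cor) <= 1, na.rm = TRUE))
  expect_equal(cv$control$n_plots, 6)
})
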