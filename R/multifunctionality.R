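#' Standardize function rates against the top-5% maximum
#'
#' Each function's observed rates (`n_success / n_offered`) are standardized
#' by `F_max`, the mean of the top 5% of observed rates for that function
#' across all observations, and clipped at 1. With fewer than 20 observations
#' the top-5% set collapses to the single maximum and is flagged.
#'
#' @param obs function-observation data.frame ([read_function_obs()] /
#'   [gen_function_obs()]).
#' @param top_frac fraction of largest rates averaged into `F_max`.
#' @return data.frame `sample_id, function_id, rate, F_max, F_std`, class
#'   `std_functions`, with per-function flags in attribute `flags`.
#' @export
standardize_functions <- function(obs, top_frac = 0.05) {
  obs$rate <- obs$n_success / obs$n_offered
  flags <- character()
  fmax <- vapply(split(obs$rate, obs$function_id), function(r) {
    m <- ceiling(top_frac * length(r))
    if (length(r) < 20) m <- 1L
    mean(sort(r, decreasing = TRUE)[seq_len(m)])
  }, numeric(1))
  if (any(fmax <= 0))
    stop_mf("standardize_functions: all-zero rates for function(s): ",
            paste(names(fmax)[fmax <= 0], collapse = ", "))
  small <- names(which(table(obs$function_id) < 20))
  if (length(small))
    flags <- c(flags, paste0("fewer than 20 observations (F_max = maximum) for: ",
                             paste(small, collapse = ", ")))
  obs$F_max <- fmax[obs$function_id]
  obs$F_std <- pmin(obs$rate / obs$F_max, 1)
  out <- obs[, c("sample_id", "function_id", "rate", "F_max", "F_std")]
  attr(out, "flags") <- flags
  class(out) <- c("std_functions", "data.frame")
  out
}

# wide per-sample table of standardized function values
std_wide <- function(std) {
  w <- stats::reshape(as.data.frame(std)[, c("sample_id", "function_id", "F_std")],
                      idvar = "sample_id", timevar = "function_id",
                      direction = "wide")
  names(w) <- sub("^F_std\\.", "", names(w))
  w
}

#' Effective multifunctionality
#'
#' For each sample with all functions observed: the arithmetic mean `A` of
#' standardized function values, the Hill number `qN` (order `q`, default 1)
#' of the function-value proportions `p_i = F_i / sum(F)`, and the effective
#' multifunctionality `M_q = A * qN / N_f` — the average performance
#' discounted by how unevenly it is spread across functions. When all
#' functions perform equally, `qN = N_f` and `M_q = A`.
#'
#' @param std a `std_functions` table.
#' @param q Hill order.
#' @return data.frame `sample_id, N_f, A, qN, M` (samples with
#'   `sum(F_std) = 0` get `qN = NA`, `M = 0`, flagged in column `flag`).
#' @export
effective_mf <- function(std, q = 1) {
  w <- std_wide(std)
  fn <- setdiff(names(w), "sample_id")
  Fm <- as.matrix(w[, fn, drop = FALSE])
  if (anyNA(Fm))
    stop_mf("effective_mf: some samples are missing functions")
  A <- rowMeans(Fm)
  tot <- rowSums(Fm)
  qN <- vapply(seq_len(nrow(Fm)), function(i)
    if (tot[i] > 0) hill_ens(Fm[i, ], q = q) else NA_real_, numeric(1))
  M <- ifelse(tot > 0, A * qN / length(fn), 0)
  data.frame(sample_id = w$sample_id, N_f = length(fn), A = A, qN = qN, M = M,
             flag = ifelse(tot > 0, "", "all-zero functions"),
             stringsAsFactors = FALSE)
}

# Poisson mixed fit of a function count on a centred diversity variable;
# returns link-scale slope, response-scale average marginal effect and CI
fit_count_slope <- function(df, overdisp_threshold = 1.5, nAGQ = 1L) {
  if (var(df$m) == 0)
    return(list(beta = 0, se = NA_real_, slope = 0, lo = 0, hi = 0,
                significant = FALSE, degenerate = TRUE, olre = FALSE))
  fit <- tryCatch(suppressWarnings(suppressMessages(
    lme4::glmer(m ~ D + (1 | block) + (1 | block:plot), data = df,
                family = stats::poisson(), nAGQ = nAGQ))),
    error = function(e) NULL)
  olre <- FALSE
  if (!is.null(fit) && overdisp_ratio(fit) > overdisp_threshold) {
    df$.obs <- factor(seq_len(nrow(df)))
    fit2 <- tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(m ~ D + (1 | block) + (1 | block:plot) + (1 | .obs),
                  data = df, family = stats::poisson(), nAGQ = nAGQ))),
      error = function(e) NULL)
    if (!is.null(fit2)) { fit <- fit2; olre <- TRUE }
  }
  if (is.null(fit)) {
    g <- stats::glm(m ~ D + block, data = df, family = stats::poisson())
    cf <- summary(g)$coefficients
    beta <- cf["D", 1]; se <- cf["D", 2]; mu_bar <- mean(fitted(g))
  } else {
    row <- fixef_row(fit, "D")
    beta <- row[["Estimate"]]; se <- row[["Std. Error"]]
    mu_bar <- mean(fitted(fit))
  }
  ci <- beta + c(-1, 1) * 1.96 * se
  list(beta = beta, se = se,
       slope = beta * mu_bar, lo = ci[1] * mu_bar, hi = ci[2] * mu_bar,
       significant = is.finite(se) && (ci[1] > 0 || ci[2] < 0),
       degenerate = FALSE, olre = olre)
}

#' Multiple-thresholds diversity-effect sweep
#'
#' For every threshold `t` (percent of the standardized maximum, default 5 to
#' 95 in steps of 1) the count of functions performing at or above `t` is
#' regressed on diversity (species richness `S` or `ENS`) with a Poisson
#' mixed model (nested block / plot-in-block random intercepts;
#' observation-level intercept added under overdispersion). Slopes are
#' reported on the response scale (average marginal effect, functions per
#' species), so the reciprocal of the realized maximum diversity effect
#' `R_mde` is the number of species needed to add one function. Thresholds
#' whose 95% Wald CI excludes zero are significant; `T_min` / `T_max` bound
#' the significant range and `T_mde` is the threshold of the strongest slope.
#'
#' @param std a `std_functions` table.
#' @param profile a [diversity_profile()] (provides diversity and design).
#' @param thresholds integer percent thresholds.
#' @param diversity `"S"` or `"ENS"`.
#' @param by_treatment sweep each arm separately (default TRUE).
#' @param nAGQ passed to `lme4::glmer` (0 gives a faster approximate fit).
#' @return a `threshold_curve` (or named list of them per arm): list with
#'   `curve` data.frame (`threshold, beta, se, slope, lo, hi, significant,
#'   degenerate`), `T_min`, `T_max`, `T_mde`, `R_mde`,
#'   `species_per_function`, `diversity`.
#' @export
threshold_sweep <- function(std, profile, thresholds = 5:95, diversity = "S",
                            by_treatment = TRUE, nAGQ = 1L) {
  w <- std_wide(std)
  fn <- setdiff(names(w), "sample_id")
  dat <- merge(profile, w, by = "sample_id")
  dat$D <- dat[[diversity]] - mean(dat[[diversity]])
  if (by_treatment) {
    arms <- split(dat, dat$zone)
    out <- lapply(arms, function(a) {
      a$D <- a[[diversity]] - mean(a[[diversity]])
      sweep_one(a, fn, thresholds, diversity, nAGQ)
    })
    return(out)
  }
  sweep_one(dat, fn, thresholds, diversity, nAGQ)
}

sweep_one <- function(dat, fn, thresholds, diversity, nAGQ) {
  Fm <- as.matrix(dat[, fn, drop = FALSE])
  rows <- lapply(thresholds, function(t) {
    df <- data.frame(m = rowSums(Fm >= t / 100), D = dat$D,
                     block = factor(dat$block), plot = factor(dat$plot))
    r <- fit_count_slope(df, nAGQ = nAGQ)
    data.frame(threshold = t, beta = r$beta, se = r$se, slope = r$slope,
               lo = r$lo, hi = r$hi, significant = r$significant,
               degenerate = r$degenerate, olre = r$olre)
  })
  curve <- do.call(rbind, rows)
  sig <- curve$threshold[curve$significant]
  if (length(sig)) {
    T_min <- min(sig); T_max <- max(sig)
    imax <- which.max(ifelse(curve$significant, abs(curve$slope), -Inf))
    T_mde <- curve$threshold[imax]
    R_mde <- curve$slope[imax]
  } else T_min <- T_max <- T_mde <- R_mde <- NA_real_
  structure(list(curve = curve, T_min = T_min, T_max = T_max, T_mde = T_mde,
                 R_mde = R_mde,
                 species_per_function = species_per_function(R_mde),
                 diversity = diversity),
            class = "threshold_curve")
}

#' Species needed per additional function
#'
#' Reciprocal of the realized maximum diversity effect: a response-scale
#' slope of `R_mde` functions gained per species corresponds to
#' `1 / R_mde` species required to add one function above the threshold.
#'
#' @param r_mde realized maximum diversity effect (functions per species).
#' @return species per function.
#' @export
species_per_function <- function(r_mde) {
  if (is.na(r_mde) || r_mde == 0) return(NA_real_)
  1 / r_mde
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "Threshold sweep (%s): T_min = %s, T_max = %s, R_mde = %s at T = %s; %s species/function\n",
    x$diversity, x$T_min, x$T_max,
    ifelse(is.na(x$R_mde), NA, signif(x$R_mde, 3)), x$T_mde,
    ifelse(is.na(x$species_per_function), NA, signif(x$species_per_function, 3))))
  invisible(x)
}

#' Treatment test at the mean R_mde threshold
#'
#' The multiple-thresholds sweep yields a curve, not a single test; the
#' suppression effect is therefore tested once, on the number of functions
#' performed at the threshold equal to the mean of the two arms' `T_mde`
#' values, with a Poisson mixed model.
#'
#' @param std a `std_functions` table.
#' @param profile a [diversity_profile()].
#' @param curves named list of per-arm `threshold_curve`s from
#'   [threshold_sweep()] (or a numeric threshold `t_star` directly).
#' @return an `effect_result` (see [treatment_effect()]) with the threshold
#'   used in `$t_star`.
#' @export
mde_test <- function(std, profile, curves) {
  t_star <- if (is.numeric(curves)) curves else {
    tm <- vapply(curves, function(x) x$T_mde, numeric(1))
    if (anyNA(tm)) stop_mf("mde_test: T_mde undefined in at least one arm")
    mean(tm)
  }
  w <- std_wide(std)
  fn <- setdiff(names(w), "sample_id")
  dat <- merge(profile, w, by = "sample_id")
  dat$m <- rowSums(as.matrix(dat[, fn, drop = FALSE]) >= t_star / 100)
  res <- treatment_effect(dat, "m", family = "poisson")
  res$t_star <- t_star
  res
}

#' Between-function covariance at plot level
#'
#' Pairwise Pearson correlations of plot-level mean standardized function
#' values, per treatment arm, with permutation p-values (one function's plot
#' vector permuted `n_perm` times, seeded).
#'
#' @param std a `std_functions` table.
#' @param design design table (provides `zone`, `plot`, `event` per sample).
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed.
#' @param by_treatment compute per arm (default TRUE).
#' @param unit aggregation unit: `"plot"` (default) or `"plot_event"` (each
#'   plot's pooled rates per sampling event; more units, useful for
#'   sign-recovery checks).
#' @return per arm (or overall), a list with `cor`, `p` (matrices) and
#'   `n_plots`; zero-variance functions give `NA` rows flagged by attribute.
#' @export
function_covariance <- function(std, design, n_perm = 999, seed = NULL,
                                by_treatment = TRUE,
                                unit = c("plot", "plot_event")) {
  unit <- match.arg(unit)
  dat <- merge(as.data.frame(std),
               design[, c("sample_id", "zone", "plot", "event")],
               by = "sample_id")
  if (unit == "plot_event") dat$plot <- paste(dat$plot, dat$event, sep = ".")
  one_arm <- function(d) {
    ag <- aggregate(F_std ~ plot + function_id, data = d, FUN = mean)
    w <- stats::reshape(ag, idvar = "plot", timevar = "function_id",
                        direction = "wide")
    M <- as.matrix(w[, -1, drop = FALSE])
    colnames(M) <- sub("^F_std\\.", "", colnames(M))
    if (nrow(M) < 3) stop_mf("function_covariance: need at least 3 plots")
    nf <- ncol(M)
    C <- diag(nf); P <- diag(0, nf)
    dimnames(C) <- dimnames(P) <- list(colnames(M), colnames(M))
    zv <- apply(M, 2, function(x) var(x) == 0)
    with_seed(seed, {
      for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
        if (zv[i] || zv[j]) { C[i, j] <- C[j, i] <- P[i, j] <- P[j, i] <- NA; next }
        r <- cor(M[, i], M[, j])
        rp <- replicate(n_perm, cor(M[, i], sample(M[, j])))
        p <- (sum(abs(rp) >= abs(r)) + 1) / (n_perm + 1)
        C[i, j] <- C[j, i] <- r
        P[i, j] <- P[j, i] <- p
      }
    })
    diag(P) <- NA
    list(cor = C, p = P, n_plots = nrow(M), zero_variance = names(zv)[zv])
  }
  if (by_treatment) lapply(split(dat, dat$zone), one_arm) else one_arm(dat)
}
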