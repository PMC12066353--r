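#' Hill-number effective number of species
#'
#' `ENS = exp(-sum p ln p)` at order `q = 1` (the exponential of Shannon
#' entropy) and `(sum p^q)^(1/(1-q))` otherwise, with `p` the relative
#' abundances of species with positive counts.
#'
#' @param x non-negative abundance vector.
#' @param q diversity order (default 1).
#' @return effective number of species; `NA` for an empty community.
#' @export
hill_ens <- function(x, q = 1) {
  x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  p <- x / sum(x)
  if (abs(q - 1) < 1e-9) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Per-sample diversity profile
#'
#' Species richness `S` (count of species with positive abundance), total
#' abundance `N` and effective number of species `ENS` for every sample, by
#' default after removal of the suppressed target species.
#'
#' @param comm a [community_matrix()].
#' @param exclude_targets drop target species first (default TRUE).
#' @param q Hill order for ENS.
#' @return data.frame of design columns plus `S`, `N`, `ENS` (ENS is `NA`,
#'   flagged, for empty samples).
#' @export
diversity_profile <- function(comm, exclude_targets = TRUE, q = 1) {
  abund <- comm$abund
  if (exclude_targets && length(comm$targets))
    abund <- abund[, setdiff(colnames(abund), comm$targets), drop = FALSE]
  out <- data.frame(sample_id = rownames(abund),
                    S = rowSums(abund > 0),
                    N = rowSums(abund),
                    ENS = apply(abund, 1, hill_ens, q = q),
                    stringsAsFactors = FALSE)
  merge(comm$design, out, by = "sample_id", sort = FALSE)
}

# weighted sampling without replacement: probability of drawing exactly the
# set `set` (indices) given weights w, via enumeration of draw orders
.set_prob <- function(set, w) {
  w <- w / sum(w)
  k <- length(set)
  if (k == 0) return(1)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  total <- 0
  for (ord in perms(set)) {
    rem <- 1
    pr <- 1
    for (j in ord) {
      pr <- pr * w[j] / rem
      rem <- rem - w[j]
    }
    total <- total + pr
  }
  total
}

# exact null distribution of the shared-species count between two null
# communities of richness k1 and k2 drawn from `n_sp` species with weights w
.shared_null_exact <- function(k1, k2, w) {
  n_sp <- length(w)
  sets1 <- combn(n_sp, k1, simplify = FALSE)
  sets2 <- if (k2 == k1) sets1 else combn(n_sp, k2, simplify = FALSE)
  p1 <- vapply(sets1, .set_prob, numeric(1), w = w)
  p2 <- if (k2 == k1) p1 else vapply(sets2, .set_prob, numeric(1), w = w)
  dist <- numeric(min(k1, k2) + 1)
  for (i in seq_along(sets1)) for (j in seq_along(sets2)) {
    sh <- length(intersect(sets1[[i]], sets2[[j]]))
    dist[sh + 1] <- dist[sh + 1] + p1[i] * p2[j]
  }
  dist  # P(shared = 0..min(k1,k2))
}

rc_from_tail <- function(p_gt, p_eq) 2 * (p_gt + 0.5 * p_eq) - 1

#' Raup-Crick compositional uniqueness
#'
#' For every pair of samples, null communities are drawn preserving each
#' sample's observed richness, with species sampled (without replacement)
#' proportionally to their occurrence frequency across samples. The pairwise
#' Raup-Crick score is
#' `RC = 2 * (P(null shared >= observed shared), ties counted half) - 1`,
#' so +1 means the pair shares fewer species than the null expects (the
#' communities are unusual, "unique") and -1 more. A sample's uniqueness is
#' the mean RC over all its partners (itself excluded).
#'
#' `method = "exact"` enumerates the full null distribution (small pools
#' only); `"sample"` uses `n_null` Monte-Carlo draws.
#'
#' @param comm a [community_matrix()].
#' @param n_null number of null draws (default 999).
#' @param seed RNG seed for the null draws.
#' @param method `"sample"` or `"exact"`.
#' @param exclude_targets drop targets before computing occurrences.
#' @param freq optional species occurrence probabilities for the null pool;
#'   defaults to the observed occurrence frequencies across samples.
#' @return data.frame `sample_id, uniqueness` (design columns merged), with
#'   the pairwise RC matrix as attribute `rc`.
#' @export
raup_crick_uniqueness <- function(comm, n_null = 999, seed = NULL,
                                  method = c("sample", "exact"),
                                  exclude_targets = TRUE, freq = NULL) {
  method <- match.arg(method)
  abund <- comm$abund
  if (exclude_targets && length(comm$targets))
    abund <- abund[, setdiff(colnames(abund), comm$targets), drop = FALSE]
  X <- 1 * (abund > 0)
  n <- nrow(X); n_sp <- ncol(X)
  if (n < 2) stop_mf("raup_crick_uniqueness: need at least 2 samples")
  freq <- freq %||% colMeans(X)
  if (length(freq) != n_sp)
    stop_mf("raup_crick_uniqueness: freq must have one entry per species")
  if (all(freq == 0)) stop_mf("raup_crick_uniqueness: all samples empty")
  freq <- pmax(freq, 1e-12)
  k <- rowSums(X)
  O <- tcrossprod(X)  # observed shared-species counts

  if (method == "exact") {
    if (n_sp > 8 || max(k) > 4)
      stop_mf("raup_crick_uniqueness: exact enumeration limited to <=8 species, richness <=4")
    RC <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dist <- .shared_null_exact(k[i], k[j], freq)
      obs <- O[i, j]
      p_gt <- if (obs + 2 <= length(dist)) sum(dist[(obs + 2):length(dist)]) else 0
      p_eq <- if (obs + 1 <= length(dist)) dist[obs + 1] else 0
      RC[i, j] <- RC[j, i] <- rc_from_tail(p_gt, p_eq)
    }
  } else {
    if (n_null < 99) stop_mf("raup_crick_uniqueness: n_null must be >= 99")
    gt <- matrix(0L, n, n); eq <- matrix(0L, n, n)
    with_seed(seed, {
      for (r in seq_len(n_null)) {
        Nmat <- matrix(0L, n, n_sp)
        for (i in seq_len(n)) {
          if (k[i] > 0)
            Nmat[i, sample.int(n_sp, k[i], prob = freq)] <- 1L
        }
        Sh <- tcrossprod(Nmat)
        gt <- gt + (Sh > O)
        eq <- eq + (Sh == O)
      }
    })
    RC <- rc_from_tail(gt / n_null, eq / n_null)
    dimnames(RC) <- list(rownames(X), rownames(X))
  }
  diag(RC) <- NA
  uni <- rowMeans(RC, na.rm = TRUE)
  out <- merge(comm$design,
               data.frame(sample_id = rownames(X), uniqueness = uni,
                          stringsAsFactors = FALSE),
               by = "sample_id", sort = FALSE)
  attr(out, "rc") <- RC
  out
}

# Pearson chi-square overdispersion ratio of a fitted (g)lmer Poisson model
overdisp_ratio <- function(fit) {
  rdf <- nrow(stats::model.frame(fit)) - length(lme4::fixef(fit)) -
    length(unlist(lme4::getME(fit, "theta")))
  sum(residuals(fit, type = "pearson")^2) / max(rdf, 1)
}

fixef_row <- function(fit, term) {
  cf <- summary(fit)$coefficients
  hit <- grep(term, rownames(cf), fixed = TRUE)
  if (!length(hit)) return(NULL)
  cf[hit[1], , drop = TRUE]
}

#' Mixed-model treatment effect on a community or function response
#'
#' Fits `response ~ zone` with nested random intercepts for block and plot
#' within block, matching the split-plot design. Counts get a Poisson GLMM
#' with an observation-level random intercept added when the Pearson
#' chi-square / df ratio exceeds 1.5; continuous responses get a Gaussian
#' LMM. Wald Z and two-sided p are reported. If the mixed fit fails, a
#' fixed-block GLM fallback is used and flagged.
#'
#' @param data data.frame containing the response plus `zone`, `block`,
#'   `plot` columns (e.g. a [diversity_profile()]).
#' @param response name of the response column.
#' @param family `"auto"` (integer-valued -> Poisson), `"poisson"` or
#'   `"gaussian"`.
#' @param overdisp_threshold Pearson ratio above which the observation-level
#'   random intercept is added.
#' @return object of class `effect_result`: list with `response`, `estimate`
#'   (suppression minus control), `se`, `z`, `p`, `family`, `random`,
#'   `flags`, `fit`.
#' @export
treatment_effect <- function(data, response,
                             family = c("auto", "poisson", "gaussian"),
                             overdisp_threshold = 1.5) {
  family <- match.arg(family)
  y <- data[[response]]
  if (is.null(y)) stop_mf("treatment_effect: no column '", response, "'")
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(data$block)) < 2)
    stop_mf("treatment_effect: need at least 2 blocks")
  if (family == "auto")
    family <- if (all(y >= 0 & abs(y - round(y)) < 1e-9)) "poisson" else "gaussian"
  data$zone <- factor(data$zone, levels = .mf_zones)
  data$block <- factor(data$block); data$plot <- factor(data$plot)
  flags <- character()

  if (var(y) == 0) {
    return(structure(list(response = response, estimate = 0, se = NA_real_,
                          z = 0, p = 1, family = family,
                          random = "(1|block/plot)",
                          flags = "degenerate: constant response", fit = NULL),
                     class = "effect_result"))
  }

  fml <- stats::as.formula(paste(response, "~ zone + (1 | block) + (1 | block:plot)"))
  fit <- NULL
  random <- "(1|block/plot)"
  if (family == "poisson") {
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = data, family = stats::poisson()))),
      error = function(e) NULL)
    if (!is.null(fit) && overdisp_ratio(fit) > overdisp_threshold) {
      data$.obs <- factor(seq_len(nrow(data)))
      fml2 <- stats::update(fml, . ~ . + (1 | .obs))
      fit2 <- tryCatch(suppressWarnings(suppressMessages(
        lme4::glmer(fml2, data = data, family = stats::poisson()))),
        error = function(e) NULL)
      if (!is.null(fit2)) {
        fit <- fit2
        random <- "(1|block/plot) + (1|obs)"
        flags <- c(flags, "overdispersed: observation-level random intercept added")
      }
    }
  } else {
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = data, REML = TRUE))),
      error = function(e) NULL)
  }

  if (!is.null(fit)) {
    row <- fixef_row(fit, "zonesuppression")
    est <- row[["Estimate"]]; se <- row[["Std. Error"]]
  } else {
    # fallback: fixed block effects, simple GLM; flagged
    flags <- c(flags, "fallback: mixed model failed, fixed-block GLM used")
    random <- "block fixed (fallback)"
    gfam <- if (family == "poisson") stats::poisson() else stats::gaussian()
    fit <- stats::glm(stats::as.formula(paste(response, "~ zone + block")),
                      data = data, family = gfam)
    cf <- summary(fit)$coefficients
    est <- cf["zonesuppression", 1]; se <- cf["zonesuppression", 2]
  }
  z <- est / se
  structure(list(response = response, estimate = est, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), family = family, random = random,
                 flags = flags, fit = fit),
            class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("%s ~ suppression (%s, %s): estimate = %.4g, Z = %.2f, P = %.3g\n",
              x$response, x$family, x$random, x$estimate, x$z, x$p))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
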