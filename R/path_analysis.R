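#' Piecewise multilevel path analysis of suppression effects
#'
#' Decomposes the effect of dominant-species suppression on a function (or on
#' effective multifunctionality) into a direct path and a path mediated by
#' diversity, with two component mixed models sharing the split-plot random
#' structure (block, plot-in-block):
#' \enumerate{
#'   \item `mediator ~ treatment` (Poisson for richness counts, Gaussian for
#'     ENS or other continuous mediators);
#'   \item `response ~ treatment + mediator` (+ `treatment:mediator` when
#'     `with_interaction`), Gaussian, binomial (`cbind(n_success,
#'     n_offered - n_success)`) or Poisson.
#' }
#' The mediator is centred, so the treatment coefficient of model 2 is the
#' direct effect with the mediator held at its mean. Standardized
#' coefficients use `beta = b * sd(x) / sd(y)`; for non-Gaussian responses
#' `sd(y)` is taken on the latent scale (variance of the linear predictor
#' plus the distribution-specific variance: `pi^2/3` for logit-binomial,
#' `log(1 + 1/lambda_bar)` for log-Poisson). The indirect effect is the
#' product of the standardized treatment-to-mediator and
#' mediator-to-response coefficients.
#'
#' @param data per-sample data.frame with `zone`, `block`, `plot`, the
#'   mediator column, and either a numeric response column or binomial count
#'   columns `n_success`, `n_offered`.
#' @param mediator name of the mediator column (`"S"` or `"ENS"`).
#' @param response name of the response column, or `"binomial"` to use the
#'   count pair.
#' @param response_family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param mediator_family `"poisson"` (richness) or `"gaussian"`.
#' @param with_interaction include a treatment-by-mediator interaction in the
#'   response model.
#' @return object of class `path_model`: `edges` data.frame (`from, to, b,
#'   se, z, p, beta`), `direct`, `indirect`, `total`, component `models`,
#'   `flags`.
#' @export
fit_paths <- function(data, mediator = "S", response,
                      response_family = c("gaussian", "binomial", "poisson"),
                      mediator_family = c("poisson", "gaussian"),
                      with_interaction = FALSE) {
  response_family <- match.arg(response_family)
  mediator_family <- match.arg(mediator_family)
  d <- data
  d$zone <- factor(d$zone, levels = .mf_zones)
  d$block <- factor(d$block); d$plot <- factor(d$plot)
  d$treat <- as.numeric(d$zone == "suppression")
  d$med <- d[[mediator]]
  d$med_c <- d$med - mean(d$med)
  flags <- character()

  # component 1: mediator ~ treatment
  if (mediator_family == "poisson") {
    m1 <- tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(med ~ treat + (1 | block) + (1 | block:plot), data = d,
                  family = stats::poisson()))), error = function(e) NULL)
  } else {
    m1 <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(med ~ treat + (1 | block) + (1 | block:plot), data = d))),
      error = function(e) NULL)
  }
  if (is.null(m1)) {
    flags <- c(flags, "mediator model: mixed fit failed, fixed-block fallback")
    fam <- if (mediator_family == "poisson") stats::poisson() else stats::gaussian()
    m1 <- stats::glm(med ~ treat + block, data = d, family = fam)
  }

  # component 2: response ~ treatment + mediator (+ interaction)
  fe <- if (with_interaction) "treat * med_c" else "treat + med_c"
  re <- "(1 | block) + (1 | block:plot)"
  # repeated assays within a plot and sampling round share conditions; give
  # them a random intercept when residuals are overdispersed
  d$.round <- if ("event" %in% names(d)) factor(paste(d$plot, d$event))
              else factor(seq_len(nrow(d)))
  fit_glmm <- function(rhs, fam) {
    fml <- stats::as.formula(paste(
      if (response_family == "binomial") "resp" else response, "~", rhs))
    tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = d, family = fam))), error = function(e) NULL)
  }
  if (response_family == "binomial") {
    d$resp <- cbind(d$n_success, d$n_offered - d$n_success)
    m2 <- fit_glmm(paste(fe, "+", re), stats::binomial())
  } else if (response_family == "poisson") {
    m2 <- fit_glmm(paste(fe, "+", re), stats::poisson())
  } else {
    fml <- stats::as.formula(paste(response, "~", fe, "+", re))
    m2 <- tryCatch(suppressWarnings(suppressMessages(lme4::lmer(fml, data = d))),
                   error = function(e) NULL)
  }
  if (response_family != "gaussian" && !is.null(m2) &&
      overdisp_ratio(m2) > 1.5) {
    m2b <- fit_glmm(paste(fe, "+", re, "+ (1 | .round)"),
                    if (response_family == "binomial") stats::binomial()
                    else stats::poisson())
    if (!is.null(m2b)) {
      m2 <- m2b
      flags <- c(flags, "response model: sampling-round random intercept added (overdispersion)")
    }
  }
  if (is.null(m2)) stop_mf("fit_paths: response model failed to converge")

  b1 <- standardize_coefficients(m1, data = d)
  b2 <- standardize_coefficients(m2, data = d)
  edge <- function(fit, std, term, from, to) {
    row <- fixef_row(fit, term)
    if (is.null(row)) return(NULL)
    z <- row[["Estimate"]] / row[["Std. Error"]]
    data.frame(from = from, to = to, b = row[["Estimate"]],
               se = row[["Std. Error"]], z = z, p = 2 * pnorm(-abs(z)),
               beta = unname(std[term]), stringsAsFactors = FALSE)
  }
  resp_name <- if (response_family == "binomial") "rate" else response
  edges <- rbind(edge(m1, b1, "treat", "treatment", mediator),
                 edge(m2, b2, "treat", "treatment", resp_name),
                 edge(m2, b2, "med_c", mediator, resp_name),
                 if (with_interaction)
                   edge(m2, b2, "treat:med_c", paste0("treatment:", mediator),
                        resp_name))
  direct <- edges$beta[edges$from == "treatment" & edges$to == resp_name]
  a_path <- edges$beta[edges$from == "treatment" & edges$to == mediator]
  b_path <- edges$beta[edges$from == mediator]
  indirect <- a_path * b_path
  structure(list(edges = edges, direct = direct, indirect = indirect,
                 total = direct + indirect,
                 models = list(mediator = m1, response = m2),
                 mediator = mediator, response = resp_name, flags = flags),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Path model: treatment -> %s -> %s\n", x$mediator, x$response))
  print(within(x$edges, { b <- signif(b, 3); se <- signif(se, 3)
                          z <- round(z, 2); p <- signif(p, 3)
                          beta <- signif(beta, 3) }), row.names = FALSE)
  cat(sprintf("direct (std) = %.3f, indirect = %.3f, total = %.3f\n",
              x$direct, x$indirect, x$total))
  invisible(x)
}

#' Standardized partial regression coefficients
#'
#' `beta = b * sd(x) / sd(y)`. For Gaussian fits `sd(y)` is the observed
#' response sd; for binomial and Poisson mixed fits it is the latent-scale sd
#' (variance of the fitted linear predictor plus the distribution-specific
#' variance, logit: `pi^2/3`; log: `log(1 + 1/lambda_bar)`). Predictor sds
#' are taken from the model frame, including the sd of a 0/1 treatment
#' indicator. Zero-variance predictors yield `NA`.
#'
#' @param fit an `lm`, `glm`, `lmerMod` or `glmerMod` fit.
#' @param data optional data.frame to take predictor sds from (defaults to
#'   the model frame).
#' @return named numeric vector of standardized coefficients (intercept
#'   excluded).
#' @export
standardize_coefficients <- function(fit, data = NULL) {
  is_mer <- inherits(fit, "merMod")
  b <- if (is_mer) lme4::fixef(fit) else coef(fit)
  mf <- data %||% stats::model.frame(fit)
  fam <- tryCatch(stats::family(fit)$family, error = function(e) "gaussian")
  link <- tryCatch(stats::family(fit)$link, error = function(e) "identity")
  eta <- if (is_mer) as.numeric(lme4::getME(fit, "X") %*% b)
         else as.numeric(stats::model.matrix(fit) %*% b)
  sd_y <- if (fam == "binomial" && link == "logit") {
    sqrt(var(eta) + pi^2 / 3)
  } else if (fam == "poisson" && link == "log") {
    sqrt(var(eta) + log(1 + 1 / exp(mean(eta))))
  } else {
    y <- stats::model.response(stats::model.frame(fit))
    sd(as.numeric(y))
  }
  terms <- setdiff(names(b), "(Intercept)")
  X <- if (is_mer) lme4::getME(fit, "X") else stats::model.matrix(fit)
  out <- vapply(terms, function(tm) {
    x <- X[, tm]
    sx <- sd(x)
    if (sx == 0) return(NA_real_)
    b[[tm]] * sx / sd_y
  }, numeric(1))
  out
}
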