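#' Null-model species-function association (standardized effect sizes)
#'
#' For one treatment arm: species abundances and standardized function values
#' are aggregated to the plot-by-sampling-event level (or plot level with
#' `unit = "plot"`); for every species-function pair the observed
#' least-squares slope of rate on abundance across units is compared with a
#' null distribution obtained by permuting the unit-level rate vector
#' (abundances fixed, following the assumption that abundance drives
#' function, not the reverse) `n_rand` times. The standardized effect size is
#' `SES = (observed - null mean) / null sd`; `|SES| > 1.96` flags a
#' significant association.
#'
#' @param comm a [community_matrix()].
#' @param std a `std_functions` table ([standardize_functions()]).
#' @param arm `"control"` or `"suppression"`.
#' @param n_rand number of randomizations (default 999).
#' @param seed RNG seed (same seed, same table).
#' @param exclude_targets drop target species.
#' @param unit aggregation/permutation unit: `"plot_event"` (default; each
#'   plot's pooled counts and rates per sampling event) or `"plot"` (pooled
#'   over all events).
#' @return data.frame `species, function_id, arm, slope, null_mean, null_sd,
#'   ses, significant, flag`, class `ses_table`. Species absent from the arm
#'   or degenerate (constant-rate) cells get `NA` SES with a flag.
#' @export
ses_null <- function(comm, std, arm, n_rand = 999, seed = NULL,
                     exclude_targets = TRUE, unit = c("plot_event", "plot")) {
  stopifnot(arm %in% .mf_zones)
  unit <- match.arg(unit)
  design <- comm$design
  ids <- design$sample_id[design$zone == arm]
  abund <- comm$abund[ids, , drop = FALSE]
  if (exclude_targets && length(comm$targets))
    abund <- abund[, setdiff(colnames(abund), comm$targets), drop = FALSE]
  di <- design[match(ids, design$sample_id), , drop = FALSE]
  unit_of <- if (unit == "plot") di$plot else paste(di$plot, di$event, sep = ".")
  if (length(unique(di$plot)) < 5) stop_mf("ses_null: need at least 5 plots per arm")
  plots <- sort(unique(unit_of))
  # unit-level species abundance
  A <- rowsum(abund, unit_of)[plots, , drop = FALSE]
  # unit-level mean standardized rate per function
  sd_arm <- merge(as.data.frame(std),
                  design[, c("sample_id", "plot", "event", "zone")],
                  by = "sample_id")
  sd_arm <- sd_arm[sd_arm$zone == arm, , drop = FALSE]
  sd_arm$plot <- if (unit == "plot") sd_arm$plot else
    paste(sd_arm$plot, sd_arm$event, sep = ".")
  R <- aggregate(F_std ~ plot + function_id, data = sd_arm, FUN = mean)

  np <- length(plots)
  out <- list()
  with_seed(seed, {
    for (f in sort(unique(R$function_id))) {
      y <- R$F_std[R$function_id == f][match(plots, R$plot[R$function_id == f])]
      Yp <- vapply(seq_len(n_rand), function(r) y[sample.int(np)],
                   numeric(np))
      for (sp in colnames(A)) {
        x <- A[, sp]
        flag <- ""
        if (all(x == 0)) {
          slope <- nm <- ns <- ses <- NA_real_
          flag <- "species absent in arm"
        } else if (var(x) == 0 || var(y) == 0) {
          slope <- if (var(x) > 0) 0 else NA_real_
          nm <- ns <- ses <- NA_real_
          flag <- "degenerate: zero variance"
        } else {
          xc <- x - mean(x)
          sxx <- sum(xc^2)
          slope <- sum(xc * y) / sxx
          b_null <- as.numeric(crossprod(xc, Yp)) / sxx
          nm <- mean(b_null); ns <- sd(b_null)
          ses <- if (ns > 1e-12) (slope - nm) / ns else NA_real_
          if (is.na(ses)) flag <- "degenerate: null sd ~ 0"
        }
        out[[length(out) + 1]] <- data.frame(
          species = sp, function_id = f, arm = arm, slope = slope,
          null_mean = nm, null_sd = ns, ses = ses,
          significant = !is.na(ses) & abs(ses) > 1.96, flag = flag,
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ses_table", "data.frame")
  res
}

#' Treatment shift in species-function association
#'
#' Subtracts control-arm standardized effect sizes from suppression-arm
#' values (`delta = SES_suppression - SES_control`) for matching
#' species-function cells and ranks the deltas from smallest to largest
#' within each function (ties broken by species id). Unmatched cells are
#' dropped and reported via the `dropped` attribute.
#'
#' @param ses_control,ses_suppression `ses_table`s from [ses_null()].
#' @return data.frame `species, function_id, ses_control, ses_suppression,
#'   delta, delta_rank`.
#' @export
delta_and_rank <- function(ses_control, ses_suppression) {
  a <- as.data.frame(ses_control)[, c("species", "function_id", "ses")]
  b <- as.data.frame(ses_suppression)[, c("species", "function_id", "ses")]
  names(a)[3] <- "ses_control"; names(b)[3] <- "ses_suppression"
  if (!length(intersect(a$species, b$species)))
    stop_mf("delta_and_rank: disjoint species sets")
  m <- merge(a, b, by = c("species", "function_id"))
  dropped <- setdiff(union(paste(a$species, a$function_id),
                           paste(b$species, b$function_id)),
                     paste(m$species, m$function_id))
  m$delta <- m$ses_suppression - m$ses_control
  m <- m[order(m$function_id, m$delta, m$species), ]
  m$delta_rank <- stats::ave(seq_len(nrow(m)), m$function_id, FUN = seq_along)
  rownames(m) <- NULL
  attr(m, "dropped") <- dropped
  m
}

#' Rank correlation between functional importance and treatment response
#'
#' Spearman's rho between each species' control-arm standardized effect size
#' (its functional importance in the intact community) and its delta
#' treatment shift, per function. A negative rho means the species most
#' important in the presence of dominants responded least (or most
#' negatively) to their suppression.
#'
#' @param delta_table output of [delta_and_rank()].
#' @param min_n minimum complete pairs required (default 5; fewer is flagged
#'   and yields `NA`).
#' @return data.frame `function_id, rho, p_value, n, flag`.
#' @export
importance_response_correlation <- function(delta_table, min_n = 5) {
  out <- lapply(split(delta_table, delta_table$function_id), function(d) {
    d <- d[stats::complete.cases(d[, c("ses_control", "delta")]), ]
    if (nrow(d) < min_n)
      return(data.frame(function_id = d$function_id[1] %||% NA, rho = NA_real_,
                        p_value = NA_real_, n = nrow(d), flag = "low-n"))
    ct <- suppressWarnings(cor.test(d$ses_control, d$delta, method = "spearman"))
    data.frame(function_id = d$function_id[1], rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d), flag = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
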