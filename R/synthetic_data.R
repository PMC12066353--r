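#' Scenario configuration for the synthetic suppression experiment
#'
#' Builds the parameter set from which a complete synthetic experiment is
#' generated. Defaults emulate the field layout of the suppression study: 3
#' spatial blocks, each split into one control and one suppression zone with 2
#' focal plots per zone, 4 plot quarters sampled over 4 events; a pool of 34
#' species structured into 5 trait groups with 3 dominant "target" species
#' whose abundance is multiplied by `target_suppression` (defaults 0.06, 0.04,
#' 0.01, i.e. 94/96/99 percent reductions) in suppression zones. Ground
#' functions are assayed with 40 baits per sampled plot quarter (80 per plot)
#' and plant protection with 16 (32 per plot), in 2 of the 4 quarters.
#'
#' Function performance is binomial with
#' `logit p = alpha_f + beta_S (S - richness_center) + beta_T T +
#'  gamma_f (log1p(a_perf) - log1p(lambda_perf)) + block effect + plot noise`,
#' where `S` is non-target richness of the sample, `T` the suppression
#' indicator, `a_perf` the abundance of the function's planted performer
#' species and the plot-by-event noise is multivariate normal across the four
#' functions with correlation `function_cov`.
#'
#' @param n_blocks number of spatial blocks.
#' @param plots_per_zone focal plots per block-zone unit.
#' @param n_quarters plot quarters per plot.
#' @param n_events sampling events.
#' @param fn_quarters number of quarters in which functions are assayed.
#' @param n_species species-pool size.
#' @param n_trait_groups number of planted trait groups.
#' @param n_targets number of suppressed dominants (one per first groups).
#' @param group_separation distance between trait-group means, in
#'   within-group standard-deviation units; 0 removes all group structure.
#' @param target_suppression multiplicative abundance retained by each target
#'   under suppression (in \[0, 1\]).
#' @param nontarget_release multiplicative abundance increase of non-targets
#'   under suppression.
#' @param n_colonists number of initially rare species that immigrate under
#'   suppression; their mean abundance is multiplied by `colonist_boost`.
#' @param colonist_boost see `n_colonists`.
#' @param nb_size negative-binomial size (dispersion) of pitfall counts;
#'   `Inf` gives Poisson counts.
#' @param abund_meanlog,abund_sdlog log-normal baseline species mean
#'   abundances per pitfall sample.
#' @param dominant_boost multiplier applied to group dominants' baseline mean.
#' @param block_sd,plot_sd,event_sd log-scale abundance random-effect sds.
#' @param fn_intercept per-function logit-scale intercepts.
#' @param richness_effect per-function planted slope of logit rate on
#'   non-target richness.
#' @param treatment_effect per-function planted direct suppression effect
#'   (logit scale).
#' @param performer_effect per-function coefficient of the planted performer
#'   species' (log) abundance.
#' @param function_cov 4x4 correlation matrix of plot-by-event function noise.
#' @param fn_noise_sd sd of that noise; `fn_block_sd` the per-function block
#'   effect sd.
#' @param fn_block_sd see `fn_noise_sd`.
#' @param richness_center centering constant for the richness effect.
#' @param n_baits_ground,n_baits_protection baits per sampled plot quarter.
#' @param seed integer RNG seed; sub-streams are derived per table.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_blocks = 3, plots_per_zone = 2, n_quarters = 4,
                            n_events = 4, fn_quarters = 2,
                            n_species = 34, n_trait_groups = 5, n_targets = 3,
                            group_separation = 3,
                            target_suppression = c(0.06, 0.04, 0.01),
                            nontarget_release = 1.4,
                            n_colonists = 5, colonist_boost = 6,
                            nb_size = 1.2,
                            abund_meanlog = log(1.5), abund_sdlog = 1.0,
                            dominant_boost = 6,
                            block_sd = 0.15, plot_sd = 0.25, event_sd = 0.15,
                            fn_intercept = c(scavenging = qlogis(0.40),
                                             myrmecochory = qlogis(0.35),
                                             granivory = qlogis(0.45),
                                             plant_protection = qlogis(0.30)),
                            richness_effect = c(scavenging = 0.15,
                                                myrmecochory = 0.22,
                                                granivory = -0.18,
                                                plant_protection = 0.18),
                            treatment_effect = c(scavenging = 0,
                                                 myrmecochory = 0,
                                                 granivory = 0.5,
                                                 plant_protection = -0.9),
                            performer_effect = c(scavenging = 1,
                                                 myrmecochory = 1,
                                                 granivory = 1,
                                                 plant_protection = 1),
                            function_cov = default_function_cov(),
                            fn_noise_sd = 0.45, fn_block_sd = 0.2,
                            richness_center = 20,
                            n_baits_ground = 40, n_baits_protection = 16,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_species < 2) stop_mf("scenario_config: need at least 2 species")
  if (cfg$n_species < cfg$n_trait_groups)
    stop_mf("scenario_config: n_species < n_trait_groups")
  if (cfg$n_targets > cfg$n_trait_groups)
    stop_mf("scenario_config: n_targets > n_trait_groups")
  if (length(cfg$target_suppression) != cfg$n_targets)
    cfg$target_suppression <- rep_len(cfg$target_suppression, cfg$n_targets)
  if (any(cfg$target_suppression < 0 | cfg$target_suppression > 1))
    stop_mf("scenario_config: target_suppression must lie in [0, 1]")
  for (nm in c("fn_intercept", "richness_effect", "treatment_effect",
               "performer_effect"))
    cfg[[nm]] <- cfg[[nm]][.mf_functions]
  fc <- as.matrix(cfg$function_cov)
  if (!isSymmetric(unname(fc)) || min(eigen(fc, symmetric = TRUE,
                                            only.values = TRUE)$values) < -1e-8)
    stop_mf("scenario_config: function_cov must be a symmetric PSD correlation matrix")
  dimnames(fc) <- list(.mf_functions, .mf_functions)
  cfg$function_cov <- fc
  class(cfg) <- "scenario_config"
  cfg
}

#' Default between-function noise correlation
#'
#' Positive association among scavenging, myrmecochory and plant protection,
#' negative between granivory and both plant protection and myrmecochory.
#'
#' @return 4x4 correlation matrix.
#' @export
default_function_cov <- function() {
  m <- diag(4)
  dimnames(m) <- list(.mf_functions, .mf_functions)
  m["scavenging", "myrmecochory"] <- m["myrmecochory", "scavenging"] <- 0.3
  m["scavenging", "plant_protection"] <- m["plant_protection", "scavenging"] <- 0.3
  m["myrmecochory", "plant_protection"] <- m["plant_protection", "myrmecochory"] <- 0.3
  m["granivory", "plant_protection"] <- m["plant_protection", "granivory"] <- -0.35
  m["granivory", "myrmecochory"] <- m["myrmecochory", "granivory"] <- -0.3
  m
}

species_pool <- function(cfg) {
  ids <- sprintf("sp%02d", seq_len(cfg$n_species))
  groups <- rep_len(seq_len(cfg$n_trait_groups), cfg$n_species)
  names(groups) <- ids
  dominants <- vapply(seq_len(cfg$n_trait_groups),
                      function(g) ids[which(groups == g)[1]], character(1))
  targets <- dominants[seq_len(cfg$n_targets)]
  list(ids = ids, groups = groups, dominants = dominants, targets = targets)
}

#' Generate a species trait table with planted group structure
#'
#' Ten mixed-type traits (6 continuous morphometrics, 1 ordinal, 2 binary, 1
#' categorical) drawn from group-specific distributions separated by
#' `group_separation`, plus incidence weights with one high-incidence dominant
#' per group. The planted group labels are attached as attribute `groups`.
#'
#' @param cfg a [scenario_config()].
#' @return trait data.frame as read by [read_traits()].
#' @export
gen_traits <- function(cfg) {
  pool <- species_pool(cfg)
  n <- cfg$n_species; k <- cfg$n_trait_groups
  g <- pool$groups
  with_seed(sub_seed(cfg$seed, 1L), {
    cont_names <- c("weber_length", "head_width", "eye_width",
                    "leg_length", "mandible_index", "pronotum_width")
    mu <- matrix(rnorm(k * 6, sd = cfg$group_separation), k, 6)
    cont <- sapply(seq_len(6), function(j) mu[g, j] + rnorm(n))
    colnames(cont) <- cont_names
    p_g <- plogis(mu[, 1])                     # reuse group scores for discrete traits
    sculpt <- rbinom(n, 3, plogis(mu[g, 2])) + 1L
    polym <- rbinom(n, 1, p_g[g])
    spines <- rbinom(n, 1, plogis(mu[g, 3]))
    lev <- c("sparse", "moderate", "dense")
    pref <- (g %% 3L) + 1L
    pil_prob <- if (cfg$group_separation > 0) 0.7 else 1 / 3
    pilosity <- vapply(seq_len(n), function(i) {
      pr <- rep((1 - pil_prob) / 2, 3); pr[pref[i]] <- pil_prob
      sample(lev, 1, prob = pr)
    }, character(1))
    incidence <- runif(n, 0.05, 0.55)
    incidence[match(pool$dominants, pool$ids)] <- runif(k, 0.75, 0.95)
    df <- data.frame(species = pool$ids, round(cont, 4),
                     sculpturing = sculpt, polymorphic = polym,
                     spinescence = spines, pilosity = pilosity,
                     incidence = round(incidence, 4),
                     is_target = pool$ids %in% pool$targets,
                     stringsAsFactors = FALSE)
    attr(df, "trait_types") <- c(setNames(rep("continuous", 6), cont_names),
                                 sculpturing = "ordinal", polymorphic = "binary",
                                 spinescence = "binary", pilosity = "categorical")
    attr(df, "groups") <- g
    df
  })
}

# expected per-sample mean abundance of every species in each zone, before
# block/plot/event effects; used by gen_community and as generator ground truth
species_lambda <- function(cfg, pool) {
  with_seed(sub_seed(cfg$seed, 2L), {
    lambda <- if (is.finite(cfg$abund_meanlog))
      exp(rnorm(cfg$n_species, cfg$abund_meanlog, cfg$abund_sdlog))
    else rep(0, cfg$n_species)
    names(lambda) <- pool$ids
    lambda[pool$dominants] <- lambda[pool$dominants] * cfg$dominant_boost
    nontargets <- setdiff(pool$ids, pool$targets)
    colonists <- nontargets[order(lambda[nontargets])][seq_len(min(cfg$n_colonists,
                                                                   length(nontargets)))]
    mult_supp <- setNames(rep(cfg$nontarget_release, cfg$n_species), pool$ids)
    mult_supp[pool$targets] <- cfg$target_suppression
    mult_supp[colonists] <- cfg$nontarget_release * cfg$colonist_boost
    list(lambda = lambda, mult_supp = mult_supp, colonists = colonists)
  })
}

make_design <- function(cfg) {
  rows <- expand.grid(quarter = paste0("q", seq_len(cfg$n_quarters)),
                      plot_i = seq_len(cfg$plots_per_zone),
                      zone = .mf_zones,
                      block = paste0("B", seq_len(cfg$n_blocks)),
                      event = seq_len(cfg$n_events),
                      stringsAsFactors = FALSE)
  rows$zone_id <- paste(rows$block, rows$zone, sep = ":")
  rows$plot <- paste0(rows$block, "_", substr(rows$zone, 1, 1), "p", rows$plot_i)
  rows$sample_id <- paste(rows$plot, rows$quarter, paste0("e", rows$event), sep = ".")
  rows[, .design_cols]
}

#' Generate the pitfall community table
#'
#' Negative-binomial counts around species-specific means; in suppression
#' zones target means are multiplied by their suppression factor, non-targets
#' by `nontarget_release` and colonists additionally by `colonist_boost`.
#' Occasional non-zero target counts in suppression zones (long-range
#' foragers) arise from the retained fraction of the mean.
#'
#' @param cfg a [scenario_config()].
#' @param traits trait table from [gen_traits()] (defines the species pool).
#' @return a [community_matrix()].
#' @export
gen_community <- function(cfg, traits) {
  pool <- species_pool(cfg)
  stopifnot(identical(traits$species, pool$ids))
  lam <- species_lambda(cfg, pool)
  design <- make_design(cfg)
  with_seed(sub_seed(cfg$seed, 3L), {
    blocks <- unique(design$block); plots <- unique(design$plot)
    b_eff <- setNames(rnorm(length(blocks), 0, cfg$block_sd), blocks)
    p_eff <- setNames(rnorm(length(plots), 0, cfg$plot_sd), plots)
    e_eff <- setNames(rnorm(cfg$n_events, 0, cfg$event_sd),
                      as.character(seq_len(cfg$n_events)))
    mult <- ifelse(design$zone == "suppression", 1, NA)
    n_s <- cfg$n_species
    abund <- matrix(0L, nrow(design), n_s,
                    dimnames = list(design$sample_id, pool$ids))
    scale_row <- exp(b_eff[design$block] + p_eff[design$plot] +
                       e_eff[as.character(design$event)])
    for (s in seq_len(n_s)) {
      sp <- pool$ids[s]
      mu <- lam$lambda[sp] * scale_row *
        ifelse(design$zone == "suppression", lam$mult_supp[sp], 1)
      abund[, s] <- if (is.finite(cfg$nb_size))
        rnbinom(nrow(design), size = cfg$nb_size, mu = mu)
      else rpois(nrow(design), mu)
    }
    community_matrix(abund, design, pool$targets)
  })
}

#' Generate binomial function observations from a community
#'
#' Success probabilities follow the logit model described in
#' [scenario_config()]; counts are binomial with the configured numbers of
#' baits. Only the first `fn_quarters` quarters of each plot are assayed,
#' matching the field protocol.
#'
#' @param cfg a [scenario_config()].
#' @param comm a [community_matrix()] from [gen_community()].
#' @return long function-observation data.frame with attribute `truth`.
#' @export
gen_function_obs <- function(cfg, comm) {
  design <- comm$design
  pool <- species_pool(cfg)
  lam <- species_lambda(cfg, pool)
  keep <- design$quarter %in% paste0("q", seq_len(cfg$fn_quarters))
  d <- design[keep, , drop = FALSE]
  nt <- setdiff(colnames(comm$abund), comm$targets)
  S_nt <- rowSums(comm$abund[d$sample_id, nt, drop = FALSE] > 0)

  # planted performers: the most abundant non-target, non-colonist species
  cand <- setdiff(nt, lam$colonists)
  performers <- setNames(cand[order(-lam$lambda[cand])][seq_len(4)], .mf_functions)

  with_seed(sub_seed(cfg$seed, 4L), {
    blocks <- unique(d$block)
    b_eff <- matrix(rnorm(length(blocks) * 4, 0, cfg$fn_block_sd),
                    length(blocks), 4, dimnames = list(blocks, .mf_functions))
    pe <- unique(d[, c("plot", "event")])
    pe_key <- paste(pe$plot, pe$event)
    noise <- matrix(rnorm(nrow(pe) * 4), nrow(pe), 4) %*%
      chol(cfg$function_cov) * cfg$fn_noise_sd
    rownames(noise) <- pe_key

    # performer abundance acts at the plot-by-event scale: the plot's whole
    # foraging population, not the single quarter's pitfall count
    pe_all <- paste(design$plot, design$event)
    out <- vector("list", 4)
    for (i in seq_along(.mf_functions)) {
      f <- .mf_functions[i]
      perf <- performers[[f]]
      a_pe <- rowsum(comm$abund[, perf, drop = FALSE], pe_all)
      a_perf <- a_pe[paste(d$plot, d$event), 1]
      eta <- cfg$fn_intercept[[f]] +
        cfg$richness_effect[[f]] * (S_nt - cfg$richness_center) +
        cfg$treatment_effect[[f]] * (d$zone == "suppression") +
        cfg$performer_effect[[f]] *
          (log1p(a_perf) - log1p(cfg$n_quarters * lam$lambda[perf])) +
        b_eff[d$block, f] + noise[paste(d$plot, d$event), f]
      n_off <- if (f == "plant_protection") cfg$n_baits_protection else cfg$n_baits_ground
      out[[i]] <- data.frame(sample_id = d$sample_id, function_id = f,
                             n_offered = n_off,
                             n_success = rbinom(nrow(d), n_off, plogis(eta)),
                             assessment_window = switch(f, scavenging = 30,
                                                        plant_protection = 15, 60),
                             stringsAsFactors = FALSE)
    }
    fobs <- do.call(rbind, out)
    rownames(fobs) <- NULL
    attr(fobs, "truth") <- list(performers = as.list(performers),
                                richness_effect = as.list(cfg$richness_effect),
                                treatment_effect = as.list(cfg$treatment_effect),
                                performer_effect = as.list(cfg$performer_effect),
                                richness_center = cfg$richness_center)
    fobs
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs [gen_traits()], [gen_community()] and [gen_function_obs()] and bundles
#' the tables with a ground-truth sidecar (planted trait groups, targets,
#' suppression factors, function-model coefficients and performer species).
#' When `dir` is given, all tables are written as CSV and the truth as YAML;
#' two runs with the same seed produce byte-identical files.
#'
#' @param cfg a [scenario_config()].
#' @param dir optional output directory.
#' @return list `design, community, traits, functions, truth` (+ `paths` when
#'   written), invisibly when `dir` is given.
#' @export
gen_scenario <- function(cfg = scenario_config(), dir = NULL) {
  traits <- gen_traits(cfg)
  comm <- gen_community(cfg, traits)
  fobs <- gen_function_obs(cfg, comm)
  pool <- species_pool(cfg)
  lam <- species_lambda(cfg, pool)
  truth <- c(list(groups = as.list(pool$groups),
                  dominants = as.list(setNames(pool$dominants,
                                               paste0("group", seq_along(pool$dominants)))),
                  targets = pool$targets,
                  target_suppression = as.list(setNames(cfg$target_suppression,
                                                        pool$targets)),
                  nontarget_release = cfg$nontarget_release,
                  colonists = lam$colonists,
                  function_cov = apply(cfg$function_cov, 1, as.list),
                  seed = cfg$seed),
             attr(fobs, "truth"))
  scn <- list(design = comm$design, community = comm, traits = traits,
              functions = fobs, truth = truth)
  if (!is.null(dir)) {
    scn$paths <- write_tables(scn, dir)
    return(invisible(scn))
  }
  scn
}
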