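#' Gower distance for mixed-type traits
#'
#' Per-trait contributions: continuous and ordinal traits contribute
#' `|x_i - x_j| / range`, binary and categorical traits contribute a 0/1
#' mismatch; the distance is the average over traits with both values
#' non-missing. Continuous/ordinal traits with zero range have no defined
#' contribution and are excluded with a warning; constant binary or
#' categorical traits contribute a well-defined mismatch of zero and are
#' kept. If no trait varies at all an error is raised.
#'
#' @param traits trait data.frame as returned by [read_traits()] or
#'   [gen_traits()] (`species`, trait columns, `incidence`).
#' @param types optional named character vector of trait types; defaults to
#'   the table's `trait_types` attribute (inferred when absent).
#' @return symmetric species x species distance matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
gower_matrix <- function(traits, types = NULL) {
  tcols <- setdiff(names(traits), c("species", "incidence", "is_target"))
  if (nrow(traits) < 2) stop_mf("gower_matrix: need at least 2 species")
  types <- types %||% attr(traits, "trait_types") %||%
    infer_trait_types(traits[tcols])
  n <- nrow(traits)
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  varying <- 0L
  for (tr in tcols) {
    x <- traits[[tr]]
    ok <- !is.na(x)
    obs <- outer(ok, ok, `&`)
    d <- switch(types[[tr]],
      continuous = , ordinal = {
        rng <- diff(range(as.numeric(x[ok])))
        if (rng == 0) { warning("gower_matrix: constant trait '", tr,
                                "' excluded"); next }
        abs(outer(as.numeric(x), as.numeric(x), `-`)) / rng
      },
      binary = , categorical = 1 * outer(x, x, `!=`))
    d[!obs] <- 0
    num <- num + d
    cnt <- cnt + obs
    if (length(unique(x[ok])) > 1) varying <- varying + 1L
  }
  if (varying == 0L) stop_mf("gower_matrix: all traits constant")
  out <- num / pmax(cnt, 1)
  out[cnt == 0] <- NA
  diag(out) <- 0
  dimnames(out) <- list(traits$species, traits$species)
  out
}

#' Incidence-weighted principal coordinates analysis
#'
#' Classical scaling of a (Gower) distance matrix with species weighted by
#' their site-wide incidence, so the embedded trait space reflects how often
#' species actually occur. Computed with [vegan::wcmdscale()]; when any
#' eigenvalue falls below `-1e-8` a Cailliez correction is applied and the
#' variance explained is reported on the corrected positive spectrum.
#'
#' @param d symmetric distance matrix.
#' @param weights non-negative species weights (e.g. incidence); `NULL` for
#'   unweighted analysis.
#' @param correction `"cailliez"` (default) or `"none"`.
#' @return object of class `trait_pcoa`: list with `coords` (species x axes),
#'   `eigvals`, `var_explained` (non-increasing, sums to 1 over retained
#'   axes), `weights`, `corrected`.
#' @export
trait_pcoa <- function(d, weights = NULL, correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop_mf("trait_pcoa: distance matrix must be symmetric")
  if (!is.null(weights)) {
    if (length(weights) != nrow(d) || any(weights < 0) || sum(weights) <= 0)
      stop_mf("trait_pcoa: weights must be non-negative, not all zero, one per species")
  } else weights <- rep(1, nrow(d))
  fit <- vegan::wcmdscale(as.dist(d), eig = TRUE, w = weights)
  corrected <- FALSE
  if (correction == "cailliez" && min(fit$eig) < -1e-8) {
    fit <- vegan::wcmdscale(as.dist(d), eig = TRUE, add = "cailliez", w = weights)
    corrected <- TRUE
  }
  pos <- fit$eig > 1e-10
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("A", seq_len(ncol(coords)))
  ve <- fit$eig[pos] / sum(fit$eig[pos])
  structure(list(coords = coords, eigvals = fit$eig, var_explained = ve,
                 weights = weights, corrected = corrected),
            class = "trait_pcoa")
}

#' @export
print.trait_pcoa <- function(x, ...) {
  cat("Weighted PCoA:", nrow(x$coords), "species,", ncol(x$coords),
      "positive axes", if (x$corrected) "(Cailliez-corrected)", "\n")
  cat("Variance explained (first axes):",
      paste0(round(100 * head(x$var_explained, 4), 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Partition species into trait groups
#'
#' Partitioning-around-medoids on the Gower distance matrix. Deterministic
#' for a given distance matrix (no random initialization in `cluster::pam`
#' with `diss = TRUE`).
#'
#' @param d species x species distance matrix.
#' @param k_groups number of groups (1..n_species).
#' @return named integer vector of group labels.
#' @export
cluster_trait_groups <- function(d, k_groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k_groups < 1) stop_mf("cluster_trait_groups: k_groups must be >= 1")
  if (k_groups > n) stop_mf("cluster_trait_groups: k_groups exceeds n_species")
  if (k_groups == 1) return(setNames(rep(1L, n), rownames(d)))
  if (k_groups == n) return(setNames(seq_len(n), rownames(d)))
  cl <- cluster::pam(as.dist(d), k = k_groups, diss = TRUE, cluster.only = TRUE)
  setNames(as.integer(cl), rownames(d))
}

#' Select the dominant species of each trait group
#'
#' The dominant is the species with the highest site-wide incidence within
#' its group; ties are broken by lexicographically smallest species id and
#' flagged in the `ties` attribute.
#'
#' @param groups named group labels (species -> group).
#' @param incidence named incidence weights covering the same species.
#' @return named character vector, one dominant species id per group, with
#'   attribute `ties`.
#' @export
select_dominants <- function(groups, incidence) {
  sp <- names(groups)
  if (!all(sp %in% names(incidence)))
    stop_mf("select_dominants: incidence missing for some species")
  ties <- character()
  doms <- vapply(sort(unique(groups)), function(g) {
    members <- sort(sp[groups == g])
    if (!length(members)) stop_mf("select_dominants: empty group ", g)
    inc <- incidence[members]
    best <- members[inc == max(inc)]
    if (length(best) > 1) ties <<- c(ties, best[1])
    best[1]
  }, character(1))
  names(doms) <- paste0("group", sort(unique(groups)))
  attr(doms, "ties") <- ties
  doms
}

#' Build the full trait space
#'
#' Convenience wrapper: Gower distances, incidence-weighted PCoA, trait-group
#' clustering and dominant selection in one object.
#'
#' @param traits trait table.
#' @param k_groups number of trait groups (default 5).
#' @param weighted use incidence weights in the PCoA.
#' @return list with `distance`, `coords`, `eigvals`, `var_explained`,
#'   `groups`, `dominants`, class `trait_space`.
#' @export
build_trait_space <- function(traits, k_groups = 5, weighted = TRUE) {
  d <- gower_matrix(traits)
  w <- if (weighted) setNames(traits$incidence, traits$species) else NULL
  pc <- trait_pcoa(d, weights = w)
  groups <- cluster_trait_groups(d, k_groups)
  doms <- select_dominants(groups, setNames(traits$incidence, traits$species))
  structure(list(distance = d, coords = pc$coords, eigvals = pc$eigvals,
                 var_explained = pc$var_explained, groups = groups,
                 dominants = doms, pcoa = pc),
            class = "trait_space")
}

# shoelace polygon area of the convex hull of 2-D points
hull_area2 <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(0)
  h <- chull(xy)
  p <- xy[h, , drop = FALSE]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Functional richness of one community
#'
#' Convex-hull area of the species present in the sample, in the first
#' `n_axes` trait-space axes. Defined as 0 when fewer than `n_axes + 1`
#' species are present or the point set is degenerate (collinear). Only the
#' two-axis case is supported, matching the two retained ordination axes.
#'
#' @param abund named abundance vector for one sample.
#' @param coords species x axes PCoA coordinates.
#' @param n_axes number of leading axes (must be 2).
#' @return non-negative hull area.
#' @export
fric <- function(abund, coords, n_axes = 2) {
  if (n_axes != 2)
    stop_mf("fric: only n_axes = 2 is supported (two retained ordination axes)")
  if (ncol(coords) < n_axes) stop_mf("fric: coords have fewer than n_axes axes")
  present <- names(abund)[abund > 0]
  present <- intersect(present, rownames(coords))
  if (length(present) < n_axes + 1) return(0)
  hull_area2(coords[present, seq_len(n_axes), drop = FALSE])
}

#' Functional dispersion of one community
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid in trait space: `c = sum(a_j x_j) / sum(a_j)`,
#' `FDis = sum(a_j ||x_j - c||) / sum(a_j)`. Zero when at most one species is
#' present; `NA` (flagged) for an empty sample.
#'
#' @param abund named abundance vector for one sample.
#' @param coords species x axes coordinates (all columns used).
#' @return non-negative dispersion, or `NA` for an empty sample.
#' @export
fdis <- function(abund, coords) {
  present <- names(abund)[abund > 0]
  present <- intersect(present, rownames(coords))
  if (!length(present)) return(NA_real_)
  if (length(present) == 1) return(0)
  a <- abund[present]
  x <- coords[present, , drop = FALSE]
  ctr <- colSums(x * a) / sum(a)
  dist_c <- sqrt(rowSums((x - matrix(ctr, nrow(x), ncol(x), byrow = TRUE))^2))
  sum(a * dist_c) / sum(a)
}

#' Per-sample functional-diversity metrics
#'
#' @param comm a [community_matrix()].
#' @param coords species x axes coordinates from [trait_pcoa()].
#' @param n_axes axes used for the FRic hull (2).
#' @param exclude_targets drop the suppressed target species before
#'   computing metrics.
#' @return data.frame `sample_id, FRic, FDis` merged with the design columns.
#' @export
fd_metrics <- function(comm, coords, n_axes = 2, exclude_targets = TRUE) {
  abund <- comm$abund
  if (exclude_targets && length(comm$targets))
    abund <- abund[, setdiff(colnames(abund), comm$targets), drop = FALSE]
  out <- data.frame(
    sample_id = rownames(abund),
    FRic = apply(abund, 1, fric, coords = coords, n_axes = n_axes),
    FDis = apply(abund, 1, fdis, coords = coords),
    stringsAsFactors = FALSE)
  merge(comm$design, out, by = "sample_id", sort = FALSE)
}
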