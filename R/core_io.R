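#' Typed readers, writers and validation for the four experiment tables
#'
#' The pipeline is driven by four plain-text CSV tables:
#' \describe{
#'   \item{design}{one row per sample: `sample_id, block, zone, zone_id, plot,
#'     quarter, event`. `zone` is the treatment level (`control` or
#'     `suppression`); `zone_id` identifies the physical block-zone unit of the
#'     split-plot layout.}
#'   \item{community}{wide table: `sample_id` plus one abundance-count column
#'     per species (individuals per pitfall set).}
#'   \item{traits}{one row per species: `species`, trait columns, `incidence`
#'     (site-wide fraction of traps occupied, in \[0, 1\]) and optionally
#'     `is_target` flagging the suppressed dominants.}
#'   \item{functions}{long table of bait trials: `sample_id, function_id,
#'     n_offered, n_success` and optionally `assessment_window` (minutes).
#'     Rates are carried as count pairs, never pre-divided, so binomial
#'     information is preserved for the models.}
#' }
#'
#' @name core_io
NULL

.design_cols <- c("sample_id", "block", "zone", "zone_id", "plot", "quarter", "event")
.function_cols <- c("sample_id", "function_id", "n_offered", "n_success")

rename_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  # schema: named character vector canonical_name = file_column
  for (canon in names(schema)) {
    hit <- match(schema[[canon]], names(df))
    if (!is.na(hit)) names(df)[hit] <- canon
  }
  df
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_mf("schema error in ", what, ": missing column(s) ",
            paste(miss, collapse = ", "), class = "mufunlab_schema_error")
  invisible(df)
}

#' Read a sample-design table
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column names
#'   to the column names used in the file, e.g. `c(block = "Block")`.
#' @return a data.frame with columns `sample_id, block, zone, zone_id, plot,
#'   quarter, event`.
#' @export
read_design <- function(path, schema = NULL) {
  df <- rename_schema(read.csv(path, stringsAsFactors = FALSE), schema)
  if (!"zone_id" %in% names(df) && all(c("block", "zone") %in% names(df)))
    df$zone_id <- paste(df$block, df$zone, sep = ":")
  require_cols(df, .design_cols, "design")
  bad <- setdiff(unique(df$zone), .mf_zones)
  if (length(bad))
    stop_mf("design: unknown zone level(s) ", paste(bad, collapse = ", "),
            class = "mufunlab_schema_error")
  df[, .design_cols]
}

#' Validate the split-plot design
#'
#' Confirms the nesting (plots in zones in blocks), the balance of treatment
#' levels within blocks, and sample-key uniqueness. Flags rather than errors
#' are returned for balance problems; structural violations (a plot assigned
#' to two blocks, duplicate sample keys) raise errors.
#'
#' @param design data.frame as returned by [read_design()].
#' @return an object of class `design_report`: list with elements `ok`
#'   (logical), `flags` (character) and `counts`.
#' @export
validate_design <- function(design) {
  require_cols(design, .design_cols, "design")
  if (!nrow(design)) stop_mf("design is empty")
  flags <- character()

  dup <- duplicated(design[, c("plot", "quarter", "event")])
  if (any(dup))
    stop_mf("design: duplicate (plot, quarter, event) key(s): ",
            paste(unique(design$sample_id[dup]), collapse = ", "),
            class = "mufunlab_uniqueness_error")
  if (anyDuplicated(design$sample_id))
    stop_mf("design: duplicate sample_id", class = "mufunlab_uniqueness_error")

  # nesting: each plot belongs to exactly one zone_id, each zone_id to one block
  pb <- unique(design[, c("plot", "block")])
  if (anyDuplicated(pb$plot))
    stop_mf("design: plot(s) assigned to more than one block: ",
            paste(unique(pb$plot[duplicated(pb$plot)]), collapse = ", "),
            class = "mufunlab_nesting_error")
  pz <- unique(design[, c("plot", "zone_id")])
  if (anyDuplicated(pz$plot))
    stop_mf("design: plot(s) assigned to more than one zone: ",
            paste(unique(pz$plot[duplicated(pz$plot)]), collapse = ", "),
            class = "mufunlab_nesting_error")

  # balance: each block should hold exactly one zone unit per treatment level
  zb <- unique(design[, c("block", "zone", "zone_id")])
  for (b in unique(zb$block)) {
    for (z in .mf_zones) {
      n <- sum(zb$block == b & zb$zone == z)
      if (n == 0L) flags <- c(flags, sprintf("block %s missing a %s zone", b, z))
      if (n > 1L) flags <- c(flags, sprintf("block %s has %d %s zones", b, n, z))
    }
  }

  out <- list(ok = !length(flags), flags = flags,
              counts = c(blocks = length(unique(design$block)),
                         plots = length(unique(design$plot)),
                         samples = nrow(design)))
  class(out) <- "design_report"
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat("Split-plot design:", x$counts["blocks"], "blocks,", x$counts["plots"],
      "plots,", x$counts["samples"], "samples\n")
  if (x$ok) cat("All balance checks passed\n")
  else cat("Flags:\n", paste(" -", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Construct a community matrix object
#'
#' @param abund integer matrix, samples x species, rownames = sample ids.
#' @param design the matching design table.
#' @param targets character vector of suppressed target species ids.
#' @return object of class `community_matrix`.
#' @export
community_matrix <- function(abund, design, targets = character()) {
  abund <- as.matrix(abund)
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop_mf("community: abundance matrix needs sample rownames and species colnames")
  if (any(abund < 0) || any(abund != round(abund)))
    stop_mf("community: abundances must be non-negative integers",
            class = "mufunlab_bounds_error")
  miss <- setdiff(rownames(abund), design$sample_id)
  if (length(miss))
    stop_mf("community: sample(s) absent from design: ",
            paste(head(miss, 5), collapse = ", "),
            class = "mufunlab_referential_error")
  bad <- setdiff(targets, colnames(abund))
  if (length(bad))
    stop_mf("community: target species not in matrix: ", paste(bad, collapse = ", "),
            class = "mufunlab_referential_error")
  design <- design[match(rownames(abund), design$sample_id), , drop = FALSE]
  structure(list(abund = abund, design = design, targets = targets),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$abund), "samples x", ncol(x$abund), "species;",
      length(x$targets), "target species\n")
  invisible(x)
}

#' Read a wide community table
#'
#' @inheritParams read_design
#' @param design design table used to cross-reference sample ids.
#' @param targets character vector of target species ids (may also be taken
#'   from the trait table's `is_target` column by [load_tables()]).
#' @return a `community_matrix`.
#' @export
read_community <- function(path, design, targets = character(), schema = NULL) {
  df <- rename_schema(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE), schema)
  require_cols(df, "sample_id", "community")
  abund <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(abund) <- df$sample_id
  storage.mode(abund) <- "double"
  community_matrix(abund, design, targets)
}

#' Read a species trait table
#'
#' Trait columns are every column other than `species`, `incidence` and
#' `is_target`. Types are declared through `trait_types` (named vector with
#' values `continuous`, `ordinal`, `binary`, `categorical`); undeclared traits
#' are inferred: numeric 0/1 -> binary, other numeric -> continuous,
#' character/factor -> categorical.
#'
#' @inheritParams read_design
#' @param trait_types optional named character vector of trait types.
#' @return data.frame with attribute `trait_types`.
#' @export
read_traits <- function(path, trait_types = NULL, schema = NULL) {
  df <- rename_schema(read.csv(path, stringsAsFactors = FALSE), schema)
  require_cols(df, c("species", "incidence"), "traits")
  if (anyDuplicated(df$species)) stop_mf("traits: duplicate species ids")
  if (any(df$incidence < 0 | df$incidence > 1))
    stop_mf("traits: incidence must lie in [0, 1]", class = "mufunlab_bounds_error")
  if (nrow(df) < 2) stop_mf("traits: need at least 2 species")
  if (!"is_target" %in% names(df)) df$is_target <- FALSE
  tcols <- setdiff(names(df), c("species", "incidence", "is_target"))
  types <- infer_trait_types(df[tcols], trait_types)
  attr(df, "trait_types") <- types
  df
}

infer_trait_types <- function(tr, declared = NULL) {
  types <- vapply(names(tr), function(nm) {
    if (!is.null(declared) && nm %in% names(declared)) return(declared[[nm]])
    x <- tr[[nm]]
    if (is.character(x) || is.factor(x)) "categorical"
    else if (is.logical(x) || all(x %in% c(0, 1, NA))) "binary"
    else "continuous"
  }, character(1))
  ok <- c("continuous", "ordinal", "binary", "categorical")
  bad <- setdiff(types, ok)
  if (length(bad)) stop_mf("traits: unknown trait type(s) ", paste(bad, collapse = ", "))
  types
}

#' Read a long function-observation table
#'
#' @inheritParams read_design
#' @return data.frame `sample_id, function_id, n_offered, n_success,
#'   assessment_window`.
#' @export
read_function_obs <- function(path, schema = NULL) {
  df <- rename_schema(read.csv(path, stringsAsFactors = FALSE), schema)
  require_cols(df, .function_cols, "functions")
  if (!"assessment_window" %in% names(df)) df$assessment_window <- NA_real_
  if (any(df$n_offered < 0) || any(df$n_success < 0) ||
      any(df$n_success > df$n_offered))
    stop_mf("functions: need 0 <= n_success <= n_offered",
            class = "mufunlab_bounds_error")
  df <- df[df$n_offered > 0, , drop = FALSE]
  df[, c(.function_cols, "assessment_window")]
}

#' Load and cross-validate all four tables
#'
#' Reads the design, community, trait and function tables, reconciles the
#' species sets (species present in the traits but never captured are dropped
#' with a report entry; species in the community but absent from the trait
#' table are a referential error), and validates the design.
#'
#' @param paths named list with elements `design`, `community`, `traits`,
#'   `functions` (file paths), e.g. as produced by [gen_scenario()].
#' @param trait_types passed to [read_traits()].
#' @param schema optional named list of per-table schemas (see [read_design()]).
#' @return list with elements `design`, `community` (a `community_matrix`),
#'   `traits`, `functions`, `report` (character vector of reconciliation
#'   notes) and `design_report`.
#' @export
load_tables <- function(paths, trait_types = NULL, schema = NULL) {
  for (nm in c("design", "community", "traits", "functions"))
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop_mf("load_tables: missing file for table '", nm, "'")
  sch <- function(nm) if (is.null(schema)) NULL else schema[[nm]]
  report <- character()

  design <- read_design(paths$design, sch("design"))
  traits <- read_traits(paths$traits, trait_types, sch("traits"))
  targets <- traits$species[isTRUE_vec(traits$is_target)]
  comm <- read_community(paths$community, design, targets, sch("community"))
  fobs <- read_function_obs(paths$functions, sch("functions"))

  orphans <- setdiff(colnames(comm$abund), traits$species)
  if (length(orphans))
    stop_mf("community species absent from trait table: ",
            paste(orphans, collapse = ", "), class = "mufunlab_referential_error")
  unseen <- setdiff(traits$species, colnames(comm$abund))
  if (length(unseen)) {
    report <- c(report, paste0("dropped trait rows for species never captured: ",
                               paste(unseen, collapse = ", ")))
    tt <- attr(traits, "trait_types")
    traits <- traits[!traits$species %in% unseen, , drop = FALSE]
    attr(traits, "trait_types") <- tt
  }
  bad_fn <- setdiff(fobs$sample_id, design$sample_id)
  if (length(bad_fn))
    stop_mf("function observations reference unknown sample(s): ",
            paste(head(bad_fn, 5), collapse = ", "),
            class = "mufunlab_referential_error")

  dr <- validate_design(design)
  report <- c(report, dr$flags)
  list(design = design, community = comm, traits = traits, functions = fobs,
       report = report, design_report = dr)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write a scenario's tables to CSV
#'
#' @param scn list with `design`, `community`, `traits`, `functions` (and
#'   optionally `truth`), as returned by [gen_scenario()].
#' @param dir output directory (created if needed).
#' @return named list of the file paths written, invisibly.
#' @export
write_tables <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(design = file.path(dir, "design.csv"),
            community = file.path(dir, "community.csv"),
            traits = file.path(dir, "traits.csv"),
            functions = file.path(dir, "functions.csv"))
  write.csv(scn$design, p$design, row.names = FALSE)
  comm_df <- data.frame(sample_id = rownames(scn$community$abund),
                        scn$community$abund, check.names = FALSE)
  write.csv(comm_df, p$community, row.names = FALSE)
  write.csv(scn$traits, p$traits, row.names = FALSE)
  write.csv(scn$functions, p$functions, row.names = FALSE)
  if (!is.null(scn$truth)) {
    p$truth <- file.path(dir, "ground_truth.yaml")
    yaml::write_yaml(scn$truth, p$truth)
  }
  invisible(p)
}
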