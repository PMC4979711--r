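#' Assemble and validate a community survey dataset
#'
#' Bundles a patch table and an observation table (plus optional species
#' groups) into a validated `comm_data` object, the input to all fitting and
#' simulation functions.  Two survey modes are supported:
#'
#' * `"abundance"`: the observation table holds encounter frequencies — for
#'   each species and patch, the number of individuals (territories) detected
#'   exactly `H` times over `visits` repeated visits.  Patches carry a sampled
#'   fraction `phi` (sampled area / patch area) and a visit count.
#' * `"frequency"`: the observation table holds plot occurrences — for each
#'   species and patch, the number of sampled plots (`y` of `ap`) in which the
#'   species was recorded.  Patches carry the sampled plot count `ap` and the
#'   total number of plots `tp` tessellating the patch; a missing `tp` is
#'   derived from the patch area via [total_plots()].
#'
#' Species and patches are keyed by string identifiers; internal integer
#' indices are assigned by sorted order, so results do not depend on the row
#' order of the input tables.
#'
#' @param patches data frame with columns `patch_id`, `area_ha`, and, per
#'   mode, `phi` and `visits` (abundance) or `ap` and `tp` (frequency).
#' @param observations data frame with columns `species_id`, `patch_id` and
#'   either `H`, `count` (abundance) or `y` (frequency).
#' @param mode `"abundance"` or `"frequency"`.
#' @param groups optional data frame with columns `species_id`, `group`.
#'   Every detected species (positive count somewhere) must map to exactly
#'   one group when groups are supplied.
#' @param plot_area_m2 area of one sampling plot in square metres, used to
#'   derive `tp` when that column is absent or blank.
#' @return An object of class `comm_data`: a list with elements `patches`,
#'   `obs`, `species` (one row per species: `species_id`, `group`,
#'   `augmented`), `mode`, and `plot_area_m2`.
#' @seealso [load_dataset()], [write_dataset()], [augment_dataset()]
#' @examples
#' patches <- data.frame(patch_id = c("p1", "p2"), area_ha = c(1, 4),
#'                       phi = 1, visits = 3)
#' obs <- data.frame(species_id = c("spA", "spA", "spB"),
#'                   patch_id = c("p1", "p2", "p1"),
#'                   H = c(1, 2, 1), count = c(2, 1, 5))
#' d <- community_data(patches, obs, mode = "abundance")
#' d
#' @export
community_data <- function(patches, observations, mode = c("abundance", "frequency"),
                           groups = NULL, plot_area_m2 = 1) {
  mode <- match.arg(mode)
  patches <- as.data.frame(patches)
  observations <- as.data.frame(observations)

  need <- c("patch_id", "area_ha")
  if (!all(need %in% names(patches)))
    stop_invalid("columns", "patches table lacks column(s): %s",
                 paste(setdiff(need, names(patches)), collapse = ", "))
  patches$patch_id <- as.character(patches$patch_id)
  if (anyDuplicated(patches$patch_id))
    stop_invalid("duplicate_patch", "duplicated patch_id: %s",
                 patches$patch_id[duplicated(patches$patch_id)][1L])
  bad <- which(!is.finite(patches$area_ha) | patches$area_ha <= 0)
  if (length(bad))
    stop_invalid("area", "patch '%s': area_ha must be > 0 (got %s)",
                 patches$patch_id[bad[1L]], patches$area_ha[bad[1L]])

  if (mode == "abundance") {
    if (is.null(patches$phi)) patches$phi <- 1
    if (is.null(patches$visits))
      stop_invalid("columns", "abundance patches table lacks column: visits")
    bad <- which(!is.finite(patches$phi) | patches$phi <= 0 | patches$phi > 1)
    if (length(bad))
      stop_invalid("phi", "patch '%s': phi must lie in (0, 1] (got %s)",
                   patches$patch_id[bad[1L]], patches$phi[bad[1L]])
    bad <- which(!is_count(patches$visits) | patches$visits < 1)
    if (length(bad))
      stop_invalid("visits", "patch '%s': visits must be a positive integer",
                   patches$patch_id[bad[1L]])
  } else {
    if (is.null(patches$ap))
      stop_invalid("columns", "frequency patches table lacks column: ap")
    if (is.null(patches$tp)) patches$tp <- NA_real_
    miss <- is.na(patches$tp)
    if (any(miss))
      patches$tp[miss] <- total_plots(patches$area_ha[miss], plot_area_m2)
    bad <- which(!is_count(patches$ap))
    if (length(bad))
      stop_invalid("ap", "patch '%s': ap must be a nonnegative integer",
                   patches$patch_id[bad[1L]])
    bad <- which(!is_count(patches$tp) | patches$tp < 1)
    if (length(bad))
      stop_invalid("tp", "patch '%s': tp must be a positive integer",
                   patches$patch_id[bad[1L]])
    bad <- which(patches$ap > patches$tp)
    if (length(bad))
      stop_invalid("ap_gt_tp", "patch '%s': ap (%d) exceeds tp (%d)",
                   patches$patch_id[bad[1L]], as.integer(patches$ap[bad[1L]]),
                   as.integer(patches$tp[bad[1L]]))
  }
  # canonical column types so datasets round-trip through CSV exactly
  patches$area_ha <- as.numeric(patches$area_ha)
  if (mode == "abundance") {
    patches$phi <- as.numeric(patches$phi)
    patches$visits <- as.integer(patches$visits)
  } else {
    patches$ap <- as.integer(patches$ap)
    patches$tp <- as.integer(patches$tp)
  }
  patches <- patches[order(patches$patch_id), , drop = FALSE]
  rownames(patches) <- NULL

  obs_cols <- if (mode == "abundance") c("species_id", "patch_id", "H", "count")
              else c("species_id", "patch_id", "y")
  if (!all(obs_cols %in% names(observations)))
    stop_invalid("columns", "observations table lacks column(s): %s",
                 paste(setdiff(obs_cols, names(observations)), collapse = ", "))
  observations <- observations[obs_cols]
  observations$species_id <- as.character(observations$species_id)
  observations$patch_id <- as.character(observations$patch_id)
  unknown <- setdiff(observations$patch_id, patches$patch_id)
  if (length(unknown))
    stop_invalid("unknown_patch", "observations refer to unknown patch '%s'",
                 unknown[1L])
  pidx <- match(observations$patch_id, patches$patch_id)

  if (mode == "abundance") {
    bad <- which(!is_count(observations$count))
    if (length(bad))
      stop_invalid("count", "observations row %d (species '%s'): count must be a nonnegative integer",
                   bad[1L], observations$species_id[bad[1L]])
    bad <- which(!is_count(observations$H) | observations$H < 1)
    if (length(bad))
      stop_invalid("H", "observations row %d (species '%s'): H must be an integer >= 1",
                   bad[1L], observations$species_id[bad[1L]])
    bad <- which(observations$H > patches$visits[pidx])
    if (length(bad))
      stop_invalid("H_gt_visits",
                   "observations row %d (species '%s', patch '%s'): H = %d exceeds visits = %d",
                   bad[1L], observations$species_id[bad[1L]],
                   observations$patch_id[bad[1L]],
                   as.integer(observations$H[bad[1L]]),
                   as.integer(patches$visits[pidx[bad[1L]]]))
    key <- paste(observations$species_id, observations$patch_id, observations$H)
    if (anyDuplicated(key))
      stop_invalid("duplicate_obs", "duplicated (species, patch, H) row: %s",
                   key[duplicated(key)][1L])
  } else {
    bad <- which(!is_count(observations$y))
    if (length(bad))
      stop_invalid("y", "observations row %d (species '%s'): y must be a nonnegative integer",
                   bad[1L], observations$species_id[bad[1L]])
    bad <- which(observations$y > patches$ap[pidx])
    if (length(bad))
      stop_invalid("y_gt_ap",
                   "observations row %d (species '%s', patch '%s'): y = %d exceeds ap = %d",
                   bad[1L], observations$species_id[bad[1L]],
                   observations$patch_id[bad[1L]],
                   as.integer(observations$y[bad[1L]]),
                   as.integer(patches$ap[pidx[bad[1L]]]))
    key <- paste(observations$species_id, observations$patch_id)
    if (anyDuplicated(key))
      stop_invalid("duplicate_obs", "duplicated (species, patch) row: %s",
                   key[duplicated(key)][1L])
  }
  for (col in intersect(c("H", "count", "y"), names(observations)))
    observations[[col]] <- as.integer(observations[[col]])
  ord <- order(observations$species_id, observations$patch_id)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL

  species <- data.frame(species_id = sort(unique(observations$species_id)),
                        group = NA_character_, augmented = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- as.data.frame(groups)
    if (!all(c("species_id", "group") %in% names(groups)))
      stop_invalid("columns", "groups table lacks column(s): species_id, group")
    groups$species_id <- as.character(groups$species_id)
    groups$group <- as.character(groups$group)
    if (anyDuplicated(groups$species_id))
      stop_invalid("duplicate_group", "species '%s' mapped to more than one group",
                   groups$species_id[duplicated(groups$species_id)][1L])
    cnt <- if (mode == "abundance") observations$count else observations$y
    det <- unique(observations$species_id[cnt > 0])
    missing_grp <- setdiff(det, groups$species_id)
    if (length(missing_grp))
      stop_invalid("ungrouped", "detected species '%s' has no group assignment",
                   missing_grp[1L])
    species$group <- groups$group[match(species$species_id, groups$species_id)]
  }

  structure(list(patches = patches, obs = observations, species = species,
                 mode = mode, plot_area_m2 = plot_area_m2),
            class = "comm_data")
}

#' @export
print.comm_data <- function(x, ...) {
  cat(sprintf("<comm_data> %s survey: %d species x %d patches\n",
              x$mode, nrow(x$species), nrow(x$patches)))
  cat(sprintf("  areas %.4g-%.4g ha", min(x$patches$area_ha), max(x$patches$area_ha)))
  if (x$mode == "abundance")
    cat(sprintf("; phi %.3g-%.3g; visits %s", min(x$patches$phi),
                max(x$patches$phi),
                paste(unique(x$patches$visits), collapse = "/")))
  else
    cat(sprintf("; ap %d-%d plots of tp %d-%d", min(x$patches$ap),
                max(x$patches$ap), min(x$patches$tp), max(x$patches$tp)))
  cat("\n")
  if (any(x$species$augmented))
    cat(sprintf("  %d detected + %d augmented all-zero species\n",
                sum(!x$species$augmented), sum(x$species$augmented)))
  if (any(!is.na(x$species$group)))
    cat("  groups:", paste(sort(unique(stats::na.omit(x$species$group))),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Load a survey dataset from CSV files
#'
#' Reads the patch and observation tables (and optionally a species-group
#' table) written in the package's CSV layout and returns a validated
#' [community_data()] object.  Expected columns: `patches.csv`: `patch_id`,
#' `area_ha`, `phi`, `ap`, `tp`, `visits` (columns unused by the mode may be
#' absent or blank); observations: `species_id`, `patch_id`, `H`, `count`
#' (abundance) or `species_id`, `patch_id`, `y` (frequency); groups:
#' `species_id`, `group`.
#'
#' @param patch_csv,observations_csv,groups_csv file paths; `groups_csv` may
#'   be `NULL`.
#' @inheritParams community_data
#' @return A `comm_data` object.
#' @export
load_dataset <- function(patch_csv, observations_csv,
                         mode = c("abundance", "frequency"),
                         groups_csv = NULL, plot_area_m2 = 1) {
  mode <- match.arg(mode)
  for (f in c(patch_csv, observations_csv, groups_csv))
    if (!file.exists(f)) stop_invalid("missing_file", "file not found: %s", f)
  patches <- utils::read.csv(patch_csv, stringsAsFactors = FALSE)
  observations <- utils::read.csv(observations_csv, stringsAsFactors = FALSE)
  groups <- if (!is.null(groups_csv))
    utils::read.csv(groups_csv, stringsAsFactors = FALSE)
  community_data(patches, observations, mode = mode, groups = groups,
                 plot_area_m2 = plot_area_m2)
}

#' Write a survey dataset to CSV files
#'
#' Writes `patches.csv`, `encounters.csv` or `plot_occ.csv`, optionally
#' `groups.csv`, and a key-value `run_metadata.txt` recording the mode, table
#' sizes and any extra metadata (e.g. simulation seeds).  The files round-trip
#' exactly through [load_dataset()].
#'
#' @param data a `comm_data` object.
#' @param dir output directory (created if needed).
#' @param metadata named list of extra key-value pairs for the metadata file.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(data, dir, metadata = list()) {
  stopifnot(inherits(data, "comm_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs_name <- if (data$mode == "abundance") "encounters.csv" else "plot_occ.csv"
  paths <- c(patches = file.path(dir, "patches.csv"),
             observations = file.path(dir, obs_name))
  utils::write.csv(data$patches, paths[["patches"]], row.names = FALSE)
  utils::write.csv(data$obs, paths[["observations"]], row.names = FALSE)
  if (any(!is.na(data$species$group))) {
    paths[["groups"]] <- file.path(dir, "groups.csv")
    grp <- data$species[!is.na(data$species$group), c("species_id", "group")]
    utils::write.csv(grp, paths[["groups"]], row.names = FALSE)
  }
  meta <- c(list(mode = data$mode,
                 n_species = nrow(data$species),
                 n_patches = nrow(data$patches),
                 n_augmented = sum(data$species$augmented),
                 plot_area_m2 = data$plot_area_m2),
            metadata)
  paths[["metadata"]] <- file.path(dir, "run_metadata.txt")
  writeLines(paste(names(meta), vapply(meta, format, ""), sep = "\t"),
             paths[["metadata"]])
  invisible(paths)
}

#' Number of plots tessellating a patch
#'
#' A patch of `area_ha` hectares divided into equal plots of `plot_area_m2`
#' square metres contains `tp = round(10000 * area_ha / plot_area_m2)` plots;
#' with 1-m^2 plots, `tp = 10000 * area_ha`.  The count of unsurveyed plots is
#' then `tp - ap`.
#'
#' @param area_ha patch area in hectares (vectorized).
#' @param plot_area_m2 plot size in square metres.
#' @return Integer vector of total plot counts.
#' @examples
#' total_plots(1)             # 10000
#' total_plots(1) - 16        # 9984 unsurveyed plots with ap = 16
#' @export
total_plots <- function(area_ha, plot_area_m2 = 1) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0))
    stop_invalid("area", "area_ha must be positive")
  if (!is.numeric(plot_area_m2) || length(plot_area_m2) != 1L || plot_area_m2 <= 0)
    stop_invalid("plot_area", "plot_area_m2 must be a positive scalar")
  as.integer(round(10000 * area_ha / plot_area_m2))
}

# ---- internal dense views -------------------------------------------------

# Encounter-frequency array y[S, J, T] and detections matrix n[S, J].
encounter_array <- function(data) {
  stopifnot(data$mode == "abundance")
  sp <- data$species$species_id
  pa <- data$patches$patch_id
  tmax <- max(data$patches$visits)
  y <- array(0L, c(length(sp), length(pa), tmax),
             dimnames = list(sp, pa, paste0("H", seq_len(tmax))))
  if (nrow(data$obs)) {
    i <- match(data$obs$species_id, sp)
    j <- match(data$obs$patch_id, pa)
    y[cbind(i, j, data$obs$H)] <- as.integer(data$obs$count)
  }
  list(y = y, n = apply(y, c(1, 2), sum), visits = data$patches$visits)
}

# Plot-occurrence matrix y[S, J].
occurrence_matrix <- function(data) {
  stopifnot(data$mode == "frequency")
  sp <- data$species$species_id
  pa <- data$patches$patch_id
  y <- matrix(0L, length(sp), length(pa), dimnames = list(sp, pa))
  if (nrow(data$obs)) {
    i <- match(data$obs$species_id, sp)
    j <- match(data$obs$patch_id, pa)
    y[cbind(i, j)] <- as.integer(data$obs$y)
  }
  y
}

# Logical: which species have at least one detection.
detected_species <- function(data) {
  if (data$mode == "abundance") rowSums(encounter_array(data)$n) > 0
  else rowSums(occurrence_matrix(data)) > 0
}
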