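SCHEMA_VERSION <- 1L

#' Write a trial to disk / read it back
#'
#' The canonical on-disk form of a trial is a directory of plain CSV files —
#' one per channel block (`forces_plate1.csv`, `forces_plate2.csv`,
#' `kinematics.csv`), each with a three-line commented header carrying the
#' schema version, the units and the sampling rate — plus a `meta.json`
#' sidecar with the trial metadata. Writing then reading reproduces all
#' channels to full stored precision and all metadata.
#'
#' @param trial A `gait_trial`.
#' @param dir Directory to write into (created if needed).
#' @return `write_trial()` returns the paths written, invisibly.
#'   `read_trial()` returns a `gait_trial` (without ground truth, which is
#'   never serialised: truth belongs to the generator, not to a recording).
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- as.list(trial$meta)
  paths <- character(0)
  for (pl in sort(unique(trial$forces$plate))) {
    block <- trial$forces[trial$forces$plate == pl,
                          c("time", "fx", "fy", "fz", "mx", "my", "mz")]
    path <- file.path(dir, sprintf("forces_plate%d.csv", pl))
    write_block(block, path, units = "time:s force:N moment:N.m",
                rate = meta$force_rate)
    paths <- c(paths, path)
  }
  kpath <- file.path(dir, "kinematics.csv")
  write_block(trial$kinematics, kpath, units = "time:s position:m",
              rate = meta$kin_rate)
  mpath <- file.path(dir, "meta.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, kpath, mpath))
}

write_block <- function(df, path, units, rate) {
  header <- c(
    sprintf("# gaitmos-trial schema %d", SCHEMA_VERSION),
    sprintf("# units: %s", units),
    sprintf("# sampling_rate_hz: %.10g", rate)
  )
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

read_block <- function(path) {
  head <- readLines(path, n = 3)
  if (!grepl("^# gaitmos-trial schema", head[1])) {
    stop("file ", path, " does not carry a gaitmos trial header",
         call. = FALSE)
  }
  rate <- as.numeric(sub("^# sampling_rate_hz: *", "", head[3]))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  check_finite(df, path)
  list(data = df, rate = rate)
}

check_finite <- function(df, path) {
  for (col in names(df)) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop("non-finite value in ", path, ", row ", bad[1], ", column '",
           col, "'", call. = FALSE)
    }
  }
  invisible(df)
}

#' @rdname write_trial
#' @param required_force_cols,required_kin_cols Mandatory column names for
#'   the force and kinematic blocks.
#' @export
read_trial <- function(dir,
                       required_force_cols = c("time", "fx", "fy", "fz",
                                               "mx", "my", "mz"),
                       required_kin_cols = c("time", "com_x", "com_y",
                                             "com_z", "heel_left_y",
                                             "heel_left_z", "heel_right_y",
                                             "heel_right_z")) {
  mpath <- file.path(dir, "meta.json")
  if (!file.exists(mpath)) stop("missing ", mpath, call. = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  # JSON null (serialised NA, e.g. an unset participant id) comes back NULL
  meta <- lapply(meta, function(x) if (is.null(x)) NA else x)
  meta <- tibble::as_tibble(meta)

  plate_paths <- Filter(file.exists, file.path(
    dir, sprintf("forces_plate%d.csv", 1:2)
  ))
  if (length(plate_paths) == 0) {
    stop("no force-plate files found in ", dir, call. = FALSE)
  }
  forces <- purrr::map_dfr(plate_paths, function(p) {
    blk <- read_block(p)
    missing <- setdiff(required_force_cols, names(blk$data))
    if (length(missing) > 0) {
      stop("file ", p, " is missing mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    pl <- as.integer(sub(".*forces_plate([0-9]+)\\.csv$", "\\1", p))
    dplyr::mutate(blk$data, plate = pl, .after = "time")
  })
  lens <- table(forces$plate)
  if (length(unique(lens)) > 1) {
    stop("force blocks have inconsistent lengths across plates",
         call. = FALSE)
  }
  meta$single_plate <- length(plate_paths) < 2

  kpath <- file.path(dir, "kinematics.csv")
  kin <- NULL
  if (file.exists(kpath)) {
    blk <- read_block(kpath)
    missing <- setdiff(required_kin_cols, names(blk$data))
    if (length(missing) > 0) {
      stop("file ", kpath, " is missing mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    kin <- blk$data
  }
  structure(list(meta = meta, forces = forces, kinematics = kin,
                 truth = NULL),
            class = "gait_trial")
}

#' Write a cohort to disk
#'
#' Writes each trial into its own subdirectory (via [write_trial()]) and a
#' tab-separated `manifest.tsv` (participant, group, condition, trial, mass,
#' height, seed, directory).
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), "trial_data" %in% names(cohort))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sub <- sprintf("%s_%s_t%02d", cohort$participant, cohort$condition,
                 cohort$trial)
  for (i in seq_len(nrow(cohort))) {
    write_trial(cohort$trial_data[[i]], file.path(dir, sub[i]))
  }
  manifest <- dplyr::mutate(
    dplyr::select(cohort, -"trial_data"), directory = sub
  )
  mpath <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, mpath)
  invisible(mpath)
}
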