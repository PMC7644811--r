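#' Trial metadata
#'
#' Participant and condition metadata carried with every trial. Locomotion is
#' coded W (walking) or R (running); environment O (overground) or T
#' (treadmill).
#'
#' @param participant_code participant identifier, e.g. "P0003".
#' @param sex "M" or "F" (or NA).
#' @param locomotion "W" or "R".
#' @param environment "O" or "T".
#' @param speed locomotion speed in m/s (> 0).
#' @param age,height,mass optional participant anthropometrics (years, cm, kg).
#' @return A `trial_meta` list.
#' @export
trial_meta <- function(participant_code = "P0000", sex = NA_character_,
                       locomotion = "W", environment = "O", speed = 1.4,
                       age = NA_real_, height = NA_real_, mass = NA_real_) {
  if (!locomotion %in% c("W", "R")) stop("locomotion must be 'W' or 'R'")
  if (!environment %in% c("O", "T")) stop("environment must be 'O' or 'T'")
  if (!is.na(sex) && !sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (speed <= 0) stop("speed must be positive")
  structure(list(participant_code = participant_code, sex = sex,
                 locomotion = locomotion, environment = environment,
                 speed = speed, age = age, height = height, mass = mass),
            class = "trial_meta")
}

#' Raw EMG recording container
#'
#' A 13-channel surface EMG recording in the canonical muscle order (see
#' \code{\link{muscle_labels}}).
#'
#' @param samples numeric matrix, 13 rows (muscles) x n samples.
#' @param fs sampling rate, Hz.
#' @param meta a \code{\link{trial_meta}}.
#' @param muscles muscle labels; must be a permutation of the canonical set.
#'   Rows are reordered to canonical order.
#' @return An `emg_recording` list with elements `muscles`, `samples`, `fs`,
#'   `meta`.
#' @export
emg_recording <- function(samples, fs, meta = trial_meta(),
                          muscles = muscle_labels()) {
  samples <- as.matrix(samples)
  if (nrow(samples) != 13L) stop("EMG recording must have exactly 13 channels")
  if (fs <= 0) stop("fs must be positive")
  canon <- muscle_labels()
  if (!setequal(muscles, canon)) {
    stop("muscle labels must be the canonical 13: ",
         paste(canon, collapse = ", "))
  }
  samples <- samples[match(canon, muscles), , drop = FALSE]
  rownames(samples) <- canon
  structure(list(muscles = canon, samples = samples, fs = fs, meta = meta),
            class = "emg_recording")
}

#' Gait-cycle event times
#'
#' Per-cycle touchdown times and stance durations, one row per gait cycle.
#'
#' @param touchdown strictly increasing touchdown times, seconds.
#' @param stance_duration per-cycle stance duration, seconds; each stance
#'   must be positive and shorter than its cycle (the gap to the next
#'   touchdown).
#' @return A `gait_cycle_times` data frame.
#' @export
gait_cycle_times <- function(touchdown, stance_duration) {
  if (length(touchdown) != length(stance_duration)) {
    stop("touchdown and stance_duration must have equal length")
  }
  if (any(diff(touchdown) <= 0)) stop("touchdown times must strictly increase")
  if (any(stance_duration <= 0)) stop("stance durations must be positive")
  n <- length(touchdown)
  if (n > 1 && any(stance_duration[-n] >= diff(touchdown))) {
    stop("stance duration must be shorter than the cycle duration")
  }
  structure(data.frame(touchdown = touchdown,
                       stance_duration = stance_duration),
            class = c("gait_cycle_times", "data.frame"))
}

#' Write a trial fixture to CSV (+ JSON sidecar)
#'
#' Writes the raw EMG as a wide CSV (first column `time` in seconds, then the
#' 13 muscle columns) and a JSON sidecar (`<path>.json`) holding the gait
#' events, metadata, and — for synthetic trials — the ground-truth parameters
#' and seed.
#'
#' @param trial an `emg_recording` or a `synthetic_trial` bundle.
#' @param path CSV file path.
#' @param events optional `gait_cycle_times` (taken from the bundle if given).
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, events = NULL) {
  if (inherits(trial, "synthetic_trial")) {
    rec <- trial$raw
    events <- trial$events
    truth <- list(seed = trial$seed, noise_sd = trial$noise_sd,
                  jitter_sd = trial$truth$jitter_sd,
                  widths = trial$truth$widths)
  } else {
    rec <- trial
    truth <- NULL
  }
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$samples)
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs, t(rec$samples))
  colnames(df) <- c("time", rec$muscles)
  # full double precision so fixtures round-trip bit-identically
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(meta = unclass(rec$meta), truth = truth)
  if (!is.null(events)) {
    sidecar$events <- list(touchdown = events$touchdown,
                           stance_duration = events$stance_duration)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trial fixture from CSV
#'
#' Reads a wide trial CSV written by \code{\link{write_trial_csv}} (or any
#' file with a `time` column and the 13 canonical muscle columns, in any
#' column order). The sampling rate is inferred from the time column, which
#' must be uniform to within 1 ppm. If a JSON sidecar exists, metadata and
#' events are restored from it.
#'
#' @param path CSV file path.
#' @return An `emg_recording`; if the sidecar carried events, they are
#'   attached as `attr(, "events")`.
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  canon <- muscle_labels()
  missing <- setdiff(canon, colnames(df))
  if (length(missing) > 0) {
    stop("missing muscle column(s): ", paste(missing, collapse = ", "))
  }
  if (!"time" %in% colnames(df)) stop("missing 'time' column")
  dt <- diff(df$time)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("non-uniform sampling in time column (beyond 1 ppm)")
  }
  fs <- 1 / mean(dt)
  meta <- trial_meta()
  events <- NULL
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$meta)) {
      keep <- !vapply(sc$meta, function(x)
        is.null(x) || (length(x) == 1 && is.na(x)), logical(1))
      meta <- do.call(trial_meta, sc$meta[keep])
    }
    if (!is.null(sc$events)) {
      events <- gait_cycle_times(sc$events$touchdown,
                                 sc$events$stance_duration)
    }
  }
  rec <- emg_recording(t(as.matrix(df[, canon])), fs = fs, meta = meta)
  if (!is.null(events)) attr(rec, "events") <- events
  rec
}

#' Parse a deposit trial key
#'
#' Trial keys follow the grammar `<PREFIX>_P####_<E><L>_##` where the
#' two-letter condition code is environment (O = overground, T = treadmill)
#' followed by locomotion (W = walking, R = running): e.g.
#' `CYCLE_TIMES_P0020_TW_01` is participant P0020, treadmill walking,
#' trial 01.
#'
#' @param key trial key string.
#' @return List with `prefix`, `participant`, `environment`, `locomotion`,
#'   `trial`.
#' @export
parse_trial_key <- function(key) {
  m <- regmatches(key,
                  regexec("^([A-Za-z_ ]+?)_?\\s*(P\\d{4})_([OT])([WR])_(\\d+)$",
                          key))[[1]]
  if (length(m) == 0) stop("unparseable trial key: ", key)
  list(prefix = gsub("[ _]+$", "", m[2]), participant = m[3],
       environment = m[4], locomotion = m[5], trial = m[6])
}

#' Read a deposited dataset directory (optional)
#'
#' Loads `RAW_EMG.RData`, `CYCLE_TIMES.RData` and, when present,
#' `metadata.dat`/`metadata.RData` from a deposit directory, pairs EMG with
#' cycle times by trial key, and returns one entry per trial. Trials with
#' fewer than 30 cycles (some overground-running trials have 21-29) are
#' accepted. This reader is optional plumbing: the rest of the pipeline only
#' needs the in-memory containers.
#'
#' @param dir directory holding the deposit files.
#' @return A list of trials, each a list with `raw` (an `emg_recording`),
#'   `events` (a `gait_cycle_times`), `meta` (a `trial_meta`) and `key`.
#' @export
read_deposit <- function(dir) {
  raw_file <- file.path(dir, "RAW_EMG.RData")
  cyc_file <- file.path(dir, "CYCLE_TIMES.RData")
  if (!file.exists(raw_file) || !file.exists(cyc_file)) {
    stop("deposit directory must contain RAW_EMG.RData and CYCLE_TIMES.RData")
  }
  raw_env <- new.env(); load(raw_file, envir = raw_env)
  cyc_env <- new.env(); load(cyc_file, envir = cyc_env)
  raw_list <- get(ls(raw_env)[1], envir = raw_env)
  cyc_list <- get(ls(cyc_env)[1], envir = cyc_env)

  meta_df <- NULL
  for (mf in file.path(dir, c("metadata.RData", "metadata.dat"))) {
    if (file.exists(mf)) {
      if (grepl("RData$", mf)) {
        menv <- new.env(); load(mf, envir = menv)
        meta_df <- get(ls(menv)[1], envir = menv)
      } else {
        meta_df <- read.table(mf, header = TRUE, stringsAsFactors = FALSE)
      }
      break
    }
  }

  trials <- list()
  for (key in names(raw_list)) {
    info <- parse_trial_key(key)
    cyc_key <- names(cyc_list)[vapply(names(cyc_list), function(k) {
      ci <- parse_trial_key(k)
      identical(ci[c("participant", "environment", "locomotion", "trial")],
                info[c("participant", "environment", "locomotion", "trial")])
    }, logical(1))]
    if (length(cyc_key) != 1) {
      stop("no unique cycle-times entry for EMG trial ", key)
    }
    df <- as.data.frame(raw_list[[key]])
    fs <- 1 / mean(diff(df[[1]]))
    meta <- trial_meta(participant_code = info$participant,
                       locomotion = info$locomotion,
                       environment = info$environment,
                       speed = if (info$locomotion == "W") 1.4 else 2.8)
    if (!is.null(meta_df)) {
      row <- meta_df[meta_df$Code == info$participant &
                       meta_df$Locomotion == info$locomotion &
                       meta_df$Environment == info$environment, , drop = FALSE]
      if (nrow(row) >= 1) {
        meta <- trial_meta(participant_code = info$participant,
                           sex = as.character(row$Sex[1]),
                           locomotion = info$locomotion,
                           environment = info$environment,
                           speed = row$Speed[1], age = row$Age[1],
                           height = row$Height[1], mass = row$Mass[1])
      }
    }
    cyc <- as.data.frame(cyc_list[[cyc_key]])
    trials[[key]] <- list(
      raw = emg_recording(t(as.matrix(df[, -1])), fs = fs, meta = meta,
                          muscles = colnames(df)[-1]),
      events = gait_cycle_times(cyc[[1]], cyc[[2]]),
      meta = meta, key = key)
  }
  trials
}
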