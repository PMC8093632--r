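# File formats: long-format trial CSV, gantry CSV, image stacks (PNG),
# ground-truth JSON and YAML walker configs. All columns carry units in
# their names; frames are 0-based; times are seconds from trial start;
# angles are degrees.

#' Read and write trials in the long CSV format
#'
#' Columns: `time_s`, `frame` (0-based), `marker_id`, `x_mm`, `y_mm`.
#' Writing then reading a trial is value-identical; unknown extra columns
#' are preserved on read as the `extra` attribute.
#'
#' @param path CSV file path.
#' @param animal_id,cohort,frame_rate_hz Metadata (not stored in the CSV).
#' @return A `walker_trial`.
#' @export
read_trial <- function(path, animal_id = "A1", cohort = "unknown",
                       frame_rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "frame", "marker_id", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trial CSV is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$marker_id %in% marker_ids())
  if (length(bad) > 0)
    stop(sprintf("row %d: unknown marker_id '%s'", bad[1], df$marker_id[bad[1]]))
  frames <- sort(unique(df$frame))
  times <- vapply(frames, function(f) df$time_s[df$frame == f][1], numeric(1))
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1]
    stop(sprintf("non-monotonic time at frame %d", frames[i + 1]))
  }
  ids <- unique(df$marker_id)
  markers <- stats::setNames(lapply(ids, function(id) {
    sub <- df[df$marker_id == id, ]
    m <- matrix(NA_real_, length(frames), 2)
    ri <- match(sub$frame, frames)
    m[ri, 1] <- sub$x_mm
    m[ri, 2] <- sub$y_mm
    m
  }), ids)
  if (is.null(frame_rate_hz))
    frame_rate_hz <- if (length(times) > 1) 1 / stats::median(diff(times)) else 50
  tr <- walker_trial(times, markers, animal_id = animal_id, cohort = cohort,
                     frame_rate_hz = frame_rate_hz)
  extra <- setdiff(names(df), need)
  if (length(extra) > 0) attr(tr, "extra") <- df[, extra, drop = FALSE]
  tr
}

#' @rdname read_trial
#' @param trial A `walker_trial`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "walker_trial"))
  n <- length(trial$times_s)
  rows <- do.call(rbind, lapply(names(trial$markers), function(id)
    data.frame(time_s = trial$times_s, frame = seq_len(n) - 1L,
               marker_id = id,
               x_mm = trial$markers[[id]][, 1],
               y_mm = trial$markers[[id]][, 2])))
  rows <- rows[order(rows$frame, match(rows$marker_id, marker_ids())), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read a gantry stream CSV
#'
#' Columns: `frame` (0-based), `cam_x_mm`, `cam_y_mm`.
#'
#' @param gantry Data frame as produced by [render_frames()].
#' @param path CSV path.
#' @export
write_gantry <- function(gantry, path) {
  utils::write.csv(gantry[, c("frame", "cam_x_mm", "cam_y_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gantry
#' @export
read_gantry <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "cam_x_mm", "cam_y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gantry CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write/read an image stack as numbered 8-bit grayscale PNGs
#'
#' Frames are written as `frame_000000.png`, `frame_000001.png`, ... in
#' `dir` (lossless, 8-bit grayscale).
#'
#' @param frames List of integer matrices (0-255).
#' @param dir Output directory (created if needed).
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
}

#' Write/read ground truth as JSON
#'
#' @param truth A `ground_truth` from [simulate_trial()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$pose <- as.data.frame(gt$pose)
  structure(gt, class = "ground_truth")
}

#' Read/write a walker configuration as YAML
#'
#' The YAML mirrors the flat key-value form accepted by
#' [build_walker_config()].
#'
#' @param path YAML path.
#' @return A validated `walker_config`.
#' @export
read_walker_config <- function(path) {
  build_walker_config(yaml::read_yaml(path))
}

#' @rdname read_walker_config
#' @param config A `walker_config`.
#' @export
write_walker_config <- function(config, path) {
  stopifnot(inherits(config, "walker_config"))
  raw <- list(
    legs = lapply(config$legs, function(l) l[setdiff(names(l), "leg_id")]),
    edges = lapply(unname(config$edges), function(e)
      e[c("sender", "receiver", "rule2_strength", "rule2_latency_s",
          "rule1_enabled")]),
    lesion = list(site = config$lesion$site,
                  severed_edges = as.list(config$lesion$severed_edges)),
    body = list(thoracic_marker_offsets = config$body$thoracic_marker_offsets,
                coxa_offsets = config$body$coxa_offsets,
                femur_length_mm = config$body$femur_length_mm),
    vx_mm_s = config$vx_mm_s, vy_mm_s = config$vy_mm_s,
    yaw_deg_s = config$yaw_deg_s, frame_rate_hz = config$frame_rate_hz)
  if (!is.null(config$seed)) raw$seed <- config$seed
  yaml::write_yaml(raw, path)
  invisible(path)
}
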