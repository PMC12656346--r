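#' Read a pose-keypoint sequence from disk
#'
#' Two on-disk dialects are supported:
#'
#' * `"csv"`: one row per frame, mandatory header with columns
#'   `frame, time_s, <joint>_x, <joint>_y` and optional `<joint>_conf`
#'   columns. An optional leading comment line
#'   `# dmsm fps=30 units=pixels handedness=right clip_id=... player_id=...`
#'   carries clip metadata; without it, fps is inferred from the median
#'   inter-frame interval and defaults are used.
#' * `"landmark_records"`: newline-delimited JSON. The first line is a header
#'   object declaring `width`, `height`, `fps` and clip metadata; each later
#'   line holds one frame: a `time` and a `landmarks` array of 33
#'   `[x, y]` or `[x, y, conf]` triples in BlazePose order, image-normalized
#'   to \[0, 1\]. On read, coordinates are converted to pixels using the
#'   declared frame size.
#'
#' Small per-frame joint dropouts (`NA` cells, or landmark records with
#' missing values) are filled by linear interpolation from neighboring frames
#' when the gap is at most `max_gap` frames; longer gaps are an error.
#'
#' @param path file to read.
#' @param format `"csv"` or `"landmark_records"`.
#' @param clip_id,player_id,handedness,fps metadata overrides; when `NULL`,
#'   taken from the file header (or defaulted).
#' @param max_gap longest joint dropout (in frames) filled by interpolation.
#' @return A validated [pose_sequence()] in pixel units (or in the units the
#'   file declares, for round-tripped body-scale files).
#' @export
read_pose_sequence <- function(path, format = c("csv", "landmark_records"),
                               clip_id = NULL, player_id = NULL,
                               handedness = NULL, fps = NULL,
                               max_gap = 3L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    read_pose_csv(path, clip_id, player_id, handedness, fps, max_gap)
  } else {
    read_landmark_records(path, clip_id, player_id, handedness, fps, max_gap)
  }
}

read_pose_csv <- function(path, clip_id, player_id, handedness, fps, max_gap) {
  first <- readLines(path, n = 1L)
  meta <- list()
  if (length(first) && startsWith(first, "#"))
    meta <- parse_meta_comment(first)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) stop("cannot parse CSV: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L)
    stop("empty pose file (no data rows): ", path, call. = FALSE)
  if (!all(c("frame", "time_s") %in% names(df)))
    stop("CSV must have 'frame' and 'time_s' columns", call. = FALSE)
  xcols <- grep("_x$", names(df), value = TRUE)
  joints <- sub("_x$", "", xcols)
  for (j in required_joints) {
    if (!all(paste0(j, c("_x", "_y")) %in% names(df)))
      stop("format error: missing required joint '", j, "' column(s)",
           call. = FALSE)
  }
  joints <- joints[paste0(joints, "_y") %in% names(df)]
  tm <- as.numeric(df$time_s)
  if (any(!is.finite(tm)) || any(diff(tm) <= 0))
    stop("validation error: timestamps must be finite and strictly increasing",
         call. = FALSE)
  x <- sapply(joints, function(j) fill_gaps(as.numeric(df[[paste0(j, "_x")]]),
                                            max_gap, j))
  y <- sapply(joints, function(j) fill_gaps(as.numeric(df[[paste0(j, "_y")]]),
                                            max_gap, j))
  x <- matrix(x, nrow = nrow(df), dimnames = list(NULL, joints))
  y <- matrix(y, nrow = nrow(df), dimnames = list(NULL, joints))
  conf_cols <- paste0(joints, "_conf")
  conf <- NULL
  if (any(conf_cols %in% names(df))) {
    conf <- matrix(NA_real_, nrow(df), length(joints),
                   dimnames = list(NULL, joints))
    for (k in seq_along(joints))
      if (conf_cols[k] %in% names(df))
        conf[, k] <- as.numeric(df[[conf_cols[k]]])
  }
  fps <- fps %||% meta$fps %||% (1 / stats::median(diff(tm)))
  pose_sequence(
    time = tm, x = x, y = y, fps = as.numeric(fps),
    units = meta$units %||% "pixels",
    handedness = handedness %||% meta$handedness %||% "right",
    clip_id = clip_id %||% meta$clip_id %||%
      tools::file_path_sans_ext(basename(path)),
    player_id = player_id %||% meta$player_id %||% "unknown",
    conf = conf)
}

read_landmark_records <- function(path, clip_id, player_id, handedness, fps,
                                  max_gap) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("validation error: landmark file needs a header and >= 1 frame",
         call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  if (is.null(hdr$width) || is.null(hdr$height))
    stop("landmark header must declare frame width and height", call. = FALSE)
  frames <- lapply(lines[-1], jsonlite::fromJSON)
  tm <- vapply(frames, function(f) as.numeric(f$time), numeric(1))
  if (any(diff(tm) <= 0))
    stop("validation error: timestamps must be strictly increasing",
         call. = FALSE)
  n <- length(frames)
  J <- length(blazepose_landmarks)
  x <- matrix(NA_real_, n, J, dimnames = list(NULL, blazepose_landmarks))
  y <- x
  conf <- x
  has_conf <- FALSE
  for (i in seq_len(n)) {
    lm <- frames[[i]]$landmarks
    lm <- if (is.matrix(lm)) lm else do.call(rbind, lm)
    if (nrow(lm) != J)
      stop("frame ", i, " has ", nrow(lm), " landmarks; expected ", J,
           call. = FALSE)
    x[i, ] <- lm[, 1] * hdr$width
    y[i, ] <- lm[, 2] * hdr$height
    if (ncol(lm) >= 3) { conf[i, ] <- lm[, 3]; has_conf <- TRUE }
  }
  for (j in seq_len(J)) {
    x[, j] <- fill_gaps(x[, j], max_gap, blazepose_landmarks[j])
    y[, j] <- fill_gaps(y[, j], max_gap, blazepose_landmarks[j])
  }
  pose_sequence(
    time = tm, x = x, y = y,
    fps = as.numeric(fps %||% hdr$fps %||% (1 / stats::median(diff(tm)))),
    units = "pixels",
    handedness = handedness %||% hdr$handedness %||% "right",
    clip_id = clip_id %||% hdr$clip_id %||%
      tools::file_path_sans_ext(basename(path)),
    player_id = player_id %||% hdr$player_id %||% "unknown",
    conf = if (has_conf) conf else NULL)
}

#' Write a pose sequence to disk
#'
#' Inverse of [read_pose_sequence()]; `read(write(seq))` reproduces times and
#' coordinates within 1e-9 and preserves the units, handedness and id
#' metadata (via the comment/header line of the respective dialect).
#'
#' @param seq a valid [pose_sequence()].
#' @param path output file.
#' @param format `"csv"` or `"landmark_records"`.
#' @param width,height declared frame size for the landmark-record dialect
#'   (used to image-normalize pixel coordinates).
#' @return `path`, invisibly.
#' @export
write_pose_sequence <- function(seq, path, format = c("csv", "landmark_records"),
                                width = 960, height = 540) {
  format <- match.arg(format)
  validate_pose_sequence(seq)
  if (format == "csv") {
    meta <- sprintf("# dmsm fps=%.10g units=%s handedness=%s clip_id=%s player_id=%s",
                    seq$fps, seq$units, seq$handedness, seq$clip_id,
                    seq$player_id)
    joints <- colnames(seq$x)
    df <- data.frame(frame = seq_along(seq$time) - 1L,
                     time_s = seq$time, check.names = FALSE)
    for (j in joints) {
      df[[paste0(j, "_x")]] <- seq$x[, j]
      df[[paste0(j, "_y")]] <- seq$y[, j]
      if (!is.null(seq$conf)) df[[paste0(j, "_conf")]] <- seq$conf[, j]
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    utils::write.csv(format_df_full(df), con, row.names = FALSE, quote = FALSE)
  } else {
    if (seq$units != "pixels")
      stop("landmark records store image-normalized pixels; normalize-on-read ",
           "sequences cannot round-trip through this dialect", call. = FALSE)
    if (!all(blazepose_landmarks %in% colnames(seq$x)))
      stop("landmark-record dialect requires the full 33-landmark set",
           call. = FALSE)
    hdr <- jsonlite::toJSON(list(
      format = "blazepose_landmarks", width = width, height = height,
      fps = seq$fps, clip_id = seq$clip_id, player_id = seq$player_id,
      handedness = seq$handedness), auto_unbox = TRUE, digits = NA)
    lines <- vapply(seq_along(seq$time), function(i) {
      lm <- cbind(seq$x[i, blazepose_landmarks] / width,
                  seq$y[i, blazepose_landmarks] / height)
      if (!is.null(seq$conf)) lm <- cbind(lm, seq$conf[i, blazepose_landmarks])
      dimnames(lm) <- NULL
      jsonlite::toJSON(list(time = seq$time[i], landmarks = lm),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}

# write.csv via format() so full precision survives the text round trip
format_df_full <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.12g", col) else col)
  df
}

#' Read a clip manifest
#'
#' A manifest is a tab-separated table with header columns
#' `clip_id, player_id, path, handedness, fps, level` — one record per clip,
#' mirroring a dataset-composition table. Relative paths are resolved against
#' the manifest's own directory.
#'
#' @param path manifest file.
#' @param check_paths verify every referenced clip file exists (default TRUE).
#' @return A `data.frame` of class `clip_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("clip_id", "player_id", "path", "handedness", "fps", "level")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$clip_id))
    stop("validation error: duplicate clip_id in manifest: ",
         paste(unique(df$clip_id[duplicated(df$clip_id)]), collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    bad_level <- setdiff(unique(df$level), c("amateur", "professional"))
    if (length(bad_level))
      stop("validation error: unknown level value(s): ",
           paste(bad_level, collapse = ", "), call. = FALSE)
    bad_hand <- setdiff(unique(df$handedness), c("right", "left"))
    if (length(bad_hand))
      stop("validation error: unknown handedness value(s): ",
           paste(bad_hand, collapse = ", "), call. = FALSE)
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
    if (check_paths) {
      gone <- df$path[!file.exists(df$path)]
      if (length(gone))
        stop("validation error: unresolvable clip path(s): ",
             paste(gone, collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("clip_manifest", "data.frame")
  df
}

#' Write a clip manifest
#'
#' @param manifest a `clip_manifest` (or plain data.frame with the manifest
#'   columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- helpers -----------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_meta_comment <- function(line) {
  toks <- strsplit(sub("^#\\s*dmsm\\s*", "", line), "\\s+")[[1]]
  kv <- strsplit(toks[grepl("=", toks)], "=", fixed = TRUE)
  out <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  if (!is.null(out$fps)) out$fps <- as.numeric(out$fps)
  out
}

# Fill NA dropouts of length <= max_gap by linear interpolation (nearest
# value at the clip edges); longer gaps are a hard error.
fill_gaps <- function(v, max_gap, joint) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  if (any(r$lengths[r$values] > max_gap))
    stop("joint '", joint, "' has a dropout gap longer than ", max_gap,
         " frames", call. = FALSE)
  if (all(is.na(v)))
    stop("joint '", joint, "' has no observed values", call. = FALSE)
  idx <- which(!is.na(v))
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}
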