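#' Write a session to a directory
#'
#' Emits the on-disk session layout: `scene/NNNNNN.pgm` and
#' `eyes/NNNNNN.pgm` 8-bit frame sequences, `livedata.json` with one JSON
#' record per line (mimicking the vendor stream: `ts` in integer
#' microseconds plus one of `vts`, `evts`, `gp`, `gp3`, `pd`+`eye`, `ac`,
#' `gy`), and `meta.json` with the camera model and task metadata. Floats
#' are serialized at full precision so a save/load round trip is lossless.
#'
#' @param session a `session_bundle`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "scene"), showWarnings = FALSE)
  dir.create(file.path(path, "eyes"), showWarnings = FALSE)
  ns <- dim(session$scene_frames)[3]
  for (i in seq_len(ns))
    write_pgm(session$scene_frames[, , i],
              file.path(path, "scene", sprintf("%06d.pgm", i)))
  ne <- dim(session$eye_frames)[3]
  for (i in seq_len(ne))
    write_pgm(session$eye_frames[, , i],
              file.path(path, "eyes", sprintf("%06d.pgm", i)))

  us <- function(t) sprintf("%.0f", round(t * 1e6))
  num <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "null"
    out
  }
  vec <- function(m) apply(matrix(num(m), nrow = nrow(m)), 1,
                           function(r) paste0("[", paste(r, collapse = ","), "]"))
  lines <- character(0)
  # video/eye-video time sync records, one per second
  st <- scene_frame_times(session)
  sync <- st[st %% 1 == 0]
  lines <- c(lines, sprintf('{"ts":%s,"vts":%s}', us(sync), us(sync)))
  et <- eye_frame_times(session)
  esync <- et[et %% 1 == 0]
  lines <- c(lines, sprintf('{"ts":%s,"evts":%s}', us(esync), us(esync)))
  g <- session$gaze
  sflag <- ifelse(g$validity, 0L, 1L)
  lines <- c(lines,
    sprintf('{"ts":%s,"gp":%s,"s":%d}', us(g$t), vec(g$gp), sflag),
    sprintf('{"ts":%s,"gp3":%s,"s":%d}', us(g$t), vec(g$gp3), sflag),
    sprintf('{"ts":%s,"pd":%s,"eye":"left","s":%d}', us(g$t), num(g$pd_left), sflag),
    sprintf('{"ts":%s,"pd":%s,"eye":"right","s":%d}', us(g$t), num(g$pd_right), sflag))
  m <- session$imu
  lines <- c(lines,
    sprintf('{"ts":%s,"ac":%s}', us(m$t), vec(m$ac)),
    sprintf('{"ts":%s,"gy":%s}', us(m$t), vec(m$gy)))
  writeLines(lines, file.path(path, "livedata.json"))

  cam <- session$camera
  meta <- list(camera = list(scene_fov_deg = cam$scene_fov_deg,
                             scene_resolution_px = cam$scene_resolution_px,
                             scene_rate_hz = cam$scene_rate_hz,
                             eye_resolution_px = cam$eye_resolution_px,
                             eye_rate_hz = cam$eye_rate_hz,
                             imu_rate_hz = cam$imu_rate_hz),
               task_label = session$task_label,
               duration_s = session$duration_s)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Load a session from a directory
#'
#' Reads the layout written by [save_session()]. All streams are
#' re-expressed on a common clock with origin at the first scene frame.
#' Invalid gaze samples (status flag non-zero) are flagged, not dropped.
#' A missing stream is a hard error naming the stream; non-monotone
#' timestamps raise an error with the first offending index.
#'
#' @param path session directory.
#' @return A `session_bundle`.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop("session directory not found: ", path)
  live <- file.path(path, "livedata.json")
  if (!file.exists(live)) stop("stream file livedata.json missing")
  meta_path <- file.path(path, "meta.json")
  cam_args <- list()
  task_label <- ""; duration_s <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(readLines(meta_path, warn = FALSE))
    if (!is.null(meta$camera)) cam_args <- meta$camera
    if (!is.null(meta$task_label)) task_label <- meta$task_label
    if (!is.null(meta$duration_s)) duration_s <- meta$duration_s
  }
  camera <- do.call(camera_model, cam_args)

  scene_frames <- read_frame_dir(file.path(path, "scene"), "scene")
  eye_frames <- read_frame_dir(file.path(path, "eyes"), "eye video")

  lines <- readLines(live, warn = FALSE)
  pick <- function(key) {
    sub <- lines[grepl(paste0('"', key, '"'), lines, fixed = TRUE)]
    if (!length(sub)) return(NULL)
    jsonlite::fromJSON(paste0("[", paste(sub, collapse = ","), "]"))
  }
  gp <- pick("gp"); gp3 <- pick("gp3"); pd <- pick("pd")
  ac <- pick("ac"); gy <- pick("gy")
  if (is.null(gp) || is.null(gp3)) stop("gaze stream missing")
  if (is.null(ac) || is.null(gy)) stop("imu stream missing")

  t_gaze <- gp$ts / 1e6
  validity <- if (!is.null(gp$s)) gp$s == 0 else rep(TRUE, nrow(gp))
  gp_m <- as_rec_matrix(gp$gp, 2)
  if (!isTRUE(all.equal(gp3$ts, gp$ts)))
    stop("gp3 records do not align with gp records")
  gp3_m <- as_rec_matrix(gp3$gp3, 3)
  pd_left <- pd_right <- rep(NA_real_, length(t_gaze))
  if (!is.null(pd)) {
    for (side in c("left", "right")) {
      sel <- pd[pd$eye == side, , drop = FALSE]
      if (nrow(sel)) {
        idx <- align_nearest(sel$ts / 1e6, t_gaze)
        v <- rep(NA_real_, length(t_gaze)); v[idx] <- sel$pd
        if (side == "left") pd_left <- v else pd_right <- v
      }
    }
  }
  gaze <- gaze_stream(t_gaze, gp_m, gp3_m, pd_left, pd_right, validity)
  if (!isTRUE(all.equal(ac$ts, gy$ts))) stop("ac/gy records do not align")
  imu <- imu_stream(ac$ts / 1e6, as_rec_matrix(ac$ac, 3), as_rec_matrix(gy$gy, 3))

  session_bundle(camera, scene_frames, eye_frames, gaze, imu,
                 task_label = task_label, duration_s = duration_s)
}

as_rec_matrix <- function(col, width) {
  if (is.matrix(col)) return(col)
  m <- do.call(rbind, lapply(col, function(x) as.numeric(x)))
  if (ncol(m) != width) stop("malformed stream record (expected width ", width, ")")
  m
}

read_frame_dir <- function(dir, what) {
  if (!dir.exists(dir)) stop(what, " stream missing")
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stop(what, " stream missing")
  first <- read_pgm(files[1])
  out <- array(as.raw(0), c(nrow(first), ncol(first), length(files)))
  out[, , 1] <- first
  for (i in seq_along(files)[-1]) out[, , i] <- read_pgm(files[i])
  out
}
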