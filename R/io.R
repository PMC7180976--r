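#' Read and write 9-DoF sensor logs
#'
#' Sensor logs are CSV files with header `t, gx, gy, gz, ax, ay, az, mx,
#' my, mz` in s, rad/s, m/s^2 and gauss, preceded by comment lines starting
#' with `#`. A `# units:` comment may declare `gyro=deg/s` or `accel=g`,
#' in which case readings are converted on read. Readings outside the
#' plausible dynamic range of wearable nodes (|gyro| > 1200 deg/s,
#' |accel| > 18 g, |mag| > 1.9 gauss) raise warnings.
#'
#' @param path CSV file path.
#' @return `read_sensor_log`: a tibble with the ten columns above (SI
#'   units) and strictly increasing `t`.
#' @export
read_sensor_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 20)
  units <- grep("^#\\s*units:", hdr, value = TRUE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  if (!all(need %in% names(df)))
    stop("sensor log must have columns: ", paste(need, collapse = ", "))
  df <- tibble::as_tibble(df[, need])
  if (any(!stats::complete.cases(df))) {
    bad <- which(!stats::complete.cases(df))[1]
    stop("malformed sensor log row at data line ", bad, " of ", path)
  }
  if (any(diff(df$t) <= 0)) stop("non-monotone timestamps in ", path)
  if (length(units)) {
    if (grepl("gyro=deg/s", units[1]))
      df[, c("gx", "gy", "gz")] <- df[, c("gx", "gy", "gz")] * pi / 180
    if (grepl("accel=g\\b", units[1]))
      df[, c("ax", "ay", "az")] <- df[, c("ax", "ay", "az")] * 9.81
  }
  if (max(abs(as.matrix(df[, c("gx", "gy", "gz")]))) > 1200 * pi / 180)
    warning("gyroscope readings exceed the plausible +/-1200 deg/s range")
  if (max(abs(as.matrix(df[, c("ax", "ay", "az")]))) > 18 * 9.81)
    warning("accelerometer readings exceed the plausible +/-18 g range")
  if (max(abs(as.matrix(df[, c("mx", "my", "mz")]))) > 1.9)
    warning("magnetometer readings exceed the plausible +/-1.9 gauss range")
  df
}

#' @rdname read_sensor_log
#' @param stream IMU stream tibble.
#' @param node Node identifier recorded in the header comment.
#' @export
write_sensor_log <- function(stream, path, node = "node") {
  cat(paste0("# node: ", node, "\n",
             "# units: gyro=rad/s accel=m/s2 mag=gauss\n"),
      file = path)
  cat(readr::format_csv(stream), file = path, append = TRUE)
  invisible(path)
}

# intrinsic Z-X-Y Euler angles (degrees) of a unit quaternion, BVH order
quat_to_euler_zxy <- function(q) {
  R <- quat_to_dcm(q)
  sx <- max(-1, min(1, R[3, 2]))
  x <- asin(sx)
  if (abs(sx) < 1 - 1e-9) {
    z <- atan2(-R[1, 2], R[2, 2])
    y <- atan2(-R[3, 1], R[3, 3])
  } else {  # gimbal: fold yaw into z
    z <- atan2(R[2, 1], R[1, 1])
    y <- 0
  }
  c(z, x, y) * 180 / pi
}

#' Export reconstructed motion as a BVH file
#'
#' Writes the body-model tree as a BVH (Biovision Hierarchy) skeleton and
#' one motion line per pose. Joints are named after the segment they
#' drive; offsets are rest-pose translations in meters. The native ground
#' frame is Z-up (ENU); `y_up = TRUE` rotates the export into the
#' conventional BVH Y-up frame.
#'
#' @param model A [body_model()].
#' @param poses List of per-frame orientation sets: each element a named
#'   list of unit quaternions (`q_B^G` per segment, missing segments
#'   inherit ancestors), or a `pose` tibble from [forward_kinematics()].
#' @param path Output file.
#' @param frame_time Seconds per frame.
#' @param y_up Rotate the export to Y-up (default `FALSE`, keep Z-up).
#' @return `path`, invisibly.
#' @export
write_bvh <- function(model, poses, path, frame_time = 0.01, y_up = FALSE) {
  stopifnot(length(poses) >= 1)
  pose_quats <- function(p) {
    if (is.data.frame(p)) {
      qs <- lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, quat_cols]))
      names(qs) <- p$segment
      qs
    } else p
  }
  conv <- if (y_up) quat_from_axis_angle(c(1, 0, 0), -pi / 2) else c(1, 0, 0, 0)
  cv <- function(v) rotate_vector(conv, v)

  kids <- function(s) model$segment[!is.na(model$parent) & model$parent == s]
  root <- model$segment[is.na(model$parent)]
  joint_order <- character(0)

  offset_of <- function(s) {
    row <- model[model$segment == s, ]
    if (is.na(row$parent)) return(c(0, 0, 0))
    pr <- model[model$segment == row$parent, ]
    if (identical(row$attach, "proximal")) c(0, 0, 0)
    else pr$length * c(pr$rest_x, pr$rest_y, pr$rest_z)
  }
  lines <- c("HIERARCHY")
  emit <- function(s, depth) {
    ind <- strrep("  ", depth)
    off <- cv(offset_of(s))
    if (depth == 0) {
      lines <<- c(lines, paste0("ROOT ", s), "{")
      lines <<- c(lines, paste0("  OFFSET 0 0 0"),
                  "  CHANNELS 6 Xposition Yposition Zposition Zrotation Xrotation Yrotation")
    } else {
      lines <<- c(lines, paste0(ind, "JOINT ", s), paste0(ind, "{"))
      lines <<- c(lines,
                  paste0(ind, "  OFFSET ", paste(format(off, trim = TRUE), collapse = " ")),
                  paste0(ind, "  CHANNELS 3 Zrotation Xrotation Yrotation"))
    }
    joint_order <<- c(joint_order, s)
    ch <- kids(s)
    if (length(ch)) {
      for (k in ch) emit(k, depth + 1)
    } else {
      row <- model[model$segment == s, ]
      tip <- cv(row$length * c(row$rest_x, row$rest_y, row$rest_z))
      lines <<- c(lines, paste0(ind, "  End Site"), paste0(ind, "  {"),
                  paste0(ind, "    OFFSET ", paste(format(tip, trim = TRUE), collapse = " ")),
                  paste0(ind, "  }"))
    }
    lines <<- c(lines, paste0(ind, "}"))
  }
  emit(root, 0)

  motion <- vapply(poses, function(p) {
    qs <- pose_quats(p)
    # resolve inheritance and convert to local rotations in writer order
    glob <- list()
    vals <- c(0, 0, 0)  # root position at origin
    for (s in joint_order) {
      parent <- model$parent[match(s, model$segment)]
      q <- qs[[s]]
      if (is.null(q)) q <- if (is.na(parent)) c(1, 0, 0, 0) else glob[[parent]]
      glob[[s]] <- q
      qg <- quat_multiply(conv, q)
      local <- if (is.na(parent)) qg
               else quat_multiply(quat_conjugate(quat_multiply(conv, glob[[parent]])), qg)
      vals <- c(vals, quat_to_euler_zxy(quat_normalize(local)))
    }
    paste(format(vals, trim = TRUE, digits = 8), collapse = " ")
  }, character(1))

  lines <- c(lines, "MOTION", paste0("Frames: ", length(poses)),
             paste0("Frame Time: ", format(frame_time, digits = 10)), motion)
  writeLines(lines, path)
  invisible(path)
}

#' Parse a BVH skeleton
#'
#' Minimal reader for round-trip checks: recovers the joint hierarchy with
#' offsets, the frame count and frame time.
#'
#' @param path BVH file.
#' @return List with `joints` (tibble `joint, parent, ox, oy, oz`),
#'   `n_frames`, `frame_time`, `motion` (numeric matrix).
#' @export
read_bvh <- function(path) {
  txt <- readLines(path)
  toks <- strsplit(trimws(txt), "\\s+")
  joints <- list(); stack <- character(0); cur <- NULL
  i <- 1
  while (i <= length(toks) && toks[[i]][1] != "MOTION") {
    tk <- toks[[i]]
    if (tk[1] %in% c("ROOT", "JOINT")) {
      parent <- if (length(stack)) stack[length(stack)] else NA_character_
      cur <- tk[2]
      joints[[cur]] <- list(joint = cur, parent = parent,
                            ox = NA_real_, oy = NA_real_, oz = NA_real_)
      stack <- c(stack, cur)
    } else if (tk[1] == "End") {
      stack <- c(stack, paste0(stack[length(stack)], "_end"))
      cur <- NULL
    } else if (tk[1] == "OFFSET") {
      nm <- stack[length(stack)]
      if (!grepl("_end$", nm)) {
        joints[[nm]]$ox <- as.numeric(tk[2])
        joints[[nm]]$oy <- as.numeric(tk[3])
        joints[[nm]]$oz <- as.numeric(tk[4])
      }
    } else if (tk[1] == "}") {
      stack <- stack[-length(stack)]
    }
    i <- i + 1
  }
  n_frames <- frame_time <- NA_real_
  motion <- NULL
  if (i <= length(toks)) {
    n_frames <- as.numeric(toks[[i + 1]][2])
    frame_time <- as.numeric(toks[[i + 2]][3])
    rows <- toks[(i + 3):length(toks)]
    rows <- rows[vapply(rows, length, 0L) > 0]
    motion <- do.call(rbind, lapply(rows, as.numeric))
  }
  list(joints = dplyr::bind_rows(lapply(joints, tibble::as_tibble)),
       n_frames = n_frames, frame_time = frame_time, motion = motion)
}

#' Run the full capture-and-analysis pipeline
#'
#' Executes the processing chain on simulated or on-disk recordings:
#' simulate (optional) -> magnetometer calibration -> orientation fusion ->
#' static alignment -> joint angles -> stroke analytics -> per-stroke /
#' windowed features -> (optional) phase classification; every artifact is
#' written under `out_dir` together with a `manifest.json` recording the
#' package version, seeds, configuration and MD5 digests of all inputs and
#' outputs, so identical configurations reproduce identical artifacts.
#'
#' @param config Either a named list or the path of a JSON file. Recognised
#'   fields: `out_dir` (required), `seed`, `profile` (arguments of
#'   [rowing_profile()]), `height`, `xi`, `init_window`,
#'   `cycle_channel` (default `"SFl"`), `window_length`, `window_overlap`,
#'   `stages` (subset of `c("fuse", "strokes", "features", "classify",
#'   "bvh")`), `bvh_y_up`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("fuse", "strokes", "features", "classify")
  seed <- config$seed %||% 1L
  log_stage <- function(...) message("[rowimu] ", ...)

  prof_args <- config$profile %||% list()
  prof_args$seed <- prof_args$seed %||% seed
  profile <- do.call(rowing_profile, prof_args)
  model <- upper_body_model(config$height %||% 1.70)

  log_stage("simulate: ", profile$duration, " s at ", profile$sample_rate, " Hz")
  truth <- simulate_kinematics(profile, model)
  streams <- imu_from_motion(truth)
  artifacts <- character(0)
  for (s in names(streams)) {
    f <- file.path(out_dir, paste0("imu_", s, ".csv"))
    write_sensor_log(streams[[s]], f, node = s)
    artifacts <- c(artifacts, f)
  }
  readr::write_csv(truth$angles, file.path(out_dir, "angles_truth.csv"))
  artifacts <- c(artifacts, file.path(out_dir, "angles_truth.csv"))

  angles <- truth$angles
  if ("fuse" %in% stages) {
    log_stage("calibrate + fuse: ", length(streams), " nodes")
    init_window <- config$init_window %||% 2
    xi <- config$xi %||% 0.1
    cal <- fit_mag_calibration(simulate_mag_samples(profile, seed = seed + 99L))
    write_mag_calibration(cal, file.path(out_dir, "magcal.json"))
    artifacts <- c(artifacts, file.path(out_dir, "magcal.json"))
    orients <- lapply(streams, fuse_imu, cal = cal, xi = xi,
                      init_window = init_window)
    static <- lapply(orients, function(o) o[o$t <= init_window, ])
    calib <- calibrate_alignment(static, model)
    chmap <- default_channel_map()
    chmap <- chmap[chmap$proximal %in% model$segment &
                   chmap$distal %in% model$segment, ]
    angles <- compute_joint_angles(model, orients, calib, channels = chmap)
    readr::write_csv(angles, file.path(out_dir, "angles.csv"))
    artifacts <- c(artifacts, file.path(out_dir, "angles.csv"))
  }

  events <- NULL
  if ("strokes" %in% stages) {
    log_stage("strokes")
    events <- detect_cycles(angles, channel = config$cycle_channel %||% "SFl")
    sm <- stroke_metrics(events, phase_labels = truth$phase)
    cs <- cycle_statistics(angles[, intersect(names(angles),
                                              c("t", "SFl", "SFr", "EFl", "EFr"))],
                           events)
    jsonlite::write_json(list(
      period_mean = sm$period_mean, period_sd = sm$period_sd,
      stroke_rate = sm$stroke_rate, n_cycles = sm$n_cycles,
      propulsion_recovery_ratio = sm$ratio_mean,
      propulsion_recovery_ratio_sd = sm$ratio_sd,
      cycle_stats = cs$stats), file.path(out_dir, "strokes.json"),
      auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out_dir, "strokes.json"))
  }

  fm <- NULL
  if ("features" %in% stages) {
    log_stage("features")
    fm <- build_feature_matrix(angles, mode = "windows",
                               window_length = config$window_length %||% 10,
                               window_overlap = config$window_overlap %||% 5,
                               sample_rate = profile$sample_rate)
    readr::write_csv(fm, file.path(out_dir, "features.csv"))
    artifacts <- c(artifacts, file.path(out_dir, "features.csv"))
  }

  if ("classify" %in% stages && !is.null(fm)) {
    log_stage("classify: propulsion/recovery phases")
    fm$label <- label_records(fm, truth$phase)
    fm$group <- "sim"
    split <- split_dataset(fm, group_level = FALSE, seed = seed)
    rep <- train_and_evaluate(split, algorithms = "svm",
                              grids = list(svm = expand.grid(cost = 10, gamma = 0.01)),
                              seed = seed)$svm
    jsonlite::write_json(list(algorithm = rep$algorithm, params = rep$params,
                              accuracy = rep$accuracy, auc = rep$auc),
                         file.path(out_dir, "phase_model.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out_dir, "phase_model.json"))
  }

  if ("bvh" %in% stages) {
    log_stage("bvh export")
    qs <- lapply(seq_len(nrow(truth$angles)), function(i) {
      lapply(truth$orientations, function(o) as.numeric(o[i, quat_cols]))
    })
    keep <- seq(1, length(qs), by = max(1, round(profile$sample_rate / 25)))
    write_bvh(model, qs[keep], file.path(out_dir, "pose.bvh"),
              frame_time = (keep[2] - keep[1]) / profile$sample_rate,
              y_up = isTRUE(config$bvh_y_up))
    artifacts <- c(artifacts, file.path(out_dir, "pose.bvh"))
  }

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "rowimu",
    version = as.character(utils::packageVersion("rowimu")),
    seed = seed,
    config = cfg_for_hash,
    config_md5 = digest_object(cfg_for_hash),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(artifacts))),
                                basename(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
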