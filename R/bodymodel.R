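#' Rigid-segment body models
#'
#' A body model is a rooted tree of rigid segments. Each row describes one
#' segment: its `parent` (NA for the root, conventionally the pelvis), its
#' `length` in meters, its rest direction (`rest_x/y/z`, a unit vector
#' pointing proximal-to-distal in the body frame at the initial standing
#' pose, which coincides with the ground frame), where it attaches on the
#' parent (`attach`: `"distal"` or `"proximal"`), and the id of the IMU node
#' mounted on it (`sensor_id`, NA if uninstrumented - such segments inherit
#' the parent's orientation).
#'
#' @param segments Data frame with columns `segment, parent, length,
#'   rest_x, rest_y, rest_z` and optionally `attach`, `sensor_id`.
#' @return A `body_model` tibble (validated: single root, acyclic,
#'   positive lengths, unit rest directions).
#' @export
body_model <- function(segments) {
  segments <- tibble::as_tibble(segments)
  need <- c("segment", "parent", "length", "rest_x", "rest_y", "rest_z")
  if (!all(need %in% names(segments)))
    stop("body model needs columns: ", paste(need, collapse = ", "))
  if (!"attach" %in% names(segments)) segments$attach <- "distal"
  if (!"sensor_id" %in% names(segments)) segments$sensor_id <- NA_character_
  roots <- which(is.na(segments$parent))
  if (length(roots) != 1) stop("body model must have exactly one root segment")
  if (any(segments$length <= 0)) stop("segment lengths must be > 0")
  bad <- setdiff(segments$parent[!is.na(segments$parent)], segments$segment)
  if (length(bad)) stop("unknown parent segment(s): ", paste(bad, collapse = ", "))
  # normalize rest directions; detect cycles via topological order
  d <- as.matrix(segments[, c("rest_x", "rest_y", "rest_z")])
  nd <- sqrt(rowSums(d^2))
  if (any(nd < .Machine$double.eps)) stop("zero rest direction")
  d <- d / nd
  segments$rest_x <- d[, 1]; segments$rest_y <- d[, 2]; segments$rest_z <- d[, 3]
  if (length(model_topo_order(segments)) != nrow(segments))
    stop("body model contains a cycle")
  class(segments) <- c("body_model", class(segments))
  segments
}

model_topo_order <- function(segments) {
  order <- character(0)
  placed <- is.na(segments$parent)
  order <- segments$segment[placed]
  repeat {
    nxt <- !placed & segments$parent %in% order
    if (!any(nxt)) break
    order <- c(order, segments$segment[nxt])
    placed <- placed | nxt
  }
  order
}

#' Default 17-segment full-body model
#'
#' Head, torso, pelvis, both clavicles, and bilateral upper arm / forearm /
#' hand and thigh / shank / foot. Segment lengths are standard
#' anthropometric fractions of standing height. The standing rest pose faces
#' North (+Y) with arms down; IMU nodes are assigned to pelvis, torso, both
#' arms (upper arm + forearm) and both legs (thigh, shank, foot); head,
#' clavicles and hands are uninstrumented.
#'
#' @param height Participant height in meters (default 1.70).
#' @return A [body_model()].
#' @export
default_body_model <- function(height = 1.70) {
  seg <- function(name, parent, frac, dir, attach = "distal", sensor = NA_character_)
    tibble::tibble(segment = name, parent = parent, length = frac * height,
                   rest_x = dir[1], rest_y = dir[2], rest_z = dir[3],
                   attach = attach, sensor_id = sensor)
  up <- c(0, 0, 1); down <- c(0, 0, -1); fwd <- c(0, 1, 0)
  body_model(dplyr::bind_rows(
    seg("pelvis", NA_character_, 0.060, up, sensor = "pelvis"),
    seg("torso", "pelvis", 0.288, up, sensor = "torso"),
    seg("head", "torso", 0.182, up),
    seg("clavicle_l", "torso", 0.102, c(-1, 0, 0)),
    seg("clavicle_r", "torso", 0.102, c(1, 0, 0)),
    seg("upperarm_l", "clavicle_l", 0.172, down, sensor = "upperarm_l"),
    seg("upperarm_r", "clavicle_r", 0.172, down, sensor = "upperarm_r"),
    seg("forearm_l", "upperarm_l", 0.157, down, sensor = "forearm_l"),
    seg("forearm_r", "upperarm_r", 0.157, down, sensor = "forearm_r"),
    seg("hand_l", "forearm_l", 0.108, down),
    seg("hand_r", "forearm_r", 0.108, down),
    seg("thigh_l", "pelvis", 0.245, down, attach = "proximal", sensor = "thigh_l"),
    seg("thigh_r", "pelvis", 0.245, down, attach = "proximal", sensor = "thigh_r"),
    seg("shank_l", "thigh_l", 0.246, down, sensor = "shank_l"),
    seg("shank_r", "thigh_r", 0.246, down, sensor = "shank_r"),
    seg("foot_l", "shank_l", 0.152, fwd, sensor = "foot_l"),
    seg("foot_r", "shank_r", 0.152, fwd, sensor = "foot_r")
  ))
}

#' Reduced upper-limb body model
#'
#' Pelvis-rooted torso plus both arms: sufficient when only upper-limb
#' activity is analysed.
#'
#' @inheritParams default_body_model
#' @return A [body_model()].
#' @export
upper_body_model <- function(height = 1.70) {
  m <- default_body_model(height)
  keep <- c("pelvis", "torso", "clavicle_l", "clavicle_r",
            "upperarm_l", "upperarm_r", "forearm_l", "forearm_r",
            "hand_l", "hand_r")
  body_model(m[m$segment %in% keep, ])
}

#' Read / write a body model as JSON
#'
#' @param path File path.
#' @param model A [body_model()].
#' @return `read_body_model` returns a `body_model`.
#' @export
read_body_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  body_model(tibble::as_tibble(obj$segments))
}

#' @rdname read_body_model
#' @export
write_body_model <- function(model, path) {
  jsonlite::write_json(list(segments = as.data.frame(model)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Sensor-to-body mounting calibration from a static pose
#'
#' During the initial standing pose the body frame coincides with the
#' ground frame, so the mounting rotation of each node is the conjugate of
#' its static SCS-to-GCS orientation: `q_B^S = (q_S,init^G)*`, averaged over
#' the static window.
#'
#' @param static_orientations Named list (by segment) of orientation tibbles
#'   (`t, q0..q3`) covering the static window.
#' @param model A [body_model()]; every instrumented segment must appear in
#'   `static_orientations`.
#' @return An `alignment_calib` tibble: `segment, q0..q3` holding `q_B^S`.
#' @export
calibrate_alignment <- function(static_orientations, model) {
  inst <- model$segment[!is.na(model$sensor_id)]
  missing <- setdiff(inst, names(static_orientations))
  if (length(missing))
    stop("no static orientation stream for segment(s): ",
         paste(missing, collapse = ", "))
  rows <- lapply(inst, function(s) {
    qm <- as_quat_matrix(static_orientations[[s]])
    qbar <- quat_mean(qm)
    qbs <- quat_canonical(quat_conjugate(qbar))
    tibble::tibble(segment = s, q0 = qbs[1], q1 = qbs[2], q2 = qbs[3], q3 = qbs[4])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("alignment_calib", class(out))
  out
}

#' Segment orientation from sensor orientation and mounting calibration
#'
#' `q_B^G = q_S^G x q_B^S`.
#'
#' @param q_s_g Unit quaternion, sensor to ground.
#' @param q_b_s Unit quaternion, body to sensor (a row of
#'   [calibrate_alignment()], as a length-4 vector).
#' @return Unit quaternion, body segment to ground.
#' @export
segment_orientation <- function(q_s_g, q_b_s) {
  quat_normalize(quat_multiply(q_s_g, q_b_s))
}

calib_quat <- function(calib, segment) {
  i <- match(segment, calib$segment)
  if (is.na(i)) return(c(1, 0, 0, 0))
  as.numeric(calib[i, quat_cols])
}

#' Forward kinematics of a body model
#'
#' Reconstructs joint positions from per-segment orientations, iterating
#' from the pelvis at the origin: each segment's distal joint is its
#' proximal joint plus `length * rotate(q, rest_direction)`. Uninstrumented
#' segments (no entry in `orientations`) inherit the nearest instrumented
#' ancestor's orientation.
#'
#' @param model A [body_model()].
#' @param orientations Named list (by segment) of unit quaternions
#'   (`q_B^G`, length-4 vectors).
#' @return A `pose` tibble: `segment, parent, px, py, pz` (proximal joint),
#'   `dx, dy, dz` (distal joint), `q0..q3`.
#' @export
forward_kinematics <- function(model, orientations) {
  ord <- model_topo_order(model)
  rows <- stats::setNames(vector("list", length(ord)), ord)
  for (s in ord) {
    row <- model[model$segment == s, ]
    q <- orientations[[s]]
    if (is.null(q)) {
      if (is.na(row$parent))
        q <- c(1, 0, 0, 0)
      else
        q <- as.numeric(rows[[row$parent]][quat_cols])
    }
    if (is.na(row$parent)) {
      prox <- c(0, 0, 0)
    } else {
      p <- rows[[row$parent]]
      prox <- if (identical(row$attach, "proximal")) c(p$px, p$py, p$pz)
              else c(p$dx, p$dy, p$dz)
    }
    dir <- rotate_vector(q, c(row$rest_x, row$rest_y, row$rest_z))
    dist <- prox + row$length * dir
    rows[[s]] <- tibble::tibble(segment = s, parent = row$parent,
                                px = prox[1], py = prox[2], pz = prox[3],
                                dx = dist[1], dy = dist[2], dz = dist[3],
                                q0 = q[1], q1 = q[2], q2 = q[3], q3 = q[4])
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pose", class(out))
  out
}

#' Interior angle between two segment directions
#'
#' `acos` of the dot product of the unit vectors, in `[0, pi]`.
#'
#' @param u,v Non-zero 3-vectors.
#' @return Angle in radians.
#' @export
joint_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .Machine$double.eps || nv < .Machine$double.eps)
    stop("zero-length segment direction")
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Default joint-angle channel map
#'
#' Each flexion channel is the interior angle at a joint: the angle between
#' the reversed proximal-segment direction and the distal-segment direction.
#' With this convention arms-down standing reads 0 rad shoulder flexion and
#' a straight elbow/knee reads pi.
#'
#' @return Tibble `channel, proximal, distal`.
#' @export
default_channel_map <- function() {
  tibble::tribble(
    ~channel, ~proximal, ~distal,
    "SFl", "torso", "upperarm_l",
    "SFr", "torso", "upperarm_r",
    "EFl", "upperarm_l", "forearm_l",
    "EFr", "upperarm_r", "forearm_r",
    "KFl", "thigh_l", "shank_l",
    "KFr", "thigh_r", "shank_r",
    "FFl", "shank_l", "foot_l",
    "FFr", "shank_r", "foot_r"
  )
}

# nearest instrumented ancestor (or self) providing an orientation stream
resolve_stream_segment <- function(model, streams, segment) {
  s <- segment
  while (!is.null(s) && !is.na(s)) {
    if (s %in% names(streams)) return(s)
    s <- model$parent[match(s, model$segment)]
  }
  NA_character_
}

#' Joint flexion angles from per-segment orientation series
#'
#' Applies the mounting calibration, synchronizes all series onto a common
#' timebase (the coarsest stream restricted to the overlapping interval,
#' with linear interpolation of quaternion components and renormalization),
#' and evaluates each configured channel per sample.
#'
#' @param model A [body_model()].
#' @param orientation_series Named list (by segment) of orientation tibbles
#'   (`t, q0..q3`), e.g. from [fuse_imu()].
#' @param calib Optional [calibrate_alignment()] result (`q_B^S` per
#'   segment); identity mounting assumed where absent.
#' @param channels Channel map tibble (see [default_channel_map()]);
#'   channels whose segments cannot be resolved are dropped with a warning.
#' @return A joint-angle tibble: `t` plus one column per channel, radians in
#'   `[0, pi]`.
#' @export
compute_joint_angles <- function(model, orientation_series, calib = NULL,
                                 channels = default_channel_map()) {
  if (!length(orientation_series)) stop("no orientation series supplied")
  # common timebase: coarsest stream over the overlap
  t0 <- max(vapply(orientation_series, function(s) min(s$t), 0))
  t1 <- min(vapply(orientation_series, function(s) max(s$t), 0))
  if (t1 <= t0) stop("orientation series do not overlap in time")
  counts <- vapply(orientation_series, function(s) sum(s$t >= t0 & s$t <= t1), 0L)
  base <- orientation_series[[which.min(counts)]]
  tt <- base$t[base$t >= t0 & base$t <= t1]

  resampled <- lapply(names(orientation_series), function(s) {
    ser <- orientation_series[[s]]
    qm <- as_quat_matrix(ser)
    # enforce sign continuity before componentwise interpolation
    for (i in seq_len(nrow(qm))[-1])
      if (sum(qm[i, ] * qm[i - 1, ]) < 0) qm[i, ] <- -qm[i, ]
    out <- sapply(1:4, function(k) stats::approx(ser$t, qm[, k], xout = tt)$y)
    out <- out / sqrt(rowSums(out^2))
    if (!is.null(calib)) {
      qbs <- calib_quat(calib, s)
      out <- t(apply(out, 1, function(q) quat_multiply(q, qbs)))
    }
    out
  })
  names(resampled) <- names(orientation_series)

  keep <- logical(nrow(channels))
  for (i in seq_len(nrow(channels))) {
    keep[i] <- !is.na(resolve_stream_segment(model, resampled, channels$proximal[i])) &&
               !is.na(resolve_stream_segment(model, resampled, channels$distal[i])) &&
               all(c(channels$proximal[i], channels$distal[i]) %in% model$segment)
  }
  if (!all(keep)) {
    warning("dropping channels without orientation data: ",
            paste(channels$channel[!keep], collapse = ", "))
    channels <- channels[keep, ]
  }
  if (!nrow(channels)) stop("no computable joint-angle channels")

  rest_dir <- function(seg) {
    i <- match(seg, model$segment)
    c(model$rest_x[i], model$rest_y[i], model$rest_z[i])
  }
  out <- tibble::tibble(t = tt)
  for (i in seq_len(nrow(channels))) {
    ps <- resolve_stream_segment(model, resampled, channels$proximal[i])
    ds <- resolve_stream_segment(model, resampled, channels$distal[i])
    qp <- resampled[[ps]]; qd <- resampled[[ds]]
    up <- rest_dir(channels$proximal[i]); vd <- rest_dir(channels$distal[i])
    ang <- vapply(seq_along(tt), function(j) {
      joint_angle(-rotate_vector(qp[j, ], up), rotate_vector(qd[j, ], vd))
    }, 0)
    out[[channels$channel[i]]] <- ang
  }
  out
}
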