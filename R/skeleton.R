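#' Planar skeletal models
#'
#' The skeleton is a planar rigid-body tree. Every segment has a local frame
#' (x forward, y up at the zero pose) with its proximal joint at the origin;
#' joints are revolute about the out-of-plane axis, except the base joint
#' which may be a planar free joint (two translations + one rotation, plus
#' two locked out-of-plane rotations so the documented coordinate count is
#' preserved). Out-of-plane coordinates are carried as inertially decoupled
#' rotations: they appear in the coordinate list and mass matrix but, while
#' locked at zero (the default), do not move.
#'
#' Sign conventions: pelvis x forward, y up; hip/shoulder flexion positive,
#' knee flexion negative, ankle dorsiflexion positive.
#'
#' @name skeleton
NULL

GENERIC_HEIGHT <- 1.78
GENERIC_MASS <- 73

#' Construct a planar model from segment/joint tables
#'
#' Low-level constructor used by [build_default_model()] and by tests that
#' need small bespoke chains (e.g. a passive pendulum).
#'
#' @param segments data.frame with columns `name`, `mass` (kg), `inertia`
#'   (kg m^2, about the COM, out-of-plane axis), `com_x`, `com_y` (m, local
#'   frame), `length` (m, bookkeeping only).
#' @param joints data.frame with columns `name`, `parent` (segment name or
#'   `"ground"`), `child`, `loc_x`, `loc_y` (joint location in the parent
#'   frame), `type` (`"rev"` for revolute, `"free"` for the planar free
#'   base joint), `coord` (coordinate name for `"rev"`; ignored for
#'   `"free"`, which creates `<child>_tx`, `<child>_ty`, `<child>_tilt`,
#'   `<child>_list`, `<child>_rotation`).
#' @param points data.frame (may be empty) with columns `name`, `segment`,
#'   `x`, `y`, `z`: named points (contact-sphere centers, exotendon
#'   anchors, markers) fixed in segment frames; `z` is a constant
#'   mediolateral offset used for 3-D distances only.
#' @param oop_coords optional data.frame `name`, `inertia` adding further
#'   locked out-of-plane coordinates (e.g. lumbar bending/rotation) beyond
#'   those implied by a free joint.
#' @param oop_inertia inertia (kg m^2) assigned to free-joint out-of-plane
#'   coordinates.
#' @param leg_length nominal leg length in m (hip-to-ground at zero pose).
#' @param coord_order optional character vector giving the final coordinate
#'   ordering; must be a permutation of the generated names.
#' @return an object of class `skeleton_model`.
#' @export
planar_model <- function(segments, joints, points = NULL, oop_coords = NULL,
                         oop_inertia = 1.0, leg_length = NA_real_,
                         coord_order = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  joints <- as.data.frame(joints, stringsAsFactors = FALSE)
  if (anyDuplicated(segments$name)) stopf("duplicate segment names")
  if (any(segments$mass <= 0)) stopf("segment masses must be positive")
  if (any(segments$length <= 0)) stopf("segment lengths must be positive")

  # topological order: parents before children
  ord <- character(0)
  remaining <- joints
  while (nrow(remaining) > 0) {
    ready <- remaining$parent == "ground" | remaining$parent %in% ord
    if (!any(ready)) stopf("joint graph is not a tree rooted at ground")
    ord <- c(ord, remaining$child[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  if (!setequal(ord, segments$name)) {
    stopf("every segment must be the child of exactly one joint")
  }

  coords <- data.frame(name = character(0), type = character(0),
                       locked = logical(0), stringsAsFactors = FALSE)
  add_coord <- function(name, type, locked = FALSE) {
    coords <<- rbind(coords, data.frame(name = name, type = type,
                                        locked = locked))
  }

  bodies <- vector("list", length(ord))
  names(bodies) <- ord
  for (i in seq_along(ord)) {
    sn <- ord[i]
    j <- joints[joints$child == sn, , drop = FALSE]
    seg <- segments[segments$name == sn, , drop = FALSE]
    parent_idx <- if (j$parent == "ground") 0L else match(j$parent, ord)
    if (j$type == "free") {
      cn <- paste0(sn, c("_tx", "_ty", "_tilt", "_list", "_rotation"))
      add_coord(cn[1], "translational"); add_coord(cn[2], "translational")
      add_coord(cn[3], "rotational")
      add_coord(cn[4], "rotational", locked = TRUE)
      add_coord(cn[5], "rotational", locked = TRUE)
      body_coords <- cn[1:3]
    } else if (j$type == "rev") {
      add_coord(j$coord, "rotational")
      body_coords <- j$coord
    } else stopf("unknown joint type '%s'", j$type)
    bodies[[i]] <- list(name = sn, parent = parent_idx, jname = j$name,
                        jtype = j$type, jloc = c(j$loc_x, j$loc_y),
                        coords = body_coords, mass = seg$mass,
                        inertia = seg$inertia,
                        com = c(seg$com_x, seg$com_y))
  }
  if (!is.null(oop_coords)) {
    for (k in seq_len(nrow(oop_coords))) {
      add_coord(oop_coords$name[k], "rotational", locked = TRUE)
    }
  }
  if (!is.null(coord_order)) {
    if (!setequal(coord_order, coords$name)) {
      stopf("coord_order must be a permutation of the coordinate names")
    }
    coords <- coords[match(coord_order, coords$name), , drop = FALSE]
    rownames(coords) <- NULL
  }
  ci <- stats::setNames(seq_len(nrow(coords)), coords$name)
  for (i in seq_along(bodies)) {
    bodies[[i]]$cidx <- unname(ci[bodies[[i]]$coords])
  }

  # diagonal inertias of out-of-plane (locked-capable) coordinates
  oop <- rep(0, nrow(coords))
  free_oop <- grep("_(list|rotation)$", coords$name)
  oop[free_oop] <- oop_inertia
  if (!is.null(oop_coords)) {
    oop[match(oop_coords$name, coords$name)] <- oop_coords$inertia
  }
  is_oop <- oop > 0

  # ancestor incidence: anc[k, j] TRUE if body j is body k or an ancestor
  nb <- length(bodies)
  anc <- matrix(FALSE, nb, nb)
  for (k in seq_len(nb)) {
    p <- k
    while (p > 0) { anc[k, p] <- TRUE; p <- bodies[[p]]$parent }
  }

  points <- if (is.null(points) || nrow(points) == 0) {
    data.frame(name = character(0), segment = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  } else as.data.frame(points, stringsAsFactors = FALSE)
  if (nrow(points) > 0 && !all(points$segment %in% ord)) {
    stopf("point attached to unknown segment")
  }

  model <- structure(list(
    segments = segments, joints = joints, coords = coords,
    bodies = bodies, ancestors = anc, oop_inertia = oop, is_oop = is_oop,
    points = points, mass = sum(segments$mass),
    leg_length = leg_length, height = NA_real_
  ), class = "skeleton_model")
  model
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model> %d segments, %d coordinates (%d locked), %.2f kg",
              nrow(x$segments), nrow(x$coords), sum(x$coords$locked),
              x$mass))
  if (is.finite(x$leg_length)) cat(sprintf(", leg length %.2f m", x$leg_length))
  cat("\n")
  invisible(x)
}

#' Number of generalized coordinates
#' @param model a `skeleton_model`.
#' @return integer count.
#' @export
n_coords <- function(model) nrow(model$coords)

#' Names of the generalized coordinates
#' @param model a `skeleton_model`.
#' @return character vector in coordinate order.
#' @export
coord_names <- function(model) model$coords$name

# default anthropometry: fractions of total mass / height, radius-of-gyration
# fractions of segment length, from standard regression tables, tuned so the
# zero-pose leg (thigh + shank + ankle height) spans 0.92 m at 1.78 m stature.
default_anthropometry <- function() {
  list(
    # name           mfrac   lfrac    com (local, m per unit length)  krad
    pelvis   = list(mfrac = 0.1576, length = 0.0955, com = c(0.0, 0.0),   krad = 0.45),
    torso    = list(mfrac = 0.3521, length = 0.2921, com = c(0.0, 0.58),  krad = 0.50),
    thigh    = list(mfrac = 0.1260, length = 0.2360, com = c(0.0, -0.433), krad = 0.323),
    shank    = list(mfrac = 0.0507, length = 0.2303, com = c(0.0, -0.433), krad = 0.302),
    calcn    = list(mfrac = 0.0151, length = 0.0899, com = c(0.38, -0.31), krad = 0.475),
    toes     = list(mfrac = 0.0027, length = 0.0449, com = c(0.38, 0.0),  krad = 0.40),
    upperarm = list(mfrac = 0.0274, length = 0.1854, com = c(0.0, -0.436), krad = 0.322),
    forearm  = list(mfrac = 0.0233, length = 0.2247, com = c(0.0, -0.430), krad = 0.40)
  )
}

#' Build the generic planar running model
#'
#' Twenty generalized coordinates: a pelvis-ground joint with three
#' rotational (tilt active; list and rotation locked out-of-plane) and two
#' translational degrees of freedom; one rotational hip, knee, ankle,
#' metatarsophalangeal (MTP), shoulder and elbow joint per side; and a
#' three-rotational lumbar joint (extension active; bending and rotation
#' locked out-of-plane). Each foot carries four contact-sphere centers (one
#' heel, two at the MTP joint, one forefoot) and one calcaneal exotendon
#' anchor. Segment inertial properties come from standard anthropometric
#' regressions scaled to the generic stature (1.78 m, 73 kg); left and
#' right limbs are mirror-identical by construction.
#'
#' @param height stature in m (default generic 1.78).
#' @param mass total body mass in kg (default generic 73).
#' @param foot_separation constant mediolateral distance between the feet
#'   in m; the planar model has no mediolateral degree of freedom, so this
#'   fixed offset supplies the out-of-plane component of 3-D point
#'   distances (exotendon anchors, shoe markers).
#' @return a `skeleton_model` with 20 coordinates and `leg_length` set.
#' @export
build_default_model <- function(height = GENERIC_HEIGHT, mass = GENERIC_MASS,
                                foot_separation = 0.25) {
  if (height <= 0 || mass <= 0) stopf("height and mass must be positive")
  a <- default_anthropometry()
  sc <- height / GENERIC_HEIGHT
  seg_row <- function(name, key) {
    p <- a[[key]]
    L <- p$length * GENERIC_HEIGHT * sc
    m <- p$mfrac * mass
    data.frame(name = name, mass = m, inertia = m * (p$krad * L)^2,
               com_x = p$com[1] * L, com_y = p$com[2] * L, length = L)
  }
  segments <- rbind(
    seg_row("pelvis", "pelvis"), seg_row("torso", "torso"),
    seg_row("thigh_r", "thigh"), seg_row("shank_r", "shank"),
    seg_row("calcn_r", "calcn"), seg_row("toes_r", "toes"),
    seg_row("upperarm_r", "upperarm"), seg_row("forearm_r", "forearm"),
    seg_row("thigh_l", "thigh"), seg_row("shank_l", "shank"),
    seg_row("calcn_l", "calcn"), seg_row("toes_l", "toes"),
    seg_row("upperarm_l", "upperarm"), seg_row("forearm_l", "forearm")
  )
  # normalize so the total matches the target mass exactly
  segments$mass <- segments$mass * (mass / sum(segments$mass))
  L <- function(nm) segments$length[segments$name == nm]

  hip_y <- -0.55 * L("pelvis")
  lumbar_y <- 0.60 * L("pelvis")
  shoulder_y <- 1.05 * L("torso")
  ankle_drop <- -L("shank_r")
  # foot geometry in the calcaneus frame (origin at the ankle)
  foot_h <- 0.055 * sc          # sphere centers below the ankle
  mtp_x <- L("calcn_r")
  jrow <- function(name, parent, child, lx, ly, type, coord = NA) {
    data.frame(name = name, parent = parent, child = child,
               loc_x = lx, loc_y = ly, type = type, coord = coord)
  }
  joints <- rbind(
    jrow("ground_pelvis", "ground", "pelvis", 0, 0, "free"),
    jrow("lumbar", "pelvis", "torso", 0, lumbar_y, "rev", "lumbar_extension"),
    jrow("hip_r", "pelvis", "thigh_r", 0, hip_y, "rev", "hip_flexion_r"),
    jrow("knee_r", "thigh_r", "shank_r", 0, -L("thigh_r"), "rev", "knee_angle_r"),
    jrow("ankle_r", "shank_r", "calcn_r", 0, ankle_drop, "rev", "ankle_angle_r"),
    jrow("mtp_r", "calcn_r", "toes_r", mtp_x, -foot_h, "rev", "mtp_angle_r"),
    jrow("shoulder_r", "torso", "upperarm_r", 0, shoulder_y, "rev", "arm_flex_r"),
    jrow("elbow_r", "upperarm_r", "forearm_r", 0, -L("upperarm_r"), "rev", "elbow_flex_r"),
    jrow("hip_l", "pelvis", "thigh_l", 0, hip_y, "rev", "hip_flexion_l"),
    jrow("knee_l", "thigh_l", "shank_l", 0, -L("thigh_l"), "rev", "knee_angle_l"),
    jrow("ankle_l", "shank_l", "calcn_l", 0, ankle_drop, "rev", "ankle_angle_l"),
    jrow("mtp_l", "calcn_l", "toes_l", mtp_x, -foot_h, "rev", "mtp_angle_l"),
    jrow("shoulder_l", "torso", "upperarm_l", 0, shoulder_y, "rev", "arm_flex_l"),
    jrow("elbow_l", "upperarm_l", "forearm_l", 0, -L("upperarm_l"), "rev", "elbow_flex_l")
  )

  zoff <- foot_separation / 2
  foot_points <- function(side, z) {
    calcn <- paste0("calcn_", side); toes <- paste0("toes_", side)
    data.frame(
      name = paste0(c("heel_", "mtp_post_", "mtp_ant_", "forefoot_",
                      "exo_anchor_", "shoe_marker_"), side),
      segment = c(calcn, calcn, calcn, toes, calcn, calcn),
      x = c(-0.35 * mtp_x, 0.80 * mtp_x, 1.00 * mtp_x, 0.55 * L(toes),
            -0.45 * mtp_x, -0.45 * mtp_x),
      # the toes frame already sits at sphere-center height (the MTP
      # joint is dropped by foot_h in the calcaneus frame)
      y = c(-foot_h, -foot_h, -foot_h, 0, 0.3 * foot_h, 0.3 * foot_h),
      z = rep(z, 6))
  }
  points <- rbind(foot_points("r", +zoff), foot_points("l", -zoff))

  coord_order <- c(
    "pelvis_tx", "pelvis_ty", "pelvis_tilt", "pelvis_list", "pelvis_rotation",
    "hip_flexion_r", "knee_angle_r", "ankle_angle_r", "mtp_angle_r",
    "hip_flexion_l", "knee_angle_l", "ankle_angle_l", "mtp_angle_l",
    "lumbar_extension", "lumbar_bending", "lumbar_rotation",
    "arm_flex_r", "elbow_flex_r", "arm_flex_l", "elbow_flex_l")

  leg_length <- L("thigh_r") + L("shank_r") + foot_h + 0.035  # to sole
  model <- planar_model(
    segments, joints, points,
    oop_coords = data.frame(name = c("lumbar_bending", "lumbar_rotation"),
                            inertia = c(1.0, 1.0)),
    oop_inertia = 1.0, leg_length = leg_length, coord_order = coord_order)
  model$height <- height
  model$foot_separation <- foot_separation
  model
}

#' Anthropometric scaling specification
#'
#' @param height target stature in m.
#' @param mass target total body mass in kg.
#' @return a `scale_spec` list.
#' @export
scale_spec <- function(height, mass) {
  if (!is.finite(height) || height <= 0 || !is.finite(mass) || mass <= 0) {
    stopf("scale_spec: height and mass must be strictly positive")
  }
  structure(list(height = height, mass = mass), class = "scale_spec")
}

#' Scale a model to target anthropometry
#'
#' Segment lengths (and all frame offsets and attached points) scale
#' linearly with the height ratio, masses with the mass ratio, and inertias
#' as mass x length^2. The scaled total mass matches the target exactly.
#'
#' @param model a `skeleton_model` built at the generic anthropometry.
#' @param spec a [scale_spec()].
#' @return the scaled `skeleton_model`.
#' @export
scale_model <- function(model, spec) {
  if (!inherits(spec, "scale_spec")) stopf("spec must be a scale_spec")
  h0 <- model$height
  if (!is.finite(h0)) stopf("model has no stored height to scale from")
  sl <- spec$height / h0
  sm <- spec$mass / model$mass
  m <- model
  m$segments$mass <- model$segments$mass * sm
  m$segments$length <- model$segments$length * sl
  m$segments$com_x <- model$segments$com_x * sl
  m$segments$com_y <- model$segments$com_y * sl
  m$segments$inertia <- model$segments$inertia * sm * sl^2
  m$joints$loc_x <- model$joints$loc_x * sl
  m$joints$loc_y <- model$joints$loc_y * sl
  m$points$x <- model$points$x * sl
  m$points$y <- model$points$y * sl
  m$points$z <- model$points$z  # mediolateral separation is a config choice
  for (i in seq_along(m$bodies)) {
    b <- model$bodies[[i]]
    m$bodies[[i]]$jloc <- b$jloc * sl
    m$bodies[[i]]$com <- b$com * sl
    m$bodies[[i]]$mass <- b$mass * sm
    m$bodies[[i]]$inertia <- b$inertia * sm * sl^2
  }
  m$mass <- sum(m$segments$mass)
  m$leg_length <- model$leg_length * sl
  m$height <- spec$height
  m
}

#' Serialize / deserialize a skeleton model
#'
#' Round-trippable YAML representation of the segment, joint and point
#' tables. The mapping from OpenSim-style coordinate names used by common
#' treadmill reference datasets is the identity for the names used here
#' (`pelvis_tx`, `hip_flexion_r`, ...), documented in the coordinate table.
#'
#' @param model a `skeleton_model`.
#' @param path file path for the YAML document.
#' @return `write_model_yaml` returns `path` invisibly; `read_model_yaml`
#'   returns the reconstructed `skeleton_model`.
#' @export
write_model_yaml <- function(model, path) {
  doc <- list(
    segments = model$segments, joints = model$joints, points = model$points,
    oop = as.list(stats::setNames(model$oop_inertia[model$is_oop],
                                  model$coords$name[model$is_oop])),
    leg_length = model$leg_length, height = model$height,
    foot_separation = model$foot_separation %||% NA_real_,
    coord_order = model$coords$name)
  yaml::write_yaml(lapply(doc, function(x) if (is.data.frame(x)) as.list(x) else x),
                   path, precision = 12)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  oop_names <- names(doc$oop)
  joints <- as.data.frame(doc$joints)
  if (!"coord" %in% names(joints)) joints$coord <- NA_character_
  # out-of-plane coordinates implied by free joints vs the extra ones
  free_children <- joints$child[joints$type == "free"]
  free_names <- as.vector(outer(free_children, c("_list", "_rotation"),
                                paste0))
  extra <- setdiff(oop_names, free_names)
  model <- planar_model(
    as.data.frame(doc$segments), joints,
    as.data.frame(doc$points),
    oop_coords = if (length(extra)) {
      data.frame(name = extra, inertia = unlist(doc$oop[extra]))
    },
    oop_inertia = if (length(intersect(oop_names, free_names))) {
      unlist(doc$oop[intersect(oop_names, free_names)])[1]
    } else 1.0,
    leg_length = doc$leg_length,
    coord_order = unlist(doc$coord_order))
  model$height <- doc$height
  if (is.finite(doc$foot_separation %||% NA_real_)) {
    model$foot_separation <- doc$foot_separation
  }
  model
}
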