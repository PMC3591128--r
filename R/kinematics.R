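# Mobility measurement through endplate reference lines: line lengths,
# direction cosines, and plane-specific relative angles of each vertebra with
# respect to the sacrum. The same code path serves model states and
# (synthetic) radiological landmark data.
#
# Plane conventions (global frame: x mediolateral, y posterior, z cranial):
#   flexion-extension  - sagittal plane YZ, measured on the sagittal lines;
#   lateral bending    - frontal plane XZ, measured on the frontal lines;
#   axial rotation     - horizontal plane XY, measured on the frontal lines.
# The literal direction-cosine formula sums the products of the two in-plane
# cosines; it equals the in-plane angle only when both lines lie in the
# measurement plane, so a plane-projected normalised variant is the default
# for three-dimensional states.

#' Reference line between two landmark nodes
#'
#' @param p1,p2 Numeric 3-vectors, mm.
#' @param plane Optional tag (`"frontal"` or `"sagittal"`).
#' @return An object of class `lumbokin_line`.
#' @export
ref_line <- function(p1, p2, plane = NULL) {
  stopifnot(length(p1) == 3, length(p2) == 3)
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), plane = plane),
            class = "lumbokin_line")
}

#' Length of a reference line
#'
#' Euclidean norm of the node difference.
#'
#' @param line A [ref_line()].
#' @return Length in mm (0 for coincident nodes, which downstream operations
#'   treat as degenerate).
#' @export
line_length <- function(line) {
  sqrt(sum((line$p2 - line$p1)^2))
}

#' Direction cosines of a reference line
#'
#' @param line A [ref_line()].
#' @return Named vector `c(l, m, n)`, the components of the unit vector from
#'   the initial to the final node.
#' @export
direction_cosines <- function(line) {
  L <- line_length(line)
  if (L <= 0) stop("degenerate reference line: coincident nodes", call. = FALSE)
  setNames((line$p2 - line$p1) / L, c("l", "m", "n"))
}

plane_spec <- function(plane) {
  switch(plane,
    FE = list(idx = c(2, 3), axis = 1),   # sagittal YZ, sign about +x
    LB = list(idx = c(3, 1), axis = 2),   # frontal  XZ, sign about +y
    AR = list(idx = c(1, 2), axis = 3),   # horizontal XY, sign about +z
    stop("plane must be one of FE, LB, AR", call. = FALSE)
  )
}

#' Relative angle between two reference lines in a movement plane
#'
#' Computes the angle of `line` relative to `reference` for the selected
#' movement plane. `method = "literal"` applies the direction-cosine sum of
#' the two in-plane components as printed; `method = "projected"` (default)
#' first projects both lines onto the plane and normalises, which equals the
#' literal value for in-plane motion and remains a true in-plane angle for
#' three-dimensional states.
#'
#' @param line,reference [ref_line()] objects (reference: sacrum or neutral).
#' @param plane `"FE"`, `"LB"` or `"AR"`.
#' @param method `"projected"` or `"literal"`.
#' @param signed If `TRUE` (default) the sign is taken from the cross-product
#'   component along the plane normal (flexion, right lateral bending and
#'   right axial rotation positive).
#' @return Angle in degrees.
#' @export
relative_angle <- function(line, reference, plane = c("FE", "LB", "AR"),
                           method = c("projected", "literal"), signed = TRUE) {
  plane <- match.arg(plane)
  method <- match.arg(method)
  ps <- plane_spec(plane)
  ca <- direction_cosines(line)
  cb <- direction_cosines(reference)
  if (method == "literal") {
    cosv <- sum(ca[ps$idx] * cb[ps$idx])
  } else {
    va <- ca[ps$idx]; vb <- cb[ps$idx]
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    if (na < 1e-12 || nb < 1e-12) {
      stop("line is orthogonal to the measurement plane", call. = FALSE)
    }
    va <- va / na; vb <- vb / nb
    cosv <- sum(va * vb)
  }
  if (abs(cosv) > 1 + 1e-9) {
    stop("cosine magnitude exceeds 1: upstream normalisation error",
         call. = FALSE)
  }
  ang <- rad2deg(acos(clamp(cosv, -1, 1)))
  if (signed) {
    # in-plane cross product (reference x line) along the plane normal:
    # for index pair (i, j) of the plane, the normal component is b_i a_j - b_j a_i
    cr <- cb[ps$idx[1]] * ca[ps$idx[2]] - cb[ps$idx[2]] * ca[ps$idx[1]]
    if (cr < 0) ang <- -ang
  }
  unname(ang)
}

line_for_plane <- function(lines, plane) {
  if (plane == "FE") lines$sagittal else lines$frontal
}

transform_line <- function(line, R, u) {
  ref_line(drop(R %*% line$p1) + u, drop(R %*% line$p2) + u, line$plane)
}

#' Measure vertebral mobility of a solved spine state
#'
#' Transforms each vertebra's endplate reference lines by its equilibrium pose
#' and measures the movement angle relative to the (fixed) sacrum with the
#' direction-cosine procedure: the reported angle is the change of the
#' vertebra-versus-sacrum plane angle between the neutral and the deformed
#' configuration, positive along the movement direction.
#'
#' @param state A solved [solve_equilibrium()] state.
#' @param geometry The geometry the state was solved on.
#' @param movement `"FLX"`, `"EXT"`, `"LB"` or `"AR"`; defaults to the
#'   movement of the state's load case when available.
#' @param method Angle extraction variant, see [relative_angle()].
#' @return An `AngleTable` tibble (class `lumbokin_angle_table`): one row per
#'   vertebra (L1 first) with `cumulative_deg` (vertebra versus sacrum) and
#'   `segmental_deg` (increment over the vertebra below).
#' @export
measure_state <- function(state, geometry, movement = NULL,
                          method = c("projected", "literal")) {
  method <- match.arg(method)
  movement <- movement %||% state$loadcase$movement
  if (is.null(movement)) {
    stop("movement is needed to select the measurement plane", call. = FALSE)
  }
  plane <- movement_plane(movement)
  sgn <- movement_sign(movement)
  poses <- state$poses
  n <- geometry$n_seg
  cum <- numeric(n)
  seg <- numeric(n)
  l0_prev <- NULL
  ld_prev <- NULL
  for (i in seq_len(n)) {
    lines0 <- reference_lines(geometry$vertebrae[[i]])
    l0 <- line_for_plane(lines0, plane)
    ld <- transform_line(l0, poses[[i]]$R, poses[[i]]$u)
    cum[i] <- sgn * relative_angle(ld, l0, plane = plane, method = method)
    seg[i] <- if (i == 1) cum[1] else {
      # measured against the vertebra below, net of the neutral offset
      sgn * (relative_angle(ld, ld_prev, plane = plane, method = method) -
               relative_angle(l0, l0_prev, plane = plane, method = method))
    }
    l0_prev <- l0; ld_prev <- ld
  }
  angle_table(
    vertebra = rev(geometry$vertebra_labels),
    cumulative_deg = rev(cum),
    segmental_deg = rev(seg),
    movement = movement
  )
}

angle_table <- function(vertebra, cumulative_deg, segmental_deg = NULL,
                        movement = NULL, ...) {
  tb <- tibble::tibble(vertebra = vertebra,
                       cumulative_deg = cumulative_deg)
  if (!is.null(segmental_deg)) tb$segmental_deg <- segmental_deg
  extra <- list(...)
  for (nm in names(extra)) tb[[nm]] <- extra[[nm]]
  if (!is.null(movement)) tb$movement <- movement
  class(tb) <- c("lumbokin_angle_table", class(tb))
  tb
}

#' Movement angles from radiological landmark records
#'
#' Computes per-subject, per-vertebra movement angles from a landmark table in
#' the package's CSV dialect (`subject_id, movement, vertebra, plane, x1, y1,
#' z1, x2, y2, z2`, mm), by comparing each movement line with the same
#' subject's `NEUTRAL` line through [relative_angle()].
#'
#' @param landmarks A landmark tibble/data frame (see [cohort_landmarks()]).
#' @param method Angle extraction variant.
#' @return A tibble `subject_id, movement, vertebra, angle_deg`.
#' @export
angles_from_landmarks <- function(landmarks, method = c("projected", "literal")) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "movement", "vertebra", "plane",
                  "x1", "y1", "z1", "x2", "y2", "z2") %in% names(landmarks)))
  moved <- landmarks[landmarks$movement != "NEUTRAL", , drop = FALSE]
  out <- vector("list", nrow(moved))
  for (k in seq_len(nrow(moved))) {
    row <- moved[k, ]
    plane <- movement_plane(row$movement)
    want <- if (plane == "FE") "sagittal" else "frontal"
    if (row$plane != want) next
    base <- landmarks[landmarks$subject_id == row$subject_id &
                        landmarks$movement == "NEUTRAL" &
                        landmarks$vertebra == row$vertebra &
                        landmarks$plane == row$plane, , drop = FALSE]
    if (nrow(base) != 1) {
      stop("missing NEUTRAL landmark line for subject ", row$subject_id,
           " vertebra ", row$vertebra, call. = FALSE)
    }
    ld <- ref_line(c(row$x1, row$y1, row$z1), c(row$x2, row$y2, row$z2))
    l0 <- ref_line(c(base$x1, base$y1, base$z1), c(base$x2, base$y2, base$z2))
    out[[k]] <- tibble::tibble(
      subject_id = row$subject_id, movement = row$movement,
      vertebra = row$vertebra,
      angle_deg = movement_sign(row$movement) *
        relative_angle(ld, l0, plane = plane, method = method)
    )
  }
  dplyr::bind_rows(out)
}
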