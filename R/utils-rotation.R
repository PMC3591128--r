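# Rotation-vector algebra used by the segment mechanics and the chain
# kinematics. Conventions: x mediolateral (subject's right), y posterior,
# z cranial; flexion is a positive rotation about +x, right lateral bending
# about +y, right axial rotation about +z. Radians internally.

`%||%` <- function(x, y) if (is.null(x)) y else x

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)
}

#' @noRd
rotvec_to_matrix <- function(theta) {
  th2 <- sum(theta^2)
  if (th2 < 1e-20) {
    return(diag(3) + skew3(theta))
  }
  th <- sqrt(th2)
  K <- skew3(theta / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Derivatives of R(theta) with respect to the three rotation-vector
# components (Gallego-Yezzi closed form, with the small-angle limit).
rotvec_dR <- function(theta, R = rotvec_to_matrix(theta)) {
  th2 <- sum(theta^2)
  out <- vector("list", 3)
  if (th2 < 1e-16) {
    e <- diag(3)
    for (k in 1:3) out[[k]] <- skew3(e[, k])
    return(out)
  }
  tcr <- skew3(theta)
  ImR <- diag(3) - R
  for (k in 1:3) {
    out[[k]] <- ((theta[k] * tcr + skew3(cross3(theta, ImR[, k]))) / th2) %*% R
  }
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# movement axes in the global (sacrum) frame; a leading "-" flips the axis
# (e.g. "-LB" for a contralateral muscle moment)
movement_axis <- function(movement) {
  sgn <- 1
  if (startsWith(movement, "-")) {
    sgn <- -1
    movement <- substring(movement, 2)
  }
  sgn * switch(movement,
    FLX = c(1, 0, 0),
    EXT = c(-1, 0, 0),
    LB  = c(0, 1, 0),
    AR  = c(0, 0, 1),
    stop("unknown movement: ", movement, call. = FALSE)
  )
}

movement_plane <- function(movement) {
  switch(movement, FLX = "FE", EXT = "FE", LB = "LB", AR = "AR",
         stop("unknown movement: ", movement, call. = FALSE))
}

# sign that maps a signed plane angle onto "movement-positive" degrees
movement_sign <- function(movement) {
  switch(movement, FLX = 1, EXT = -1, LB = 1, AR = 1)
}

VERTEBRAE <- c("L5", "L4", "L3", "L2", "L1")
SEGMENT_LEVELS <- c("L5-S1", "L4-L5", "L3-L4", "L2-L3", "L1-L2")
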