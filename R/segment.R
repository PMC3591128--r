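# Motion-segment mechanics. The relative motion of the upper vertebra with
# respect to the lower is described by q = (ux, uy, uz, tx, ty, tz) in the
# disc frame (translations mm, rotation vector rad, acting about the disc
# centroid). The restoring wrench sums:
#   (a) annulus ground substance: a diagonal 6-DOF foundation built from the
#       confined modulus (axial/bending) and the shear modulus (shear/torsion)
#       of the elastic layer between the endplates;
#   (b) nucleus pulposus: a volumetric term K/2 * (dV/V0)^2 * V0 with
#       dV = A_n * uz + S_m * b, where the internal scalar b is the radial
#       bulge of the annulus mid-surface (condensed out at every evaluation);
#       for the Mooney-Rivlin card K is the incompressibility penalty, for
#       elastic cards the actual bulk modulus; a small deviatoric foundation
#       carries the nucleus shear modulus;
#   (c) annulus hoop stretch resisting the bulge, k_hoop = E_a * V_a / r_m^2;
#   (d) fibre layers: tension-only linear samples whose strain is affine in
#       (q, b) (rebar assumption), slackened by disc height loss;
#   (e) ligaments: exact attachment-distance strains through the bilinear
#       tension-only laws times cross-section;
#   (f) facets: unilateral penalty contact along an oblique normal.
# The segment energy is C1; its analytic gradient is the (negative) wrench.

# One-sided C2 regularisation of tension-only/contact laws used inside the
# equilibrium solver: the unit-modulus stress ramp is x^2/(2w) on [0, w] and
# x - w/2 beyond (exactly 0 for x <= 0), its energy x^3/(6w) then
# x^2/2 - w x/2 + w^2/6. The blend width is mechanically negligible
# (1e-3 strain, 0.02 mm gap) but makes the energy C2, which keeps Newton
# iterations from cycling across activation boundaries. The public
# constitutive operations stay exactly piecewise-linear.
RAMP_W_STRAIN <- 1e-3
RAMP_W_GAP <- 2e-2

ramp_s <- function(x, w) {
  ifelse(x <= 0, 0, ifelse(x < w, x^2 / (2 * w), x - w / 2))
}
ramp_ds <- function(x, w) {
  ifelse(x <= 0, 0, ifelse(x < w, x / w, 1))
}
ramp_psi <- function(x, w) {
  ifelse(x <= 0, 0,
         ifelse(x < w, x^3 / (6 * w), x^2 / 2 - w * x / 2 + w^2 / 6))
}

# smoothed bilinear tension-only law (stress, energy density)
bilinear_smooth_stress <- function(law, eps, w = RAMP_W_STRAIN) {
  law$E1 * ramp_s(eps, w) +
    (law$E2 - law$E1) * ramp_s(eps - law$transition_strain, w)
}
bilinear_smooth_energy <- function(law, eps, w = RAMP_W_STRAIN) {
  law$E1 * ramp_psi(eps, w) +
    (law$E2 - law$E1) * ramp_psi(eps - law$transition_strain, w)
}

segment_model <- function(seg, card) {
  Ma <- constrained_modulus(card$annulus$E, card$annulus$nu)
  Ga <- card$annulus$E / (2 * (1 + card$annulus$nu))
  nm <- nucleus_moduli(card$nucleus)
  h <- seg$h
  k6 <- c(
    (Ga * seg$A_a + nm$G * seg$A_n) / h,
    (Ga * seg$A_a + nm$G * seg$A_n) / h,
    (Ma * seg$A_a + 4 / 3 * nm$G * seg$A_n) / h,
    seg$eta_bend * (Ma * seg$I_xa + 4 / 3 * nm$G * seg$I_xn) / h,
    seg$eta_bend * (Ma * seg$I_ya + 4 / 3 * nm$G * seg$I_yn) / h,
    seg$eta_tors * (Ga * seg$J_a + nm$G * seg$J_n) / h
  )
  ligs <- lapply(seg$ligaments, function(lg) {
    law <- card$ligaments[[lg$name]]
    if (is.null(law)) stop("material card has no ligament law for ", lg$name,
                           call. = FALSE)
    c(lg, list(law = law))
  })
  list(
    seg = seg,
    level = seg$level,
    k6 = k6,
    kv = nm$K / seg$V_n,     # volumetric: U = kv/2 * (A_n uz + S_m b)^2
    A_n = seg$A_n, S_m = seg$S_m, V_n = seg$V_n,
    k_hoop = card$annulus$E * seg$hoop_geom,
    fib_G = seg$fib$G,
    fib_EA = card$fiber_layers$E[seg$fib$layer] * seg$fib$al,
    fib_eps0 = seg$fib$eps0,
    fib_layer = seg$fib$layer,
    ligaments = ligs,
    facets = seg$facets,
    card_name = card$name %||% "card"
  )
}

# condense the bulge DOF: solve dU/db = 0 (monotone piecewise-linear)
solve_bulge <- function(m, q, b0 = 0) {
  eps_q <- drop(m$fib_G[, 1:6] %*% q) + m$fib_eps0
  Gb <- m$fib_G[, 7]
  b <- b0
  for (it in 1:60) {
    eps <- eps_q + Gb * b
    sv <- ramp_s(eps, RAMP_W_STRAIN)
    r <- m$kv * (m$A_n * q[3] + m$S_m * b) * m$S_m + m$k_hoop * b +
      sum(m$fib_EA * sv * Gb)
    dr <- m$kv * m$S_m^2 + m$k_hoop +
      sum(m$fib_EA * ramp_ds(eps, RAMP_W_STRAIN) * Gb^2)
    step <- r / dr
    b <- b - step
    if (abs(step) < 1e-12) break
  }
  b
}

# energy and gradient of one segment at q (disc frame); returns the condensed
# bulge and the relative nucleus volume change as well
segment_eval <- function(m, q, b0 = 0, deriv = TRUE, breakdown = FALSE) {
  b <- solve_bulge(m, q, b0)
  DV <- m$A_n * q[3] + m$S_m * b
  eps <- drop(m$fib_G %*% c(q, b)) + m$fib_eps0
  fib_s <- ramp_s(eps, RAMP_W_STRAIN)

  E_found <- 0.5 * sum(m$k6 * q^2)
  E_vol <- 0.5 * m$kv * DV^2
  E_hoop <- 0.5 * m$k_hoop * b^2
  E_fib <- sum(m$fib_EA * ramp_psi(eps, RAMP_W_STRAIN))

  theta <- q[4:6]
  R <- rotvec_to_matrix(theta)
  dR <- if (deriv) rotvec_dR(theta, R) else NULL
  tr <- q[1:3]

  g <- if (deriv) m$k6 * q else NULL
  if (deriv) {
    g[3] <- g[3] + m$kv * DV * m$A_n
    g <- g + drop(crossprod(m$fib_G[, 1:6], m$fib_EA * fib_s))
  }
  bd <- if (breakdown) list() else NULL
  if (breakdown) {
    bd$annulus <- list(E = E_found + E_hoop, g = m$k6 * q)
    gn <- numeric(6); gn[3] <- m$kv * DV * m$A_n
    bd$nucleus <- list(E = E_vol, g = gn)
    for (l in sort(unique(m$fib_layer))) {
      sel <- m$fib_layer == l
      bd[[paste0("fiber_layer_", l)]] <- list(
        E = sum(m$fib_EA[sel] * ramp_psi(eps[sel], RAMP_W_STRAIN)),
        g = drop(crossprod(m$fib_G[sel, 1:6, drop = FALSE],
                           m$fib_EA[sel] * fib_s[sel])))
    }
  }

  E_lig <- 0
  for (lg in m$ligaments) {
    p <- tr + drop(R %*% lg$xi)
    v <- p - lg$O
    L <- sqrt(sum(v^2))
    strain <- (L - lg$L0) / lg$L0 + lg$slack
    E_l <- lg$cs * lg$L0 * bilinear_smooth_energy(lg$law, strain)
    E_lig <- E_lig + E_l
    gl <- NULL
    if (deriv && strain > 0) {
      sig <- bilinear_smooth_stress(lg$law, strain)
      vh <- v / L
      gl <- c(lg$cs * sig * vh,
              lg$cs * sig * c(sum(vh * (dR[[1]] %*% lg$xi)),
                              sum(vh * (dR[[2]] %*% lg$xi)),
                              sum(vh * (dR[[3]] %*% lg$xi))))
      g <- g + gl
    }
    if (breakdown) {
      key <- paste0("lig_", lg$name, if (lg$side != 0)
        paste0("_", if (lg$side < 0) "L" else "R") else "")
      prev <- bd[[key]] %||% list(E = 0, g = numeric(6))
      bd[[key]] <- list(E = prev$E + E_l,
                        g = prev$g + (gl %||% numeric(6)))
    }
  }

  E_fac <- 0
  gfac <- numeric(6)
  for (fc in m$facets) {
    p <- tr + drop(R %*% fc$xi)
    gap <- fc$gap + sum(fc$n * (p - fc$xi))
    if (gap < 0) {
      depth <- -gap
      E_fac <- E_fac + fc$penalty * ramp_psi(depth, RAMP_W_GAP)
      if (deriv) {
        fmag <- -fc$penalty * ramp_s(depth, RAMP_W_GAP)   # dU/dgap
        gf <- c(fmag * fc$n,
                fmag * c(sum(fc$n * (dR[[1]] %*% fc$xi)),
                         sum(fc$n * (dR[[2]] %*% fc$xi)),
                         sum(fc$n * (dR[[3]] %*% fc$xi))))
        gfac <- gfac + gf
        g <- g + gf
      }
    }
  }
  if (breakdown) bd$facets <- list(E = E_fac, g = gfac)

  list(E = E_found + E_vol + E_hoop + E_fib + E_lig + E_fac,
       g = g, b = b, e_v = DV / m$V_n, breakdown = bd)
}

state_to_q <- function(state) {
  c(state$translation, deg2rad(state$rotation))
}

find_segment <- function(geometry, level) {
  idx <- match(level, geometry$levels)
  if (is.na(idx)) stop("unknown level: ", level, call. = FALSE)
  idx
}

#' Restoring wrench of one motion segment
#'
#' Evaluates the generalized restoring wrench (force and moment on the upper
#' vertebra, about the disc centroid, in the disc frame) for a relative
#' 6-DOF displacement, with a per-constituent breakdown.
#'
#' @param state A segment state: `list(level, translation, rotation)` with
#'   translation in mm and rotation in degrees (about x: flexion positive;
#'   about y: lateral bending; about z: axial rotation).
#' @param geometry A [build_default_spine()] geometry.
#' @param card The [material_card()] for this segment.
#' @return An object of class `lumbokin_wrench`: `force` (N), `moment` (N m),
#'   and a `breakdown` tibble whose rows sum to the total.
#' @export
segment_wrench <- function(state, geometry, card) {
  if (any(abs(state$rotation) >= 90)) {
    stop("segment rotations must stay below 90 degrees", call. = FALSE)
  }
  idx <- find_segment(geometry, state$level)
  m <- segment_model(geometry$segments[[idx]], card)
  q <- state_to_q(state)
  ev <- segment_eval(m, q, deriv = TRUE, breakdown = TRUE)
  bd <- ev$breakdown
  tb <- dplyr::bind_rows(lapply(names(bd), function(nm) {
    g <- bd[[nm]]$g
    tibble::tibble(constituent = nm,
                   Fx = -g[1], Fy = -g[2], Fz = -g[3],
                   Mx = -g[4] / 1000, My = -g[5] / 1000, Mz = -g[6] / 1000,
                   energy_J = bd[[nm]]$E / 1000)
  }))
  structure(list(
    level = state$level,
    force = -ev$g[1:3],
    moment = -ev$g[4:6] / 1000,
    breakdown = tb,
    bulge_mm = ev$b,
    volume_change = ev$e_v
  ), class = "lumbokin_wrench")
}

#' @export
print.lumbokin_wrench <- function(x, ...) {
  cat("<segment wrench at", x$level, ">\n")
  cat("  force  (N):  ", paste(sprintf("%.4g", x$force), collapse = ", "), "\n")
  cat("  moment (N m):", paste(sprintf("%.4g", x$moment), collapse = ", "), "\n")
  print(x$breakdown, n = 5)
  invisible(x)
}

#' Relative nucleus volume change
#'
#' `(V - V0) / V0` of the nucleus pulposus. For a solved spine state the
#' converged per-segment values are returned; for a single segment state the
#' value is computed at that displacement.
#'
#' @param x A solved [solve_equilibrium()] state, or a segment state list as
#'   in [segment_wrench()].
#' @param geometry,card Needed for the single-segment form.
#' @return Named numeric vector of relative volume changes (dimensionless).
#' @export
nucleus_volume_change <- function(x, geometry = NULL, card = NULL) {
  if (inherits(x, "lumbokin_spine_state")) {
    return(setNames(x$e_v, x$levels))
  }
  stopifnot(!is.null(geometry), !is.null(card))
  idx <- find_segment(geometry, x$level)
  m <- segment_model(geometry$segments[[idx]], card)
  ev <- segment_eval(m, state_to_q(x), deriv = FALSE)
  setNames(ev$e_v, x$level)
}

#' Tangent stiffness of a motion segment
#'
#' Central finite difference of the restoring wrench; the symmetric part is
#' returned (units: N/mm, N, N mm blocks on the (translation, rotation)
#' partition, rotations in radians).
#'
#' @param state Segment state as in [segment_wrench()].
#' @param geometry,card Geometry and material card.
#' @param h Finite-difference step (mm / rad); must be positive.
#' @return A 6x6 symmetric matrix.
#' @export
tangent_stiffness <- function(state, geometry, card, h = 1e-5) {
  if (h <= 0) stop("step size h must be positive", call. = FALSE)
  idx <- find_segment(geometry, state$level)
  m <- segment_model(geometry$segments[[idx]], card)
  q0 <- state_to_q(state)
  K <- matrix(0, 6, 6)
  for (j in 1:6) {
    qp <- q0; qp[j] <- qp[j] + h
    qm <- q0; qm[j] <- qm[j] - h
    K[, j] <- (segment_eval(m, qp)$g - segment_eval(m, qm)$g) / (2 * h)
  }
  (K + t(K)) / 2
}
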