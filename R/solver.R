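# Quasi-static equilibrium of the L1-sacrum chain. Generalized coordinates:
# q = 6 relative DOF per motion segment (disc-frame translation mm, rotation
# vector rad), sacrum fixed. The total potential is
#   sum of segment energies
#   + P * sum of centroid-to-centroid distances     (follower preload; exactly
#     conservative, its gradient is a compressive force pair along the
#     deformed inter-vertebral axis)
#   - sum over moment loads M * a . (D_i theta_i)   (applied moments / global
#     muscles; the neutral-frame axis mapping is exact for single-axis
#     movements)
#   + sum over local muscles F * |p - anchor|       (a tensile slip pulling a
#     vertebral attachment towards a fixed pelvic anchor).
# Equilibrium is a stationary point: Newton iteration on the analytic
# gradient, with the Hessian assembled by finite differences of the gradient,
# incremental load stepping (preload first, then moments/muscles) and
# backtracking line search on the energy.

#' Define a load case
#'
#' @param movement Optional movement tag `"FLX"`, `"EXT"`, `"LB"`, `"AR"`;
#'   sets the default applied moment (15 N m, 6 N m for axial rotation) about
#'   the movement axis at L1.
#' @param preload Follower preload magnitude, N (default 400).
#' @param preload_type `"follower"` (reoriented along the deformed segment
#'   axis) or `"fixed"` (direction fixed vertical).
#' @param moment Applied moment magnitude at L1 about the movement axis, N m;
#'   `NULL` uses the movement default, 0 disables it.
#' @param muscles Optional list of muscle loads, each
#'   `list(name, type = "local"|"global", vertebra, magnitude, ...)` with
#'   `anchor`/`attach`/`bilateral` for local and `axis` for global muscles
#'   (see the packaged `muscles.yaml`).
#' @return A `lumbokin_loadcase`.
#' @export
load_case <- function(movement = NULL, preload = 400,
                      preload_type = c("follower", "fixed"),
                      moment = NULL, muscles = NULL) {
  preload_type <- match.arg(preload_type)
  if (!is.finite(preload) || preload < 0) {
    stop("preload must be a nonnegative finite number", call. = FALSE)
  }
  if (is.null(moment)) {
    moment <- if (is.null(movement)) 0 else if (movement == "AR") 6 else 15
  }
  if (!is.finite(moment)) stop("moment must be finite", call. = FALSE)
  for (mu in muscles %||% list()) {
    if (!is.finite(mu$magnitude) || mu$magnitude < 0) {
      stop("muscle magnitudes must be nonnegative: ", mu$name, call. = FALSE)
    }
  }
  structure(list(movement = movement, preload = preload,
                 preload_type = preload_type, moment = moment,
                 muscles = muscles %||% list()),
            class = "lumbokin_loadcase")
}

# resolve a card or per-level card list into one card per segment
card_map_for <- function(geometry, cards) {
  n <- geometry$n_seg
  if (inherits(cards, "lumbokin_card")) return(rep(list(cards), n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cd <- cards[[geometry$levels[i]]] %||% cards$default
    if (is.null(cd)) stop("no material card for level ", geometry$levels[i],
                          call. = FALSE)
    out[[i]] <- cd
  }
  out
}

spine_models <- function(geometry, cards) {
  cm <- card_map_for(geometry, cards)
  lapply(seq_len(geometry$n_seg), function(i) {
    segment_model(geometry$segments[[i]], cm[[i]])
  })
}

vertebra_index <- function(geometry, label) {
  j <- match(label, geometry$vertebra_labels)
  if (is.na(j)) stop("unknown vertebra: ", label, call. = FALSE)
  j
}

# forward kinematics: absolute poses (R, u) per vertebra plus the per-joint
# frame maps E_i = R_{i-1} D_i, the current disc centroids a_i, and the
# rotation-derivative maps used by external-load gradients
chain_poses <- function(geometry, qmat, deriv = FALSE) {
  n <- geometry$n_seg
  poses <- vector("list", n)
  Emaps <- vector("list", n)
  amat <- matrix(0, 3, n)
  Wmaps <- if (deriv) vector("list", n) else NULL
  Rprev <- diag(3); uprev <- c(0, 0, 0)
  for (i in seq_len(n)) {
    sg <- geometry$segments[[i]]
    th <- qmat[4:6, i]
    Rth <- rotvec_to_matrix(th)
    Ei <- Rprev %*% sg$D
    ai <- drop(Rprev %*% sg$centroid) + uprev
    Ri <- Rprev %*% sg$D %*% Rth %*% t(sg$D)
    ui <- ai + drop(Ei %*% qmat[1:3, i]) - drop(Ri %*% sg$centroid)
    poses[[i]] <- list(R = Ri, u = ui)
    Emaps[[i]] <- Ei
    amat[, i] <- ai
    if (deriv) {
      dR <- rotvec_dR(th, Rth)
      Wmaps[[i]] <- lapply(1:3, function(k) {
        Ei %*% dR[[k]] %*% t(Rth) %*% t(Ei)
      })
    }
    Rprev <- Ri; uprev <- ui
  }
  list(poses = poses, E = Emaps, a = amat, W = Wmaps)
}

# energy and gradient of the external loads at scales (sp: preload, sm:
# moments and muscles); gradient is a 6 x n matrix
external_eval <- function(geometry, lc, qmat, sp = 1, sm = 1, deriv = TRUE) {
  n <- geometry$n_seg
  ck <- chain_poses(geometry, qmat, deriv = deriv)
  g <- matrix(0, 6, n)
  E <- 0

  add_point_load <- function(w, p, j) {
    # dU/dp = w at point p attached to vertebra j
    for (i in seq_len(j)) {
      g[1:3, i] <<- g[1:3, i] + drop(crossprod(ck$E[[i]], w))
      r <- p - ck$a[, i]
      for (k in 1:3) {
        g[3 + k, i] <<- g[3 + k, i] + sum(w * (ck$W[[i]][[k]] %*% r))
      }
    }
  }

  # Follower (or fixed-direction) preload: compressive force pairs along the
  # deformed axis. The path is the polyline sacrum centroid -> disc centroid
  # -> body centroid -> disc centroid -> ... -> L1 centroid (disc centroids
  # ride with the lower body), so each pair acts almost exactly along the
  # local segment axis and the preload introduces no spurious bending.
  if (lc$preload > 0 && sp > 0) {
    P <- lc$preload * sp
    pts <- list(list(p = geometry$sacrum$origin, body = 0L))
    for (i in seq_len(n)) {
      pts[[length(pts) + 1]] <- list(p = ck$a[, i], body = i - 1L)
      pts[[length(pts) + 1]] <- list(
        p = drop(ck$poses[[i]]$R %*% geometry$vertebrae[[i]]$origin) +
          ck$poses[[i]]$u,
        body = i)
    }
    for (k in seq_len(length(pts) - 1)) {
      lo <- pts[[k]]; hi <- pts[[k + 1]]
      d <- hi$p - lo$p
      L <- sqrt(sum(d^2))
      vh <- if (lc$preload_type == "follower") d / L else c(0, 0, 1)
      E <- E + P * (if (lc$preload_type == "follower") L else sum(d * c(0, 0, 1)))
      if (deriv) {
        if (hi$body > 0) add_point_load(P * vh, hi$p, hi$body)
        if (lo$body > 0) add_point_load(-P * vh, lo$p, lo$body)
      }
    }
  }

  add_moment <- function(Mnmm, axis, j) {
    for (i in seq_len(j)) {
      ai <- drop(crossprod(geometry$segments[[i]]$D, axis))
      E <<- E - Mnmm * sum(ai * qmat[4:6, i])
      if (deriv) g[4:6, i] <<- g[4:6, i] - Mnmm * ai
    }
  }

  if (sm > 0) {
    if (!is.null(lc$movement) && lc$moment != 0) {
      # applied at the topmost built vertebra (L1 for the full chain)
      add_moment(1000 * lc$moment * sm, movement_axis(lc$movement),
                 geometry$n_seg)
    }
    for (mu in lc$muscles) {
      if (mu$magnitude <= 0) next
      j <- vertebra_index(geometry, mu$vertebra)
      if (identical(mu$type, "global")) {
        add_moment(1000 * mu$magnitude * sm, movement_axis(mu$axis), j)
      } else {
        sides <- if (isTRUE(mu$bilateral)) c(-1, 1) else 1
        Fm <- mu$magnitude * sm / length(sides)
        vb <- geometry$vertebrae[[j]]
        for (sd in sides) {
          xp <- vb$origin + drop(vb$axes %*% (c(sd, 1, 1) * mu$attach))
          anchor <- c(sd, 1, 1) * mu$anchor
          p <- drop(ck$poses[[j]]$R %*% xp) + ck$poses[[j]]$u
          d <- p - anchor
          L <- sqrt(sum(d^2))
          E <- E + Fm * L
          if (deriv) add_point_load(Fm * d / L, p, j)
        }
      }
    }
  }
  list(E = E, g = g, chain = ck)
}

total_eval <- function(models, geometry, lc, qmat, bvec, sp, sm, deriv = TRUE) {
  n <- length(models)
  E <- 0
  g <- matrix(0, 6, n)
  e_v <- numeric(n)
  for (i in seq_len(n)) {
    sv <- segment_eval(models[[i]], qmat[, i], b0 = bvec[i], deriv = deriv)
    E <- E + sv$E
    if (deriv) g[, i] <- sv$g
    bvec[i] <- sv$b
    e_v[i] <- sv$e_v
  }
  ex <- external_eval(geometry, lc, qmat, sp, sm, deriv = deriv)
  list(E = E + ex$E, g = g + ex$g, b = bvec, e_v = e_v)
}

#' Solve quasi-static equilibrium of the spine chain
#'
#' Newton iteration with incremental load stepping: the preload is ramped
#' first, then moments and muscle forces. Convergence requires the residual
#' (the energy gradient) below `tol_force` N on translations and
#' `tol_moment_nmm` N mm on rotations.
#'
#' @param loadcase A [load_case()].
#' @param geometry A [build_default_spine()] geometry.
#' @param cards A single [material_card()] for all levels, or a named list
#'   keyed by level (with optional `default`).
#' @param control Solver control overrides: `tol_force` (N, default 1e-6),
#'   `tol_moment_nmm` (N mm, default 1e-3), `n_steps` (moment-phase load
#'   increments, default 6), `preload_steps` (default 2), `max_iter` per step
#'   (default 60).
#' @param warm Optional warm start: a previous `lumbokin_spine_state` solved
#'   on the same geometry (single-step continuation).
#' @return A `lumbokin_spine_state`: per-segment coordinates, poses,
#'   convergence record, bulges and nucleus volume changes, and the
#'   load-step trajectory used for work integrals.
#' @export
solve_equilibrium <- function(loadcase, geometry, cards,
                              control = list(), warm = NULL) {
  stopifnot(inherits(loadcase, "lumbokin_loadcase"),
            inherits(geometry, "lumbokin_geometry"))
  ctl <- utils::modifyList(list(tol_force = 1e-6, tol_moment_nmm = 1e-3,
                                n_steps = 6, preload_steps = 2,
                                max_iter = 60, max_rot_step = 0.15), control)
  models <- spine_models(geometry, cards)
  n <- geometry$n_seg
  qmat <- matrix(0, 6, n)
  bvec <- numeric(n)
  if (!is.null(warm)) {
    qmat <- warm$q
    bvec <- warm$b
  }

  trajectory <- list(list(q = qmat, sm = 0))
  total_iter <- 0L
  n_steps_done <- 0L
  H <- NULL
  res <- Inf
  # two phases, each ramped adaptively: on Newton failure the increment is
  # halved (down to 1/512), on success it may grow again
  phases <- if (is.null(warm)) {
    list(list(what = "preload", n = ctl$preload_steps),
         list(what = "moment", n = ctl$n_steps))
  } else {
    list(list(what = "moment", n = 1))
  }
  for (ph in phases) {
    s <- 0; ds <- 1 / ph$n
    while (s < 1 - 1e-12) {
      ds <- min(ds, 1 - s)
      sp <- if (ph$what == "preload") s + ds else 1
      sm <- if (ph$what == "moment") s + ds else 0
      st <- newton_step_solve(models, geometry, loadcase, qmat, bvec, sp, sm,
                              ctl, H)
      total_iter <- total_iter + st$iter
      res <- st$res
      if (st$converged) {
        qmat <- st$q; bvec <- st$b; H <- st$H
        s <- s + ds
        ds <- min(ds * 1.5, 1 / ph$n)
        n_steps_done <- n_steps_done + 1L
        if (ph$what == "moment") {
          trajectory[[length(trajectory) + 1]] <- list(q = qmat, sm = s)
        }
      } else {
        H <- NULL
        ds <- ds / 2
        if (ds < 1 / 512) {
          stop("equilibrium solve did not converge (last residual ",
               signif(res, 4), " at ", ph$what, " factor ",
               signif(s + 2 * ds, 3), ")", call. = FALSE)
        }
      }
    }
  }
  converged <- TRUE

  ck <- chain_poses(geometry, qmat)
  fin <- total_eval(models, geometry, loadcase, qmat, bvec, 1, 1)
  structure(list(
    q = qmat, b = fin$b, e_v = fin$e_v,
    poses = ck$poses,
    levels = geometry$levels,
    vertebra_labels = geometry$vertebra_labels,
    loadcase = loadcase,
    converged = converged,
    residual = res,
    iterations = total_iter,
    load_steps = n_steps_done,
    energy_nmm = fin$E,
    trajectory = trajectory,
    H = H
  ), class = "lumbokin_spine_state")
}

residual_norms <- function(g) {
  c(force = max(abs(g[1:3, ])), moment = max(abs(g[4:6, ])))
}

newton_step_solve <- function(models, geometry, lc, qmat, bvec, sp, sm, ctl,
                              H = NULL) {
  n <- length(models)
  dim6 <- 6 * n
  ev <- total_eval(models, geometry, lc, qmat, bvec, sp, sm)
  bvec <- ev$b
  lam <- 1e-6
  iter <- 0L
  refresh <- is.null(H)
  repeat {
    rn <- residual_norms(ev$g)
    if (rn["force"] < ctl$tol_force && rn["moment"] < ctl$tol_moment_nmm) {
      return(list(q = qmat, b = bvec, H = H, iter = iter, converged = TRUE,
                  res = max(rn)))
    }
    if (iter >= ctl$max_iter) {
      return(list(q = qmat, b = bvec, H = H, iter = iter, converged = FALSE,
                  res = max(rn)))
    }
    if (refresh || is.null(H)) {
      H <- numeric_hessian(models, geometry, lc, qmat, bvec, sp, sm)
      refresh <- FALSE
    }
    g <- as.vector(ev$g)
    step <- tryCatch(
      -solve(H + lam * diag(dim6), g),
      error = function(e) NULL
    )
    if (is.null(step)) {
      lam <- lam * 100
      refresh <- TRUE
      iter <- iter + 1L
      next
    }
    smax <- max(abs(step[rep(4:6, n) + rep(seq(0, dim6 - 6, by = 6), each = 3)]))
    if (is.finite(smax) && smax > ctl$max_rot_step) {
      step <- step * ctl$max_rot_step / smax
    }
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:10) {
      qtry <- qmat + matrix(alpha * step, 6, n)
      evt <- total_eval(models, geometry, lc, qtry, bvec, sp, sm)
      rt <- residual_norms(evt$g)
      if (evt$E < ev$E + 1e-8 * abs(ev$E) + 1e-8 || max(rt) < max(rn)) {
        qmat <- qtry; ev <- evt; bvec <- evt$b
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    iter <- iter + 1L
    if (!accepted || alpha < 1) {
      refresh <- TRUE
      if (!accepted) lam <- lam * 10 else lam <- max(lam, 1e-4)
    } else {
      lam <- max(lam / 10, 1e-8)
      if (iter %% 4 == 0) refresh <- TRUE
    }
  }
}

numeric_hessian <- function(models, geometry, lc, qmat, bvec, sp, sm,
                            h = 1e-6) {
  n <- length(models)
  dim6 <- 6 * n
  H <- matrix(0, dim6, dim6)
  g0 <- as.vector(total_eval(models, geometry, lc, qmat, bvec, sp, sm)$g)
  for (j in seq_len(dim6)) {
    qp <- qmat
    qp[j] <- qp[j] + h
    gp <- as.vector(total_eval(models, geometry, lc, qp, bvec, sp, sm)$g)
    H[, j] <- (gp - g0) / h
  }
  (H + t(H)) / 2
}

#' Range of motion of the chain under a load case
#'
#' Solves equilibrium and measures the cumulative and segmental vertebral
#' angles for the movement plane.
#'
#' @inheritParams solve_equilibrium
#' @param movement Movement tag; defaults to the load case's movement.
#' @param ... Passed to [solve_equilibrium()].
#' @return An `AngleTable` tibble, L1 first.
#' @export
range_of_motion <- function(movement, loadcase = NULL, geometry, cards, ...) {
  lc <- loadcase %||% load_case(movement = movement)
  st <- solve_equilibrium(lc, geometry, cards, ...)
  measure_state(st, geometry, movement = movement)
}

#' @export
print.lumbokin_spine_state <- function(x, ...) {
  cat("<lumbokin spine state:",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations /", x$load_steps, "load steps>\n")
  cat("  residual:", signif(x$residual, 4),
      " energy (J):", signif(x$energy_nmm / 1000, 6), "\n")
  rot <- round(rad2deg(t(x$q[4:6, , drop = FALSE])), 3)
  rownames(rot) <- x$levels
  colnames(rot) <- c("flex_deg", "latbend_deg", "axrot_deg")
  print(rot)
  invisible(x)
}
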