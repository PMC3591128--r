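# Parametric stand-in for the scanned lumbar anatomy: vertebral reference
# frames with lordotic tilts, elliptical disc cross-sections split into nucleus
# and annulus, crossed fibre-layer sample directions (35-80 degrees), ligament
# attachment pairs, unilateral facet contact pairs, and the endplate reference
# nodes used for mobility measurement. Everything is a named parameter of the
# geometry config; the default file carries anatomy-book magnitudes.

#' Default spine geometry configuration
#'
#' @param file Optional YAML file; defaults to the packaged geometry config.
#' @return A validated configuration list of class `lumbokin_spine_config`.
#' @export
default_spine_config <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "geometry_default.yaml",
                        package = "lumbokin", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(file)
  validate_spine_config(cfg)
}

validate_spine_config <- function(cfg) {
  # YAML sequences with mixed int/float entries arrive as lists
  num_vec <- function(x) as.numeric(unlist(x))
  cfg$disc_heights <- num_vec(cfg$disc_heights)
  cfg$level_scale <- num_vec(cfg$level_scale)
  cfg$disc_tilt_deg <- num_vec(cfg$disc_tilt_deg)
  cfg$fiber$orientations_deg <- num_vec(cfg$fiber$orientations_deg)
  cfg$fiber$layer_radial_scale <- num_vec(cfg$fiber$layer_radial_scale)
  cfg$fiber$layer_weights <- num_vec(cfg$fiber$layer_weights)
  cfg$levels <- as.character(unlist(cfg$levels))
  cfg$vertebrae <- as.character(unlist(cfg$vertebrae))
  if (!is.null(cfg$iliolumbar)) {
    cfg$iliolumbar$origin <- num_vec(cfg$iliolumbar$origin)
    cfg$iliolumbar$insertion <- num_vec(cfg$iliolumbar$insertion)
  }
  pos_fields <- list(
    body_height = cfg$body_height,
    disc_heights = cfg$disc_heights,
    ellipse_a_ml = cfg$ellipse_a_ml,
    ellipse_b_ap = cfg$ellipse_b_ap,
    level_scale = cfg$level_scale,
    fiber_total_area = cfg$fiber$total_area,
    fiber_layer_weights = cfg$fiber$layer_weights,
    facet_penalty = cfg$facets$penalty
  )
  for (nm in names(pos_fields)) {
    v <- pos_fields[[nm]]
    if (is.null(v) || !all(is.finite(v)) || any(v <= 0)) {
      stop("geometry config field '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$nucleus_area_fraction <= 0 || cfg$nucleus_area_fraction >= 1) {
    stop("geometry config field 'nucleus_area_fraction' must lie in (0, 1)",
         call. = FALSE)
  }
  ang <- cfg$fiber$orientations_deg
  if (any(ang < 35 - 1e-9) || any(ang > 80 + 1e-9)) {
    stop("fibre orientations must lie within [35, 80] degrees", call. = FALSE)
  }
  if (any(diff(ang) < 0)) {
    stop("fibre orientations must not decrease from inner to outer layer",
         call. = FALSE)
  }
  if (cfg$facets$gap < 0) {
    stop("geometry config field 'facets$gap' must be nonnegative", call. = FALSE)
  }
  cfg$total_height <- sum(cfg$disc_heights) +
    length(cfg$vertebrae) * cfg$body_height
  structure(cfg, class = "lumbokin_spine_config")
}

#' Build the parametric lumbar spine geometry
#'
#' Constructs vertebra frames (sacrum to L1), disc geometry, fibre-layer sample
#' directions, ligament attachments and facet pairs from a configuration. The
#' default geometry is bilaterally symmetric about the sagittal plane.
#'
#' @param config A [default_spine_config()] (or an edited copy).
#' @param n_levels Number of motion segments to build, counted from the sacrum
#'   (5 = full L1-sacrum chain; 1 = an L5-S1 functional unit).
#' @param degeneration Optional list describing disc degeneration geometry at
#'   one level: `list(level = "L5-S1", height_loss = 0.2,
#'   slack = c(ALL = -0.02, PLL = -0.02))`. Height loss reduces the disc
#'   height while ligament rest lengths and fibre rest strains keep their
#'   healthy values, so the approach of the vertebrae slackens them; `slack`
#'   adds extra (nonpositive) pre-strain offsets to named ligaments.
#' @return An object of class `lumbokin_geometry`.
#' @export
build_default_spine <- function(config = default_spine_config(), n_levels = 5,
                                degeneration = NULL) {
  if (!inherits(config, "lumbokin_spine_config")) {
    config <- validate_spine_config(config)
  }
  stopifnot(n_levels >= 1, n_levels <= length(config$levels))
  bh <- config$body_height
  tilts <- deg2rad(config$disc_tilt_deg)
  vtilts <- (tilts + c(tilts[-1], 0)) / 2

  hl_by_seg <- rep(0, n_levels)
  slack_extra <- NULL
  if (!is.null(degeneration)) {
    lev <- degeneration$level %||% "L5-S1"
    idx <- match(lev, config$levels)
    if (is.na(idx) || idx > n_levels) {
      stop("degeneration level not in geometry: ", lev, call. = FALSE)
    }
    hl <- degeneration$height_loss %||% 0
    if (hl < 0 || hl >= 1) stop("height_loss must lie in [0, 1)", call. = FALSE)
    if (any((degeneration$slack %||% 0) > 0)) {
      stop("ligament slack offsets must be nonpositive", call. = FALSE)
    }
    hl_by_seg[idx] <- hl
    slack_extra <- list(idx = idx, slack = degeneration$slack %||% numeric())
  }

  # sacrum frame: superior endplate centre at the origin
  s_axes <- rot_x(tilts[1])
  sacrum <- list(
    label = "S",
    origin = drop(-s_axes %*% c(0, 0, 20)),
    axes = s_axes,
    endplate_sup = endplate_nodes(c(0, 0, 0), s_axes, 1.1, config)
  )

  segments <- vector("list", n_levels)
  vertebrae <- vector("list", n_levels)
  top <- c(0, 0, 0)
  for (i in seq_len(n_levels)) {
    h_h <- config$disc_heights[i]
    h <- h_h * (1 - hl_by_seg[i])
    D <- rot_x(tilts[i])
    d0 <- top + drop(D %*% c(0, 0, h / 2))
    bot_i <- d0 + drop(D %*% c(0, 0, h / 2))
    Q <- rot_x(vtilts[i])
    cen <- bot_i + drop(Q %*% c(0, 0, bh / 2))
    top <- cen + drop(Q %*% c(0, 0, bh / 2))
    s <- config$level_scale[i]

    vertebrae[[i]] <- list(
      label = config$vertebrae[i],
      origin = cen,
      axes = Q,
      scale = s,
      endplate_sup = endplate_nodes(top, Q, s, config),
      endplate_inf = endplate_nodes(bot_i, Q, s, config)
    )
    segments[[i]] <- build_segment(config, i, h, h_h, d0, D, s, hl_by_seg[i])
  }

  if (!is.null(slack_extra)) {
    seg <- segments[[slack_extra$idx]]
    sl <- slack_extra$slack
    for (nm in names(sl)) {
      hit <- vapply(seg$ligaments, function(lg) lg$name == nm, logical(1))
      for (j in which(hit)) {
        seg$ligaments[[j]]$slack <- seg$ligaments[[j]]$slack + sl[[nm]]
      }
    }
    segments[[slack_extra$idx]] <- seg
  }

  geom <- structure(list(
    config = config,
    n_seg = n_levels,
    levels = config$levels[seq_len(n_levels)],
    vertebra_labels = config$vertebrae[seq_len(n_levels)],
    sacrum = sacrum,
    vertebrae = vertebrae,
    segments = segments,
    degeneration = degeneration,
    total_height = config$total_height
  ), class = "lumbokin_geometry")
  geom
}

endplate_nodes <- function(center, axes, scale, config) {
  fh <- config$endplate$frontal_halfspan * scale
  sh <- config$endplate$sagittal_halfspan * scale
  list(
    frontal = rbind(center - drop(axes %*% c(fh, 0, 0)),
                    center + drop(axes %*% c(fh, 0, 0))),
    sagittal = rbind(center - drop(axes %*% c(0, sh, 0)),
                     center + drop(axes %*% c(0, sh, 0)))
  )
}

build_segment <- function(config, i, h, h_h, d0, D, s, height_loss) {
  a <- config$ellipse_a_ml * s
  b <- config$ellipse_b_ap * s
  f <- config$nucleus_area_fraction
  A <- pi * a * b
  Ix <- pi * a * b^3 / 4
  Iy <- pi * a^3 * b / 4
  A_n <- f * A; A_a <- A - A_n
  I_xn <- f^2 * Ix; I_yn <- f^2 * Iy
  I_xa <- Ix - I_xn; I_ya <- Iy - I_yn
  am <- a * config$annulus_mid_scale
  bm <- b * config$annulus_mid_scale
  r_m <- sqrt(am * bm)
  S_m <- pi * (am + bm) * h
  V_n <- A_n * h
  V_a <- A_a * h

  fib <- build_fibers(config, a, b, h, r_m, s, height_loss)
  ligs <- build_ligaments(config, i, h, h_h)
  facets <- build_facets(config, h)

  list(
    level = config$levels[i],
    index = i,
    h = h, h_healthy = h_h, height_loss = height_loss,
    centroid = d0, D = D,
    a = a, b = b,
    A = A, A_n = A_n, A_a = A_a,
    I_xa = I_xa, I_ya = I_ya, J_a = I_xa + I_ya,
    I_xn = I_xn, I_yn = I_yn, J_n = I_xn + I_yn,
    r_m = r_m, S_m = S_m, V_n = V_n, V_a = V_a,
    hoop_geom = V_a / r_m^2,
    eta_bend = config$foundation_bending_efficiency %||% 1,
    eta_tors = config$foundation_torsion_efficiency %||% 1,
    nucleus_area_fraction = f,
    fib = fib,
    ligaments = ligs,
    facets = facets
  )
}

# Fibre sampling: each material layer lies on its own concentric ellipse, as a
# crossed +/- pair of families at the layer orientation. The linearised strain
# of a fibre sample under the segment coordinates q = (ux, uy, uz, tx, ty, tz)
# and the annulus radial bulge b is eps = G %*% c(q, b) + eps0.
build_fibers <- function(config, a, b, h, r_m, s, height_loss) {
  fc <- config$fiber
  n <- fc$n_samples
  w <- fc$layer_weights / sum(fc$layer_weights)
  total <- fc$total_area * s^2
  phis <- (seq_len(n) - 0.5) * 2 * pi / n
  rows <- list()
  for (l in seq_along(fc$orientations_deg)) {
    al <- a * fc$layer_radial_scale[l]
    bl <- b * fc$layer_radial_scale[l]
    alpha <- deg2rad(fc$orientations_deg[l])
    sa <- sin(alpha); ca <- cos(alpha)
    area <- total * w[l] / 2 / n      # per sample, per family
    for (fam in c(1, -1)) {
      x <- al * cos(phis); y <- bl * sin(phis)
      tn <- sqrt((al * sin(phis))^2 + (bl * cos(phis))^2)
      tx <- -al * sin(phis) / tn; ty <- bl * cos(phis) / tn
      dz <- fam * sa
      rows[[length(rows) + 1]] <- data.frame(
        layer = l, family = fam, x = x, y = y,
        dtx = ca * tx, dty = ca * ty, dz = dz, dc2 = ca^2,
        area = area, len = h / sa,
        eps0 = -height_loss * sa^2
      )
    }
  }
  df <- do.call(rbind, rows)
  G <- cbind(
    ux = df$dz * df$dtx / h,
    uy = df$dz * df$dty / h,
    uz = df$dz^2 / h,
    tx = df$dz^2 * df$y / h,
    ty = -df$dz^2 * df$x / h,
    tz = df$dz * (-df$dtx * df$y + df$dty * df$x) / h,
    b  = df$dc2 / r_m
  )
  list(meta = df, G = G, al = df$area * df$len, eps0 = df$eps0,
       layer = df$layer)
}

build_ligaments <- function(config, i, h, h_h) {
  zm0 <- config$ligament_z_margin
  out <- list()
  for (nm in names(config$ligaments)) {
    lg <- config$ligaments[[nm]]
    zm <- lg$z_margin %||% zm0
    sides <- if (isTRUE(lg$bilateral)) c(-1, 1) else 0
    for (sd in sides) {
      x <- if (sd == 0) lg$ml else sd * lg$ml
      O <- c(x, lg$ap, -h / 2 - zm)
      xi <- c(x, lg$ap, h / 2 + zm)
      L0 <- h_h + 2 * zm                     # healthy neutral distance
      out[[length(out) + 1]] <- list(
        name = nm, side = sd, O = O, xi = xi, L0 = L0,
        cs = lg$cs, slack = 0
      )
    }
  }
  if (i == 1 && !is.null(config$iliolumbar)) {
    il <- config$iliolumbar
    for (sd in c(-1, 1)) {
      O <- c(sd * il$origin[1], il$origin[2], -h / 2 + il$origin[3])
      xi <- c(sd * il$insertion[1], il$insertion[2], h / 2 + il$insertion[3])
      O_h <- c(O[1:2], -h_h / 2 + il$origin[3])
      xi_h <- c(xi[1:2], h_h / 2 + il$insertion[3])
      out[[length(out) + 1]] <- list(
        name = "ILL", side = sd, O = O, xi = xi,
        L0 = sqrt(sum((xi_h - O_h)^2)), cs = il$cs, slack = 0
      )
    }
  }
  out
}

# Facet contact: one unilateral penalty contact per side, with an oblique
# normal combining a circumferential component (resists axial rotation; the
# left facet engages in right rotation and vice versa) and a vertical
# component (posterior bony apposition in extension). The gap is measured in
# the segment's neutral configuration.
build_facets <- function(config, h) {
  fx <- config$facets$ml; fy <- config$facets$ap
  wc <- config$facets$weight_circumferential
  wz <- config$facets$weight_vertical
  r_left <- c(-fx, fy, h / 2)
  tau_left <- unit3(c(-fy, -fx, 0))          # z-hat x r, normalised
  n_left <- unit3(-wc * tau_left + c(0, 0, wz))
  n_right <- n_left * c(-1, 1, 1)
  r_right <- c(fx, fy, h / 2)
  list(
    list(side = "left", xi = r_left, n = n_left,
         gap = config$facets$gap, penalty = config$facets$penalty),
    list(side = "right", xi = r_right, n = n_right,
         gap = config$facets$gap, penalty = config$facets$penalty)
  )
}

#' Fibre sample directions for one layer of a disc
#'
#' @param disc A segment entry of a [build_default_spine()] geometry.
#' @param layer Layer index 1..5 (innermost to outermost).
#' @param n_samples Number of sample points per family (at least 4).
#' @param config Geometry config (for orientations and radial placement).
#' @return A matrix of unit direction vectors; crossed layers return both
#'   families, `2 * n_samples` rows.
#' @export
fiber_directions <- function(disc, layer, n_samples = 12,
                             config = default_spine_config()) {
  if (!layer %in% seq_along(config$fiber$orientations_deg)) {
    stop("layer index outside 1..", length(config$fiber$orientations_deg),
         call. = FALSE)
  }
  if (n_samples < 4) stop("n_samples must be at least 4", call. = FALSE)
  alpha <- deg2rad(config$fiber$orientations_deg[layer])
  rho <- config$fiber$layer_radial_scale[layer]
  al <- disc$a * rho; bl <- disc$b * rho
  phis <- (seq_len(n_samples) - 0.5) * 2 * pi / n_samples
  tn <- sqrt((al * sin(phis))^2 + (bl * cos(phis))^2)
  tx <- -al * sin(phis) / tn; ty <- bl * cos(phis) / tn
  dirs <- rbind(
    cbind(cos(alpha) * tx, cos(alpha) * ty, sin(alpha)),
    cbind(cos(alpha) * tx, cos(alpha) * ty, -sin(alpha))
  )
  dirs / sqrt(rowSums(dirs^2))
}

#' Endplate reference lines of a vertebra frame
#'
#' The frontal line joins the two mediolateral superior-endplate nodes, the
#' sagittal line the two anteroposterior ones; in the neutral configuration the
#' two are perpendicular.
#'
#' @param frame A vertebra (or sacrum) entry of a geometry, or any list with
#'   an `endplate_sup` component.
#' @return A list with `frontal` and `sagittal` reference lines (each a
#'   `ref_line`).
#' @export
reference_lines <- function(frame) {
  ep <- frame$endplate_sup
  if (is.null(ep)) stop("frame has no superior endplate nodes", call. = FALSE)
  list(
    frontal = ref_line(ep$frontal[1, ], ep$frontal[2, ]),
    sagittal = ref_line(ep$sagittal[1, ], ep$sagittal[2, ])
  )
}

#' @export
print.lumbokin_geometry <- function(x, ...) {
  cat("<lumbokin spine geometry: ", x$n_seg, " segment(s), ",
      paste(rev(x$vertebra_labels), collapse = "-"), "-sacrum>\n", sep = "")
  cat("  disc heights (mm):",
      paste(sprintf("%s=%.1f", x$levels,
                    vapply(x$segments, `[[`, numeric(1), "h")),
            collapse = ", "), "\n")
  if (!is.null(x$degeneration)) {
    cat("  degeneration at", x$degeneration$level %||% "L5-S1",
        "- height loss", x$degeneration$height_loss %||% 0, "\n")
  }
  invisible(x)
}

#' Export a geometry as JSON
#'
#' @param geometry A [build_default_spine()] result.
#' @param path Optional output path; if `NULL`, the JSON string is returned.
#' @export
geometry_json <- function(geometry, path = NULL) {
  dump <- list(
    levels = geometry$levels,
    vertebrae = lapply(geometry$vertebrae, function(v) {
      list(label = v$label, origin = v$origin, axes = v$axes,
           endplate_sup = v$endplate_sup)
    }),
    segments = lapply(geometry$segments, function(sg) {
      list(level = sg$level, height = sg$h, centroid = sg$centroid,
           areas = list(total = sg$A, nucleus = sg$A_n, annulus = sg$A_a),
           ligaments = lapply(sg$ligaments, function(lg) {
             lg[c("name", "side", "O", "xi", "L0", "cs", "slack")]
           }),
           facets = sg$facets)
    })
  )
  js <- jsonlite::toJSON(dump, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
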