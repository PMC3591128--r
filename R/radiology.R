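# Synthetic radiological verification cohort: per-subject per-level movement
# angles emulating the 25-subject X-ray study (flexion, extension and lateral
# bending; torsion has no radiological arm), with optional noisy landmark
# coordinates in the package's CSV dialect, cohort statistics, and the
# model-versus-radiology agreement report.

#' Packaged radiological reference statistics
#'
#' Per-vertebra cumulative angle means and standard deviations from the
#' 25-subject radiological study (flexion, extension, lateral bending).
#'
#' @return Tibble `vertebra, movement, mean_deg, sd_deg`.
#' @export
radiology_reference <- function() {
  f <- system.file("extdata", "table3_radiology.csv", package = "lumbokin",
                   mustWork = TRUE)
  tb <- utils::read.csv(f, stringsAsFactors = FALSE)
  tibble::as_tibble(tb)
}

#' Cohort specification for the synthetic radiological study
#'
#' @param n_subjects Number of subjects (default 25).
#' @param age_mean,age_range Age distribution (years), truncated normal.
#' @param weight_mean,weight_range Body weight (kg), truncated normal.
#' @param angle_stats Per-level angle means/SDs; defaults to the packaged
#'   radiological reference.
#' @param icc Intraclass correlation of levels within a subject: angles share
#'   a subject-level mobility factor before the monotone correction.
#' @param landmark_noise_sd Additive landmark coordinate noise, mm.
#' @param seed RNG seed for reproducible cohorts.
#' @return A `lumbokin_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25, age_mean = 27.4,
                        age_range = c(23, 33), weight_mean = 78.6,
                        weight_range = c(72.1, 81.7),
                        angle_stats = radiology_reference(), icc = 0.5,
                        landmark_noise_sd = 0.5, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (any(angle_stats$sd_deg < 0)) stop("SDs must be nonnegative", call. = FALSE)
  if (icc < 0 || icc > 1) stop("icc must lie in [0, 1]", call. = FALSE)
  if (age_mean < age_range[1] || age_mean > age_range[2] ||
      weight_mean < weight_range[1] || weight_mean > weight_range[2]) {
    stop("range must contain the mean", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, age_mean = age_mean,
                 age_range = age_range, weight_mean = weight_mean,
                 weight_range = weight_range, angle_stats = angle_stats,
                 icc = icc, landmark_noise_sd = landmark_noise_sd,
                 seed = as.integer(seed)),
            class = "lumbokin_cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic radiological cohort
#'
#' Per-subject cumulative angles are drawn per level from
#' `N(mean, sd)` with a shared subject-level mobility factor (intraclass
#' correlation `icc`), then corrected isotonically so that cumulative angles
#' decrease from L1 to L5 (and stay nonnegative). Deterministic given the
#' spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble `subject_id, age, weight, movement, vertebra, angle_deg`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "lumbokin_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ages <- rtruncnorm1(n, spec$age_mean, diff(spec$age_range) / 4,
                      spec$age_range[1], spec$age_range[2])
  weights <- rtruncnorm1(n, spec$weight_mean, diff(spec$weight_range) / 4,
                         spec$weight_range[1], spec$weight_range[2])
  stats <- spec$angle_stats
  movements <- unique(stats$movement)
  out <- vector("list", length(movements))
  for (k in seq_along(movements)) {
    mv <- movements[k]
    sub <- stats[stats$movement == mv, ]
    sub <- sub[order(match(sub$vertebra, c("L1", "L2", "L3", "L4", "L5"))), ]
    nl <- nrow(sub)
    zsub <- rnorm(n)                      # shared subject mobility factor
    z <- sqrt(spec$icc) * matrix(zsub, n, nl) +
      sqrt(1 - spec$icc) * matrix(rnorm(n * nl), n, nl)
    ang <- matrix(sub$mean_deg, n, nl, byrow = TRUE) +
      matrix(sub$sd_deg, n, nl, byrow = TRUE) * z
    ang <- t(apply(ang, 1, monotone_decreasing))
    out[[k]] <- tibble::tibble(
      subject_id = rep(seq_len(n), each = nl),
      age = rep(ages, each = nl),
      weight = rep(weights, each = nl),
      movement = mv,
      vertebra = rep(sub$vertebra, n),
      angle_deg = as.vector(t(ang))
    )
  }
  dplyr::bind_rows(out)
}

# pool-adjacent-violators fit, decreasing along the input order, floored at 0
monotone_decreasing <- function(x) {
  fit <- rev(isoreg(seq_along(x), rev(x))$yf)
  pmax(fit, 0)
}

#' Cohort statistics
#'
#' Per-vertebra sample mean and (n-1)-denominator standard deviation of the
#' cumulative angles for one movement.
#'
#' @param records A [generate_cohort()] tibble.
#' @param movement Movement tag.
#' @return An `AngleTable` tibble with `mean_deg`, `sd_deg`, `n`.
#' @export
cohort_stats <- function(records, movement) {
  sub <- records[records$movement == movement, ]
  if (!nrow(sub)) stop("no records for movement ", movement, call. = FALSE)
  if (length(unique(sub$subject_id)) < 2) {
    stop("cohort statistics need at least two subjects", call. = FALSE)
  }
  out <- sub |>
    dplyr::group_by(.data$vertebra) |>
    dplyr::summarise(mean_deg = mean(.data$angle_deg),
                     sd_deg = sd(.data$angle_deg),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$vertebra, c("L1", "L2", "L3", "L4", "L5")))
  out$movement <- movement
  class(out) <- c("lumbokin_angle_table", class(out))
  out
}

#' Model-versus-radiology agreement report
#'
#' Flags, per vertebra, whether the model angle falls within the cohort mean
#' +/- 1 SD (and 2 SD), with the absolute deviation.
#'
#' @param model An `AngleTable` of model angles (`cumulative_deg`).
#' @param cohort An `AngleTable` with `mean_deg` and `sd_deg` (from
#'   [cohort_stats()] or [radiology_reference()] filtered to one movement).
#' @return Tibble with deviations and within-band flags.
#' @export
agreement_report <- function(model, cohort) {
  if (!all(model$vertebra %in% cohort$vertebra)) {
    stop("model and cohort tables cover different levels", call. = FALSE)
  }
  j <- dplyr::inner_join(
    tibble::as_tibble(model)[, c("vertebra", "cumulative_deg")],
    tibble::as_tibble(cohort)[, c("vertebra", "mean_deg", "sd_deg")],
    by = "vertebra"
  )
  j$deviation_deg <- j$cumulative_deg - j$mean_deg
  j$within_1sd <- abs(j$deviation_deg) <= j$sd_deg
  j$within_2sd <- abs(j$deviation_deg) <= 2 * j$sd_deg
  j
}

#' Synthetic landmark coordinates for a cohort
#'
#' Writes each subject's endplate reference lines in the neutral position and
#' after each movement, rotated in the movement plane by the subject's angles
#' and contaminated with additive coordinate noise. The landmark dialect is
#' `subject_id, movement, vertebra, plane, x1, y1, z1, x2, y2, z2` (mm).
#'
#' @param records A [generate_cohort()] tibble.
#' @param geometry A spine geometry providing the neutral reference lines.
#' @param noise_sd Landmark noise SD in mm (0 for noise-free).
#' @param seed RNG seed for the noise.
#' @return A landmark tibble.
#' @export
cohort_landmarks <- function(records, geometry = build_default_spine(),
                             noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  axis_of <- list(FLX = c(1, 0, 0), EXT = c(1, 0, 0),
                  LB = c(0, 1, 0), AR = c(0, 0, 1))
  rows <- list()
  emit <- function(subject, movement, vertebra, plane, line) {
    noisy <- list(p1 = line$p1 + rnorm(3, 0, noise_sd),
                  p2 = line$p2 + rnorm(3, 0, noise_sd))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      subject_id = subject, movement = movement, vertebra = vertebra,
      plane = plane,
      x1 = noisy$p1[1], y1 = noisy$p1[2], z1 = noisy$p1[3],
      x2 = noisy$p2[1], y2 = noisy$p2[2], z2 = noisy$p2[3]
    )
  }
  idx_of <- setNames(seq_along(geometry$vertebra_labels),
                     geometry$vertebra_labels)
  for (s in unique(records$subject_id)) {
    done_neutral <- character()
    sub <- records[records$subject_id == s, ]
    for (k in seq_len(nrow(sub))) {
      vb <- geometry$vertebrae[[idx_of[[sub$vertebra[k]]]]]
      lines0 <- reference_lines(vb)
      mv <- sub$movement[k]
      plane <- movement_plane(mv)
      want <- if (plane == "FE") "sagittal" else "frontal"
      if (!sub$vertebra[k] %in% done_neutral) {
        for (pl in c("frontal", "sagittal")) {
          emit(s, "NEUTRAL", sub$vertebra[k], pl, lines0[[pl]])
        }
        done_neutral <- c(done_neutral, sub$vertebra[k])
      }
      ang <- deg2rad(sub$angle_deg[k] * movement_sign(mv))
      R <- rotvec_to_matrix(ang * axis_of[[mv]])
      ctr <- (lines0[[want]]$p1 + lines0[[want]]$p2) / 2
      rot <- ref_line(drop(R %*% (lines0[[want]]$p1 - ctr)) + ctr,
                      drop(R %*% (lines0[[want]]$p2 - ctr)) + ctr)
      emit(s, mv, sub$vertebra[k], want, rot)
    }
  }
  dplyr::bind_rows(rows)
}
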