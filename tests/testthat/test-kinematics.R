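test_that("line lengths and direction cosines follow the analytic geometry formulas", {
  expect_equal(line_length(ref_line(c(0, 0, 0), c(0, 0, 10))), 10)
  expect_equal(line_length(ref_line(c(1, 2, 2), c(0, 0, 0))), 3)
  expect_equal(line_length(ref_line(c(1, 1, 1), c(1, 1, 1))), 0)

  expect_equal(unname(direction_cosines(ref_line(c(0, 0, 0), c(0, 0, 5)))),
               c(0, 0, 1))
  dc <- direction_cosines(ref_line(c(0, 0, 0), c(1, 1, 0)))
  expect_equal(unname(dc), c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  neg <- direction_cosines(ref_line(c(1, 1, 0), c(0, 0, 0)))
  expect_equal(unname(neg), -unname(dc))
  set.seed(7)
  for (k in 1:20) {
    d <- direction_cosines(ref_line(rnorm(3), rnorm(3)))
    expect_equal(sum(d^2), 1, tolerance = 1e-12)
  }
  expect_error(direction_cosines(ref_line(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("relative plane angles recover constructed rotations with signs", {
  base <- ref_line(c(0, -15, 0), c(0, 15, 0))    # sagittal line
  expect_equal(relative_angle(base, base, "FE"), 0)
  R30 <- rotvec_to_matrix(c(deg2rad(30), 0, 0))
  rot <- ref_line(drop(R30 %*% base$p1), drop(R30 %*% base$p2))
  expect_equal(relative_angle(rot, base, "FE"), 30, tolerance = 1e-9)
  expect_equal(relative_angle(rot, base, "FE", method = "literal"), 30,
               tolerance = 1e-9)
  # extension is negative
  Rm <- rotvec_to_matrix(c(-deg2rad(12), 0, 0))
  ext <- ref_line(drop(Rm %*% base$p1), drop(Rm %*% base$p2))
  expect_equal(relative_angle(ext, base, "FE"), -12, tolerance = 1e-9)
  # 90 degrees in-plane
  R90 <- rotvec_to_matrix(c(deg2rad(90), 0, 0))
  perp <- ref_line(drop(R90 %*% base$p1), drop(R90 %*% base$p2))
  expect_equal(abs(relative_angle(perp, base, "FE")), 90, tolerance = 1e-9)

  # frontal-line planes: lateral bending and axial rotation
  fbase <- ref_line(c(-20, 0, 0), c(20, 0, 0))
  Rlb <- rotvec_to_matrix(c(0, deg2rad(14), 0))
  flb <- ref_line(drop(Rlb %*% fbase$p1), drop(Rlb %*% fbase$p2))
  expect_equal(relative_angle(flb, fbase, "LB"), 14, tolerance = 1e-9)
  Rar <- rotvec_to_matrix(c(0, 0, deg2rad(8)))
  far <- ref_line(drop(Rar %*% fbase$p1), drop(Rar %*% fbase$p2))
  expect_equal(relative_angle(far, fbase, "AR"), 8, tolerance = 1e-9)
})

test_that("literal and projected variants differ only out of plane", {
  # both lines tilted 5 degrees out of the sagittal plane, 20 degrees apart
  tilt <- rotvec_to_matrix(c(0, 0, deg2rad(5)))
  base <- ref_line(c(0, -15, 0), c(0, 15, 0))
  b2 <- ref_line(drop(tilt %*% base$p1), drop(tilt %*% base$p2))
  R20 <- rotvec_to_matrix(c(deg2rad(20), 0, 0))
  a2 <- ref_line(drop(tilt %*% R20 %*% base$p1), drop(tilt %*% R20 %*% base$p2))
  lit <- relative_angle(a2, b2, "FE", method = "literal")
  proj <- relative_angle(a2, b2, "FE", method = "projected")
  expect_gt(abs(lit - proj), 1e-6)     # literal feels the out-of-plane tilt
  expect_equal(proj, 20, tolerance = 0.2)
  # invariance to scaling and in-plane translation
  sc <- ref_line(b2$p1 * 3, b2$p2 * 3)
  expect_equal(relative_angle(a2, sc, "FE"), relative_angle(a2, b2, "FE"),
               tolerance = 1e-10)
})

test_that("measured state angles match a rotation-matrix oracle", {
  # rigid 10-degree flexion of the whole lumbar spine
  R10 <- rotvec_to_matrix(c(deg2rad(10), 0, 0))
  poses <- rep(list(list(R = R10, u = c(0, 0, 0))), 5)
  st <- list(poses = poses, loadcase = list(movement = "FLX"))
  at <- measure_state(st, geom_full, movement = "FLX")
  expect_equal(at$cumulative_deg, rep(10, 5), tolerance = 1e-9)
  expect_equal(at$segmental_deg, c(0, 0, 0, 0, 10), tolerance = 1e-9)

  # random in-plane poses vs axis-angle extraction
  set.seed(42)
  for (mv in c("FLX", "LB", "AR")) {
    axis <- abs(movement_axis(mv))
    angs <- cumsum(runif(5, -2, 4))
    poses <- lapply(angs, function(a)
      list(R = rotvec_to_matrix(deg2rad(a) * axis), u = rnorm(3)))
    st <- list(poses = poses, loadcase = list(movement = mv))
    at <- measure_state(st, geom_full, movement = mv)
    oracle <- vapply(poses, function(p) {
      tr <- (sum(diag(p$R)) - 1) / 2
      rad2deg(acos(clamp(tr, -1, 1)))
    }, numeric(1))
    expect_equal(abs(rev(at$cumulative_deg)), oracle, tolerance = 0.05)
  }
})

test_that("cumulative angles are the running sum of segmental angles", {
  st <- solve_equilibrium(load_case("FLX"), geom_full, card_h)
  at <- measure_state(st, geom_full)
  cum_from_seg <- rev(cumsum(rev(at$segmental_deg)))
  expect_equal(at$cumulative_deg, cum_from_seg, tolerance = 0.05)
})
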