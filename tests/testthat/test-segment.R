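test_that("neutral segment state carries no load in any constituent", {
  w <- segment_wrench(seg_state(), geom_full, card_h)
  expect_lt(max(abs(w$force)), 1e-9)
  expect_lt(max(abs(w$moment)), 1e-9)
  expect_lt(max(abs(as.matrix(w$breakdown[, c("Fx", "Fy", "Fz", "Mx", "My", "Mz")]))),
            1e-9)
})

test_that("axial compression is resisted by disc, not by tension-only elements", {
  w <- segment_wrench(seg_state(t = c(0, 0, -1)), geom_full, card_h)
  expect_gt(w$force[3], 0)     # restoring force pushes the upper vertebra up
  bd <- w$breakdown
  lig <- bd[grepl("^lig_", bd$constituent), ]
  expect_lt(max(abs(lig$energy_J)), 1e-12)          # all ligaments slack
  fib <- bd[grepl("^fiber", bd$constituent), ]
  expect_true(all(fib$energy_J >= 0))
})

test_that("flexion loads the posterior column, extension the anterior", {
  wf <- segment_wrench(seg_state(r = c(5, 0, 0)), geom_full, card_h)
  bd <- wf$breakdown
  eJ <- setNames(bd$energy_J, bd$constituent)
  expect_gt(eJ[["lig_ISL"]], 0)
  expect_gt(eJ[["lig_SSL"]], 0)
  expect_gt(eJ[["lig_LF"]], 0)
  expect_gt(eJ[["lig_PLL"]], 0)
  expect_equal(eJ[["lig_ALL"]], 0)
  expect_lt(wf$moment[1], 0)                       # restoring, opposes flexion

  we <- segment_wrench(seg_state(r = c(-5, 0, 0)), geom_full, card_h)
  eJe <- setNames(we$breakdown$energy_J, we$breakdown$constituent)
  expect_gt(eJe[["lig_ALL"]], 0)
  expect_equal(eJe[["lig_ISL"]], 0)
  expect_equal(eJe[["lig_SSL"]], 0)
  expect_gt(we$moment[1], 0)
})

test_that("flexion tensions posterior fibres and extension anterior fibres", {
  m <- lumbokin:::segment_model(geom_full$segments[[3]], card_h)
  eps_f <- drop(m$fib_G[, 1:6] %*% c(0, 0, 0, deg2rad(5), 0, 0)) + m$fib_eps0
  meta <- geom_full$segments[[3]]$fib$meta
  expect_true(all(meta$y[eps_f > 1e-9] > 0))   # +y posterior
  eps_e <- drop(m$fib_G[, 1:6] %*% c(0, 0, 0, -deg2rad(5), 0, 0)) + m$fib_eps0
  expect_true(all(meta$y[eps_e > 1e-9] < 0))
})

test_that("pure axial rotation tensions a single helix family", {
  m <- lumbokin:::segment_model(geom_full$segments[[2]], card_h)
  meta <- geom_full$segments[[2]]$fib$meta
  for (sgn in c(1, -1)) {
    eps <- drop(m$fib_G[, 1:6] %*% c(0, 0, 0, 0, 0, sgn * deg2rad(3))) +
      m$fib_eps0
    fams <- unique(meta$family[eps > 1e-9])
    expect_length(fams, 1)
  }
})

test_that("the wrench is mirror-symmetric about the sagittal plane", {
  # mirror x -> -x maps (ux, tx unchanged sign rules): lateral bending and
  # axial rotation flip, flexion is preserved
  q <- c(0.4, -0.2, -0.5, deg2rad(2), deg2rad(3), deg2rad(1.5))
  qm <- q * c(-1, 1, 1, 1, -1, -1)
  w1 <- segment_wrench(seg_state(t = q[1:3], r = rad2deg(q[4:6])),
                       geom_full, card_h)
  w2 <- segment_wrench(seg_state(t = qm[1:3], r = rad2deg(qm[4:6])),
                       geom_full, card_h)
  expect_equal(w2$force, w1$force * c(-1, 1, 1), tolerance = 1e-9)
  expect_equal(w2$moment, w1$moment * c(1, -1, -1), tolerance = 1e-9)
})

test_that("the restoring wrench is the exact gradient of a scalar energy", {
  m <- lumbokin:::segment_model(geom_full$segments[[4]], card_h)
  set.seed(11)
  for (k in 1:5) {
    q <- c(runif(3, -0.5, 0.5), runif(3, -0.06, 0.06))
    ev <- lumbokin:::segment_eval(m, q)
    gfd <- numeric(6)
    for (j in 1:6) {
      h <- 1e-6
      qp <- q; qp[j] <- qp[j] + h
      qm_ <- q; qm_[j] <- qm_[j] - h
      gfd[j] <- (lumbokin:::segment_eval(m, qp, deriv = FALSE)$E -
                   lumbokin:::segment_eval(m, qm_, deriv = FALSE)$E) / (2 * h)
    }
    expect_equal(unname(ev$g), gfd, tolerance = 1e-5)
  }
  # closed loading loop returns zero net work (energy is a state function)
  qA <- c(0, 0, -0.3, 0.02, 0, 0)
  EA1 <- lumbokin:::segment_eval(m, qA, deriv = FALSE)$E
  for (qmid in list(c(0.2, 0, -0.4, 0.04, 0.01, 0), c(0, 0.3, -0.2, 0, 0.03, 0.01))) {
    invisible(lumbokin:::segment_eval(m, qmid, deriv = FALSE))
  }
  EA2 <- lumbokin:::segment_eval(m, qA, deriv = FALSE)$E
  expect_equal(EA1, EA2, tolerance = 1e-12)
})

test_that("tangent stiffness matches a Richardson-extrapolated oracle and orders cards", {
  st <- seg_state("L5-S1", t = c(0, 0, -0.3), r = c(1, 0.5, 0.5))
  K1 <- tangent_stiffness(st, geom_full, card_h, h = 2e-5)
  K2 <- tangent_stiffness(st, geom_full, card_h, h = 1e-5)
  K_rich <- (4 * K2 - K1) / 3
  expect_lt(max(abs(K2 - K_rich)) / max(abs(K_rich)), 1e-5)
  # positive definite on the compression-rotation subspace at a compressed state
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # degenerated card: lower axial stiffness (compressible nucleus), L5-S1
  Kd <- tangent_stiffness(st, geom_full, card_d, h = 1e-5)
  expect_lt(Kd[3, 3], K2[3, 3])
  expect_error(tangent_stiffness(st, geom_full, card_h, h = 0), "positive")
})

test_that("nucleus volume change is zero at neutral and bounded by the penalty", {
  expect_equal(unname(nucleus_volume_change(seg_state(), geom_full, card_h)), 0)
  vc <- nucleus_volume_change(seg_state(t = c(0, 0, -0.5)), geom_full, card_h)
  expect_lt(abs(vc), 1e-4)         # incompressible penalty tolerance
  vce <- nucleus_volume_change(seg_state(t = c(0, 0, -0.5)), geom_full,
                               comparison_card())
  expect_lt(vce, 0)                # compressible card loses volume
})
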