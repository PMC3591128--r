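test_that("default spine has the expected anatomy counts and bookkeeping", {
  expect_equal(geom_full$n_seg, 5)
  expect_equal(length(geom_full$vertebrae), 5)
  # eight ligament families at L5-S1 (with iliolumbar), seven above
  fams <- lapply(geom_full$segments, function(sg)
    sort(unique(vapply(sg$ligaments, `[[`, character(1), "name"))))
  expect_setequal(fams[[1]], c("ALL", "PLL", "LF", "ISL", "SSL", "ITL", "CL", "ILL"))
  for (i in 2:5) {
    expect_setequal(fams[[i]], c("ALL", "PLL", "LF", "ISL", "SSL", "ITL", "CL"))
  }
  # column height bookkeeping
  expect_equal(sum(vapply(geom_full$segments, `[[`, numeric(1), "h")) +
                 5 * geom_full$config$body_height,
               geom_full$config$total_height)
  # origins strictly increasing in z from sacrum to L1
  zs <- c(geom_full$sacrum$origin[3],
          vapply(geom_full$vertebrae, function(v) v$origin[3], numeric(1)))
  expect_true(all(diff(zs) > 0))
  # frames orthonormal
  for (v in geom_full$vertebrae) {
    expect_lt(max(abs(crossprod(v$axes) - diag(3))), 1e-10)
  }
})

test_that("facet pairs mirror about the sagittal plane", {
  for (sg in geom_full$segments) {
    l <- sg$facets[[1]]; r <- sg$facets[[2]]
    expect_lt(max(abs(l$xi * c(-1, 1, 1) - r$xi)), 1e-9)
    expect_lt(max(abs(l$n * c(-1, 1, 1) - r$n)), 1e-9)
    expect_equal(l$gap, r$gap)
  }
})

test_that("invalid geometry dimensions are rejected with the field name", {
  cfg <- unclass(default_spine_config())
  cfg$disc_heights[2] <- 0
  expect_error(build_default_spine(cfg), "disc_heights")
  cfg <- unclass(default_spine_config())
  cfg$nucleus_area_fraction <- 1.2
  expect_error(build_default_spine(cfg), "nucleus_area_fraction")
})

test_that("fibre directions keep the layer orientation and crossed pairing", {
  disc <- geom_full$segments[[3]]
  cfg <- geom_full$config
  for (l in c(1, 3, 5)) {
    dirs <- fiber_directions(disc, l, n_samples = 8, config = cfg)
    expect_equal(nrow(dirs), 16)   # both families
    ang <- asin(abs(dirs[, 3]))
    expect_lt(max(abs(ang - deg2rad(cfg$fiber$orientations_deg[l]))), 1e-8)
    expect_equal(sum(dirs[, 3] > 0), 8)
    expect_lt(max(abs(sqrt(rowSums(dirs^2)) - 1)), 1e-12)
  }
  # orientations within the anatomical band, monotone inner -> outer
  expect_true(all(cfg$fiber$orientations_deg >= 35 &
                    cfg$fiber$orientations_deg <= 80))
  expect_true(all(diff(cfg$fiber$orientations_deg) >= 0))
  # hypothetical 0-degree layer: purely circumferential directions
  cfg0 <- cfg
  cfg0$fiber$orientations_deg[1] <- 0
  dirs0 <- fiber_directions(disc, 1, n_samples = 8, config = cfg0)
  expect_lt(max(abs(dirs0[, 3])), 1e-12)
  expect_error(fiber_directions(disc, 7, config = cfg), "layer")
})

test_that("reference lines are perpendicular and transform rigidly", {
  ln <- reference_lines(geom_full$vertebrae[[3]])
  df <- unit3(ln$frontal$p2 - ln$frontal$p1)
  ds <- unit3(ln$sagittal$p2 - ln$sagittal$p1)
  expect_lt(abs(sum(df * ds)), 1e-9)

  v <- geom_full$vertebrae[[3]]
  shift <- c(3, -2, 7)
  vt <- v
  vt$endplate_sup <- lapply(v$endplate_sup, function(m) sweep(m, 2, -shift))
  lt <- reference_lines(vt)
  expect_equal(unit3(lt$sagittal$p2 - lt$sagittal$p1), ds, tolerance = 1e-12)

  R <- rotvec_to_matrix(c(deg2rad(10), 0, 0))
  vr <- v
  vr$endplate_sup <- lapply(v$endplate_sup, function(m) t(R %*% t(m)))
  lr <- reference_lines(vr)
  expect_equal(unit3(lr$sagittal$p2 - lr$sagittal$p1), drop(R %*% ds),
               tolerance = 1e-12)

  bad <- list(endplate_sup = list(frontal = rbind(c(0, 0, 0), c(0, 0, 0)),
                                  sagittal = rbind(c(0, 0, 0), c(1, 0, 0))))
  lines <- reference_lines(bad)
  expect_error(direction_cosines(lines$frontal), "degenerate")
})

test_that("geometry JSON dump is well-formed", {
  js <- geometry_json(geom_toy)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$levels, "L5-S1")
  expect_equal(length(parsed$vertebrae$label), 1)
})
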