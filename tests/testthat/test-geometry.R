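# Axis construction and the division angle theta.

test_that("oocyte-basal axis passes through both centres, errors when coincident", {
  a <- oocyte_basal_axis(c(0, 0), c(3, 4))
  expect_equal(a$direction, c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(oocyte_basal_axis(c(2, 0), c(5, 0))$direction, c(1, 0))
  expect_error(oocyte_basal_axis(c(1, 1), c(1, 1), cell_id = "c7"),
               class = "gcorient_degenerate_geometry")
  expect_error(oocyte_basal_axis(c(1, 1), c(1, 1), cell_id = "c7"), "c7")
})

test_that("anaphase spindle axis joins the chromatid-group centroids", {
  expect_equal(spindle_axis_anaphase(rbind(c(0, 0)), rbind(c(0, 2)))$direction, c(0, 1))
  ax <- spindle_axis_anaphase(rbind(c(0, 0), c(2, 0)), rbind(c(1, 3), c(1, 5)))
  expect_equal(ax$direction, c(0, 1))
  expect_equal(ax$origin, c(1, 2))
  expect_error(spindle_axis_anaphase(rbind(c(0, 0)), rbind(c(0, 0))),
               class = "gcorient_degenerate_geometry")
  expect_error(spindle_axis_anaphase(list(), rbind(c(0, 0))),
               class = "gcorient_degenerate_geometry")
})

test_that("metaphase spindle axis is perpendicular to the plate", {
  expect_equal(abs(spindle_axis_metaphase(rbind(c(0, 0), c(0, 4)))$direction),
               c(1, 0))
  d45 <- spindle_axis_metaphase(rbind(c(0, 0), c(1, 1)))$direction
  expect_equal(abs(d45), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(sign(prod(d45)), -1)  # perpendicular to the 45-degree line
  # >2 collinear points: orthogonal regression recovers the exact line
  d3 <- spindle_axis_metaphase(rbind(c(0, 0), c(2, 0), c(4, 0)))$direction
  expect_equal(abs(d3), c(0, 1), tolerance = 1e-12)
  expect_error(spindle_axis_metaphase(rbind(c(1, 1), c(1, 1), c(1, 1))),
               class = "gcorient_degenerate_geometry")
})

test_that("division angle folds into [0, 90] and is symmetric", {
  e1 <- axis2d(c(0, 0), c(1, 0))
  expect_equal(division_angle(e1, axis2d(c(0, 0), c(1, 0))), 0)
  expect_equal(division_angle(e1, axis2d(c(0, 0), c(0, 1))), 90)
  expect_equal(division_angle(e1, axis2d(c(0, 0), c(1, 1))), 45, tolerance = 1e-12)
  # folding: planted alpha in [0, 180) recovers min(alpha, 180 - alpha)
  for (alpha in seq(0, 179, by = 7.3)) {
    d <- axis2d(c(0, 0), c(cos(alpha * pi / 180), sin(alpha * pi / 180)))
    expect_equal(division_angle(e1, d), min(alpha, 180 - alpha), tolerance = 1e-9)
  }
  # symmetry and reversal invariance
  a <- axis2d(c(0, 0), c(2, 1)); b <- axis2d(c(5, 5), c(-1, 3))
  expect_equal(division_angle(a, b), division_angle(b, a))
  expect_equal(division_angle(a, b),
               division_angle(axis2d(c(0, 0), -a$direction), b), tolerance = 1e-12)
})

test_that("angles_for_section recovers hand-planted angles and skips degenerate cells", {
  s30 <- section_one_cell(30, azimuth_deg = 110, phase = "metaphase")
  s60 <- section_one_cell(60, azimuth_deg = 245, phase = "anaphase")
  expect_equal(angles_for_section(s30)$theta_deg, 30, tolerance = 1e-9)
  expect_equal(angles_for_section(s60)$theta_deg, 60, tolerance = 1e-9)

  empty <- follicle_section("e", c(0, 0), lamina_circle(), list(), oocyte_radius = 20)
  expect_equal(nrow(angles_for_section(empty)), 0L)

  # one degenerate cell among three: two records plus one skip report
  good1 <- section_one_cell(10, 20)$cells[[1]]
  good2 <- section_one_cell(80, 200)$cells[[1]]
  good2$cell_id <- "c2"
  bad <- mitotic_cell("cbad", c(30, 5), "anaphase",
                      landmarks_a = rbind(c(30, 5)), landmarks_b = rbind(c(30, 5)))
  sec <- follicle_section("mix", c(0, 0), lamina_circle(),
                          list(good1, good2, bad), oocyte_radius = 20)
  out <- angles_for_section(sec)
  expect_equal(nrow(out), 2L)
  skipped <- attr(out, "skipped")
  expect_equal(nrow(skipped), 1L)
  expect_equal(skipped$cell_id, "cbad")
})

test_that("section invariant violations abort before any angle is computed", {
  cell <- section_one_cell(30)$cells[[1]]
  # oocyte centre outside the lamina
  expect_error(
    follicle_section("bad", c(200, 0), lamina_circle(), list(cell), oocyte_radius = 20),
    class = "gcorient_validation_error"
  )
  # cell centre inside the oocyte disc
  inner <- mitotic_cell("ci", c(5, 0), "anaphase",
                        landmarks_a = rbind(c(4, 0)), landmarks_b = rbind(c(6, 0)))
  expect_error(
    follicle_section("bad2", c(0, 0), lamina_circle(), list(inner), oocyte_radius = 20),
    class = "gcorient_validation_error"
  )
  expect_error(
    follicle_section("bad3", c(0, 0), lamina_circle(), layer_count = 3),
    class = "gcorient_validation_error"
  )
})

test_that("theta is invariant under rigid motions and annotation reversals", {
  for (theta in c(5, 30, 57.5, 88)) {
    for (phase in c("metaphase", "anaphase")) {
      sec <- section_one_cell(theta, azimuth_deg = 77, phase = phase)
      base <- angles_for_section(sec)$theta_deg
      expect_equal(base, theta, tolerance = 1e-9)
      moved <- transform_section(sec, phi_deg = 123.4, shift = c(-57, 19))
      expect_equal(angles_for_section(moved)$theta_deg, base, tolerance = 1e-9)
    }
  }
  # swapping anaphase groups / reversing plate order leaves theta unchanged
  sec <- section_one_cell(41, phase = "anaphase")
  cell <- sec$cells[[1]]
  swapped <- follicle_section("f", c(0, 0), lamina_circle(), list(
    mitotic_cell("c1", cell$centre, "anaphase",
                 landmarks_a = cell$landmarks_b, landmarks_b = cell$landmarks_a)
  ), oocyte_radius = 20)
  expect_equal(angles_for_section(swapped)$theta_deg,
               angles_for_section(sec)$theta_deg, tolerance = 1e-12)
  secm <- section_one_cell(41, phase = "metaphase")
  cellm <- secm$cells[[1]]
  revm <- follicle_section("f", c(0, 0), lamina_circle(), list(
    mitotic_cell("c1", cellm$centre, "metaphase",
                 landmarks = cellm$landmarks[2:1, ])
  ), oocyte_radius = 20)
  expect_equal(angles_for_section(revm)$theta_deg,
               angles_for_section(secm)$theta_deg, tolerance = 1e-12)
})

test_that("metaphase and anaphase annotations of the same spindle agree", {
  for (theta in seq(0, 90, by = 12.5)) {
    tm <- angles_for_section(section_one_cell(theta, 33, "metaphase"))$theta_deg
    ta <- angles_for_section(section_one_cell(theta, 33, "anaphase"))$theta_deg
    expect_equal(tm, ta, tolerance = 1e-9)
  }
})
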