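# Step parameters, Zp, A/B classification, RMSD, overlap areas and
# grooves.

test_that("step parameters are rigid-motion invariant", {
  m <- built_duplex()
  sp <- step_parameters(m)
  sp2 <- step_parameters(rigid_move(m))
  for (col in c("twist", "roll", "slide", "rise", "Zp"))
    expect_equal(sp2[[col]], sp[[col]], tolerance = 1e-6, info = col)
  g <- groove_widths(built("pY(a)"))
  g2 <- groove_widths(rigid_move(built("pY(a)")))
  expect_equal(g2, g, tolerance = 1e-6)
})

test_that("Zp matches the closed-form value for the uninclined B build", {
  # with zero inclination the mid-step frame z is the global z, so
  # Zp = p_z(local) + rise/2 exactly: an independent closed form
  m <- built_duplex()
  p_local_z <- triplexkit:::.p_local_B[3L]
  expect_equal(zp(m)$mean, p_local_z + 3.38 / 2, tolerance = 1e-6)
  # per-step values are uniform in an ideal fiber
  expect_lt(diff(range(zp(m)$per_step)), 1e-6)
})

test_that("form classification applies the slide/Zp thresholds", {
  expect_identical(classify_form(built_duplex())$aggregate, "B")
  expect_identical(classify_form(built_duplex(form = "A"))$aggregate, "A")
  # explicit threshold logic on synthetic parameter tables
  fake <- data.frame(slide = c(-1.2, 0.1, -1.2), Zp = c(2.0, 0.2, 1.0))
  expect_identical(classify_form(fake)$per_step,
                   c("A", "B", "intermediate"))
  # Zp extracted from a triplex's duplex part stays in the B camp
  expect_lt(zp(built("pY(a)"))$mean, 0.5)
})

test_that("RMSD is zero under rigid motion and matches the quaternion oracle", {
  m <- built_duplex()
  expect_equal(rmsd_fit(m, m), 0, tolerance = 1e-9)
  expect_equal(rmsd_fit(m, rigid_move(m)), 0, tolerance = 1e-9)
  expect_equal(rmsd_fit(m, rigid_move(m), "backbone"), 0,
               tolerance = 1e-9)
  # toy 4-atom systems against the independent Horn quaternion method
  set.seed(7)
  for (k in 1:10) {
    P <- matrix(rnorm(12), 4L, 3L)
    Q <- P + matrix(rnorm(12, 0, 0.4), 4L, 3L)
    expect_equal(triplexkit:::kabsch(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-6)
  }
  # atom-count mismatch is an error
  m2 <- m; m2$atoms <- m2$atoms[-1L, ]
  expect_error(rmsd_fit(m, m2), "pair up")
})

test_that("RMSD separates the A and B references as the forms require", {
  b <- built_duplex()
  a <- built_duplex(form = "A")
  hyb_a <- built_duplex(form = "A", chem = c("RNA", "DNA"))
  expect_lt(rmsd_fit(hyb_a, a, "backbone"),
            rmsd_fit(hyb_a, b, "backbone"))
})

test_that("polygon clipping agrees with the Monte-Carlo sampling oracle", {
  # perfectly eclipsed polygons give the polygon area
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(triplexkit:::.poly_area(
    triplexkit:::.clip_polygon(sq, sq)), 4)
  # disjoint polygons give zero
  far <- sq; far[, 1L] <- far[, 1L] + 10
  expect_equal(triplexkit:::.poly_area(
    triplexkit:::.clip_polygon(sq, far)), 0)
  # random small displacements of convex hulls vs MC sampling
  set.seed(21)
  for (k in 1:5) {
    pts <- matrix(rnorm(24, sd = 2), ncol = 2L)
    p1 <- triplexkit:::.hull2d(pts)
    p2 <- sweep(p1, 2L, runif(2L, -1, 1), "+")
    exact <- triplexkit:::.poly_area(triplexkit:::.clip_polygon(p1, p2))
    approx <- mc_overlap_area(p1, p2, seed = k)
    expect_lt(abs(exact - approx) / max(exact, 1e-9), 0.02)
  }
})

test_that("step overlap areas behave on built duplexes", {
  ov_b <- step_overlap_area(built_duplex())
  expect_length(ov_b$per_step, 8L)
  expect_true(all(ov_b$per_step >= 0))
  expect_equal(ov_b$total, sum(ov_b$per_step[ov_b$inner_steps]))
  # A-form slide/displacement changes the stacking overlap
  ov_a <- step_overlap_area(built_duplex(form = "A"))
  expect_false(isTRUE(all.equal(ov_a$total, ov_b$total)))
  full <- step_overlap_area(built_duplex(), inner_only = FALSE)
  expect_equal(full$total, sum(full$per_step))
})

test_that("groove widths identify the narrow parallel-strand groove", {
  for (lab in c("pY(a)", "pR-S(a)", "pR(+)-S(a)")) {
    g <- groove_widths(built(lab))
    expect_identical(names(which.min(g)), "third_purine", info = lab)
  }
  expect_named(groove_widths(built("apY(a)")),
               c("third_purine", "third_pyrimidine", "duplex_minor"))
})
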