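# Tilt angles, effective areas and the stacking totals.

test_that("plane normals are correct, equivariant and noise-tolerant", {
  m <- built("pY(a)")
  # construct a flat ring in the xy-plane
  flat <- m
  sel <- flat$atoms$strand == "C" & flat$atoms$res == 1L
  ring <- triplexkit:::.base_rings[["C"]]
  ring_sel <- sel & flat$atoms$elety %in% ring
  th <- seq(0, 2 * pi, length.out = sum(ring_sel) + 1L)[-1L]
  flat$atoms[ring_sel, c("x", "y", "z")] <-
    cbind(cos(th), sin(th), 0)
  nrm <- base_plane_normal(flat, "C", 1L)
  expect_equal(abs(nrm[3L]), 1, tolerance = 1e-12)
  # equivariance under rigid rotation
  R <- triplexkit:::rot_axis(c(1, 1, 0), 40)
  n0 <- base_plane_normal(m, "C", 2L)
  n1 <- base_plane_normal(rigid_move(m, c(1, 1, 0), 40, c(0, 0, 0)),
                          "C", 2L)
  expect_equal(as.numeric(R %*% n0), n1, tolerance = 1e-9)
  # jittered ring stays within 5 degrees
  set.seed(99)
  noisy <- m
  nsel <- noisy$atoms$strand == "C" & noisy$atoms$res == 2L
  noisy$atoms[nsel, c("x", "y", "z")] <-
    noisy$atoms[nsel, c("x", "y", "z")] +
    matrix(rnorm(3L * sum(nsel), 0, 0.05), ncol = 3L)
  ang <- acos(min(1, abs(sum(base_plane_normal(noisy, "C", 2L) * n0))))
  expect_lt(ang * 180 / pi, 5)
})

test_that("alpha angles fold to [0, 90] and track constructed rotations", {
  m <- built("pY(a)")
  # coplanar as built
  expect_lt(alpha_angle(m, 5L), 3)
  # rotate the third-strand base of plane 5 about an in-plane axis
  r5 <- triplexkit:::plane_to_third(m$spec, 9L)[5L]
  rot_base <- function(model, deg) {
    sel <- model$atoms$strand == "C" & model$atoms$res == r5 &
      !model$atoms$elety %in% c("P", "O4'", "C2'", "C1'")
    xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    nrm <- base_plane_normal(model, "C", r5)
    axis <- if (abs(nrm[1L]) < 0.9) triplexkit:::vunit(
      triplexkit:::vcross(nrm, c(1, 0, 0))) else triplexkit:::vunit(
        triplexkit:::vcross(nrm, c(0, 1, 0)))
    R <- triplexkit:::rot_axis(axis, deg)
    model$atoms[sel, c("x", "y", "z")] <-
      sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr, "+")
    model
  }
  a30 <- alpha_angle(rot_base(m, 30), 5L)
  expect_equal(a30, 30, tolerance = 1.5)
  # antiparallel normals fold to the same angle
  a210 <- alpha_angle(rot_base(m, 210), 5L)
  expect_equal(a210, 30, tolerance = 1.5)
})

test_that("effective areas follow the closed form with both forcing rules", {
  expect_equal(effective_area("T", 0, 1), 4.95)
  expect_equal(effective_area("C", 0, 2), 4.95)
  expect_equal(effective_area("A", 0, 1), 8.29)
  expect_equal(effective_area("G", 0, 1), 8.29)
  expect_equal(effective_area("A", 45, 2), 0)
  expect_equal(effective_area("G", 60, 2), 0)
  expect_equal(effective_area("A", 0, 0), 0)
  expect_equal(effective_area("T", 30, 1),
               4.95 * (cos(pi / 6) - sin(pi / 6)))
  # continuous and strictly decreasing on [0, 45], zero at and past 45
  a <- effective_area("G", seq(0, 45, by = 1), 1)
  expect_true(all(diff(a) < 0))
  expect_equal(a[46L], 0)
  expect_lt(a[45L], 0.3)
  expect_equal(effective_area("G", 45 + 1e-9, 1), 0)
})

test_that("step stacking is the geometric mean and sums correctly", {
  st <- effective_stacking(c(4.95, 8.29))
  expect_equal(st$total, sqrt(4.95 * 8.29), tolerance = 1e-12)
  expect_equal(round(st$total, 2), 6.41)
  # any zero area kills both adjacent steps
  z <- effective_stacking(c(5, 0, 7, 7))
  expect_equal(z$per_step[1:2], c(0, 0))
  expect_gt(z$per_step[3L], 0)
  # uniform areas over nine planes
  u <- effective_stacking(rep(3.7, 9L))
  expect_equal(u$total, 8 * 3.7, tolerance = 1e-12)
  expect_warning(one <- effective_stacking(5), "fewer than two")
  expect_equal(one$total, 0)
})

test_that("S_eff is rigid-motion invariant and attains its bound when ideal", {
  m <- built("pY(a)")
  sm <- stacking_metrics(m)
  sm_mov <- stacking_metrics(rigid_move(m))
  expect_equal(sm_mov$s_eff, sm$s_eff, tolerance = 1e-6)
  expect_equal(sm_mov$h_eff, sm$h_eff)
  # coplanar fully-bonded build sits essentially at the upper bound
  mm <- metric_maxima(m$spec)
  expect_lte(sm$s_eff, mm$s_max + 1e-9)
  expect_gt(sm$s_eff, 0.9 * mm$s_max)
  # a detached strand scores exactly zero however well stacked
  far <- m
  sel <- far$atoms$strand == "C"
  far$atoms$x[sel] <- far$atoms$x[sel] + 10
  smf <- stacking_metrics(far)
  expect_true(all(smf$per_plane$alpha < 5, na.rm = TRUE))
  expect_equal(smf$s_eff, 0)
  expect_equal(smf$h_eff, 0)
})

test_that("terminal-plane exclusion trims totals consistently", {
  m <- built("pY(a)")
  full <- stacking_metrics(m)
  trim <- stacking_metrics(m, exclude_terminal = TRUE)
  expect_lt(trim$h_eff, full$h_eff)
  expect_lt(trim$s_eff, full$s_eff)
  mm <- metric_maxima(m$spec, exclude_terminal = TRUE)
  expect_equal(trim$h_eff, mm$h_max)
  expect_gt(trim$s_eff, 0.9 * mm$s_max)
})
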