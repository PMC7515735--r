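# Hydrogen-bond detection, the effective bond number and pattern
# classification.

test_that("detection respects both cutoffs on controlled geometry", {
  expect_equal(nrow(detect_hbonds(probe_geometry_model(3.4, 180))), 1L)
  expect_equal(nrow(detect_hbonds(probe_geometry_model(3.6, 180))), 0L)
  expect_equal(nrow(detect_hbonds(probe_geometry_model(3.2, 120))), 0L)
  expect_equal(nrow(detect_hbonds(probe_geometry_model(3.2, 150))), 1L)
})

test_that("a geometry sweep recovers the cutoffs exactly", {
  # distance threshold at linear geometry
  d_grid <- seq(3.30, 3.70, by = 0.01)
  hit <- vapply(d_grid, function(d)
    nrow(detect_hbonds(probe_geometry_model(d, 180))) > 0L, TRUE)
  expect_equal(max(d_grid[hit]), 3.50)
  expect_equal(min(d_grid[!hit]), 3.51)
  # angle threshold at a compliant distance
  a_grid <- seq(120, 170, by = 0.5)
  hita <- vapply(a_grid, function(a)
    nrow(detect_hbonds(probe_geometry_model(3.0, a))) > 0L, TRUE)
  expect_equal(min(a_grid[hita]), 140)
  expect_equal(max(a_grid[!hita]), 139.5)
})

test_that("records carry plane annotations and deterministic order", {
  m <- built("pY(a)")
  b <- detect_hbonds(m)
  expect_true(all(b$distance <= 3.5))
  expect_true(all(b$angle >= 140))
  # Watson-Crick bonds are duplex-internal, same plane
  wc <- b[b$duplex_internal, ]
  expect_gt(nrow(wc), 0L)
  expect_true(all(wc$same_plane))
  expect_identical(b, detect_hbonds(m))
})

test_that("H_eff counts only same-plane third-strand bonds", {
  m <- built("pY(a)")
  hb <- effective_hbonds(m)
  expect_equal(hb$total, 18L)
  expect_equal(unname(hb$per_plane), rep(2L, 9L))
  # strand moved one helical step: identical bond geometry, but every
  # bond now crosses planes, so H_eff collapses to zero
  shifted <- shift_third_strand_one_plane(m)
  b <- detect_hbonds(shifted)
  cross <- b[b$third_strand_involved, ]
  expect_gt(nrow(cross), 10L)
  expect_true(all(!cross$same_plane))
  expect_equal(effective_hbonds(shifted, bonds = b)$total, 0L)
  # strand far out of the groove: nothing at all
  far <- m
  sel <- far$atoms$strand == "C"
  far$atoms$x[sel] <- far$atoms$x[sel] + 10
  expect_equal(effective_hbonds(far)$total, 0L)
})

test_that("H_eff agrees with the brute-force all-pairs oracle", {
  for (lab in c("pY(a)", "pR(a)", "pR(+)-S(a)", "apY(s)", "apR-S(a)")) {
    m <- built(lab)
    pkg <- effective_hbonds(m)
    orc <- brute_force_heff(m)
    expect_equal(pkg$total, orc$total, info = lab)
    expect_equal(unname(pkg$per_plane), orc$per_plane, info = lab)
  }
  # and on a jittered conformation
  tr <- generate_trajectory(parse_label("pY(a)"),
                            scenario_config("stable", n_frames = 3L,
                                            seed = 5L))
  m3 <- traj_frame(tr, 3L)
  expect_equal(effective_hbonds(m3)$total, brute_force_heff(m3)$total)
})

test_that("H_eff is rigid-motion invariant and bounded by the template", {
  for (lab in c("pY(a)", "pR(a)")) {
    m <- built(lab)
    expect_equal(effective_hbonds(rigid_move(m))$total,
                 effective_hbonds(m)$total, info = lab)
  }
  # per-plane ceiling: number of chemically possible donor/acceptor
  # pairings for that triplet
  m <- built("pY(a)")
  per <- effective_hbonds(m)$per_plane
  st <- step_types(m$spec)
  caps <- vapply(seq_len(9L), function(i) {
    rr <- m$residues[m$residues$strand == "C" &
                       m$residues$res == st$third_res[i], ]
    dn3 <- length(triplexkit:::hb_donors(rr$base, rr$protonated))
    # loose chemical ceiling: donors+acceptors of the third base
    ac3 <- length(triplexkit:::hb_acceptors(rr$base, rr$protonated))
    (dn3 + ac3) * 2L
  }, 0L)
  expect_true(all(per <= caps))
})

test_that("plane patterns classify as initial, variant, novel or none", {
  m <- built("pY(a)")
  b <- detect_hbonds(m)
  st <- step_types(m$spec)
  for (i in c(1L, 2L)) {
    pb <- b[!is.na(b$donor_plane) & b$donor_plane == i &
              !is.na(b$acceptor_plane) & b$acceptor_plane == i, ]
    cl <- classify_plane_pattern(pb, st$triplet[i], st$bond_class[i])
    expect_identical(cl$flag, "initial", info = i)
  }
  # empty set
  none <- classify_plane_pattern(b[0L, ], "C+.G:C", "H")
  expect_identical(none$pattern, "none")
  # a named variant: the duplex-crossing adenine pattern on an A.A:T
  # plane, assembled synthetically
  vb <- data.frame(
    donor_strand = c("C", "A"), donor_res = c(2L, 2L),
    donor_atom = c("N6", "N6"), acceptor_strand = c("B", "C"),
    acceptor_res = c(8L, 2L), acceptor_atom = c("O4", "N1"),
    donor_plane = 2L, acceptor_plane = 2L,
    third_strand_involved = TRUE, same_plane = TRUE,
    stringsAsFactors = FALSE)
  cl <- classify_plane_pattern(vb, "A.A:T", "H")
  expect_identical(cl$flag, "variant")
  expect_identical(cl$pattern, "duplex-crossing-N6-O4+N1-N6")
  # an unseen combination reports verbatim
  nb <- vb[1L, ]; nb$acceptor_atom <- "O2"
  expect_match(classify_plane_pattern(nb, "A.A:T", "H")$pattern,
               "^novel:")
})

test_that("pattern timelines report occupancies that sum to one", {
  spec <- parse_label("pY(a)")
  tr <- generate_trajectory(spec, scenario_config("stable",
                                                  n_frames = 1L,
                                                  seed = 1L))
  tl <- pattern_timeline(tr, plane = 5L)
  expect_length(tl$timeline, 1L)
  expect_equal(sum(tl$occupancy), 1)
  expect_identical(names(tl$occupancy)[1L], "initial H-type")
  # synthetic 2-state alternation: alternate intact/detached frames
  tr2 <- generate_trajectory(spec, scenario_config("stable",
                                                   n_frames = 4L,
                                                   jitter_sigma = 0,
                                                   seed = 1L))
  sel <- tr2$model$atoms$strand == "C"
  idx <- which(rep(sel, each = 3L))
  tr2$xyz[c(2L, 4L), idx] <- tr2$xyz[c(2L, 4L), idx] + 30
  tl2 <- pattern_timeline(tr2, plane = 5L)
  expect_equal(unname(sort(tl2$occupancy)), c(0.5, 0.5))
  expect_setequal(names(tl2$occupancy), c("initial H-type", "none"))
  # stable scenario: the dominant pattern outweighs any minor ones
  tr3 <- generate_trajectory(spec, scenario_config("stable",
                                                   n_frames = 20L,
                                                   seed = 2L))
  tl3 <- pattern_timeline(tr3, plane = 5L)
  expect_identical(names(tl3$occupancy)[1L], "initial H-type")
  expect_gt(tl3$occupancy[1L], 0.5)
})
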