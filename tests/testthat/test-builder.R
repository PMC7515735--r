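# De-novo construction of duplexes and triplexes.

test_that("duplex builder produces paired antiparallel strands", {
  dx <- built_duplex()
  expect_equal(nrow(dx$residues), 18L)
  expect_equal(as.vector(table(dx$residues$strand)[c("A", "B")]),
               c(9L, 9L))
  expect_identical(dx$residues$base[dx$residues$strand == "A"],
                   rep(c("G", "A", "A"), 3L))
  # complementary pyrimidine strand generated automatically (5'->3')
  expect_identical(dx$residues$base[dx$residues$strand == "B"],
                   rep(c("T", "T", "C"), 3L))
  expect_error(build_duplex("GAX"), "only G and A")
  # Watson-Crick pairing: duplex-internal bonds on every plane
  b <- detect_hbonds(dx)
  expect_gte(nrow(b), 2L * 9L)
})

test_that("hybrid duplexes carry U and O2' on the RNA strand", {
  hy <- built_duplex(form = "A", chem = c("RNA", "DNA"))
  rna <- hy$atoms$chem == "RNA"
  expect_true(all(hy$atoms$strand[rna] == "A"))
  expect_true("O2'" %in% hy$atoms$elety[rna])
  expect_false("O2'" %in% hy$atoms$elety[!rna])
  hy2 <- built_duplex(chem = c("DNA", "RNA"))
  expect_identical(sort(unique(hy2$residues$base[hy2$residues$strand ==
                                                   "B"])), c("C", "U"))
})

test_that("built forms classify as requested for all chemistry combinations", {
  for (chem in list(c("DNA", "DNA"), c("RNA", "DNA"), c("RNA", "RNA"))) {
    for (form in c("B", "A")) {
      m <- built_duplex(form = form, chem = chem)
      expect_identical(classify_form(m)$aggregate, form,
                       info = paste(form, paste(chem, collapse = ":")))
    }
  }
})

test_that("built B-form matches its generation parameters", {
  sp <- step_parameters(built_duplex())
  expect_lt(abs(mean(sp$twist) - 36), 0.5)
  expect_lt(abs(mean(sp$rise) - 3.38), 0.05)
  expect_gt(mean(sp$slide), -0.8)
  expect_lt(mean(sp$Zp, na.rm = TRUE), 0.5)
  spa <- step_parameters(built_duplex(form = "A"))
  expect_lt(mean(spa$slide), -0.8)
  expect_gt(mean(spa$Zp, na.rm = TRUE), 1.5)
})

test_that("triplex builder honors repeats, register and protonation", {
  tri <- built("pY(a)")
  expect_equal(nrow(tri$residues), 27L)
  expect_equal(as.vector(table(tri$residues$strand)[c("A", "B", "C")]),
               c(9L, 9L, 9L))
  # protonated cytosines carry the extra N3 proton
  protC <- tri$residues$strand == "C" & tri$residues$base == "C"
  expect_true(all(tri$residues$protonated[protC]))
  h3 <- tri$atoms$strand == "C" & tri$atoms$elety == "H3" &
    tri$atoms$base == "C"
  expect_equal(sum(h3), 3L)
  # adenine protonation only where the register meets a G
  trp <- built("pR(+)-S(a)")
  protA <- trp$residues$strand == "C" & trp$residues$protonated
  expect_equal(sum(protA), 3L)
  expect_true(all(trp$residues$base[protA] == "A"))
  # one repeat also builds
  small <- suppressWarnings(build_triplex(parse_label("pY(a)"),
                                          n_repeats = 1L))
  expect_equal(nrow(small$residues), 9L)
})

test_that("syn builds put the third-strand chi in the syn range", {
  tri <- built("apY(s)")
  chis <- vapply(1:9, function(r) chi_torsion(tri, "C", r), 0)
  expect_true(all(chis > -90 & chis <= 90))
})

test_that("initial tilt angles are small and template bonds formed", {
  tri <- built("pY(a)")
  sm <- stacking_metrics(tri)
  expect_true(all(sm$per_plane$alpha < 45, na.rm = TRUE))
  expect_true(all(sm$per_plane$alpha < 5, na.rm = TRUE))
  # all 18 template bonds of pY(a) are satisfied as built
  ref <- idealize_hbonds(tri)
  v <- attr(ref, "violations")
  expect_equal(nrow(v), 18L)
  expect_true(all(v$satisfied))
  # Hoogsteen-type bonds on built pR(a) are geometrically satisfiable
  prr <- idealize_hbonds(built("pR(a)"))
  expect_true(all(attr(prr, "violations")$distance < 3.5))
})

test_that("builds are deterministic and clash-checked", {
  a <- suppressWarnings(build_triplex(parse_label("pR(a)")))
  b <- suppressWarnings(build_triplex(parse_label("pR(a)")))
  expect_identical(a$atoms, b$atoms)
  # B-form starting models respect the steric floor
  for (lab in c("pY(a)", "pY(s)", "pR(a)", "apR-S(a)", "pR(+)-S(a)"))
    expect_equal(count_clashes(built(lab)), 0L, info = lab)
})

test_that("built planes carry the taxonomy's residue identities", {
  for (lab in c("pY(a)", "pR-S(a)", "apR(+)(a)")) {
    tri <- built(lab)
    st <- step_types(tri$spec)
    for (i in which(!is.na(st$third_res))) {
      rr <- tri$residues[tri$residues$strand == "C" &
                           tri$residues$res == st$third_res[i], ]
      expect_identical(rr$base, st$third_base[i], info = paste(lab, i))
      expect_identical(rr$protonated, st$protonated[i],
                       info = paste(lab, i))
    }
  }
})

test_that("hydrogen-bond idealization repairs a displaced third strand", {
  tri <- built("pY(a)")
  sel <- tri$atoms$strand == "C"
  moved <- tri
  moved$atoms[sel, c("x", "y", "z")] <-
    moved$atoms[sel, c("x", "y", "z")] + rep(2 / sqrt(3), 3L)
  d0 <- attr(suppressWarnings(
    idealize_hbonds(moved, max_iter = 0L)), "violations")$distance
  fixed <- suppressWarnings(idealize_hbonds(moved))
  d1 <- attr(fixed, "violations")$distance
  # violations strictly decrease overall
  expect_lt(sum((d1 - 2.9)^2), sum((d0 - 2.9)^2))
  expect_true(mean(abs(d1 - 2.9)) < mean(abs(d0 - 2.9)))
  # an already-satisfied model is a fixed point within tolerance
  again <- idealize_hbonds(tri)
  expect_lt(max(abs(as.matrix(again$atoms[, c("x", "y", "z")]) -
                      as.matrix(tri$atoms[, c("x", "y", "z")]))), 0.3)
})
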