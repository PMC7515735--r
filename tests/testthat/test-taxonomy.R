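# Enumeration, labelling and the counterpart symmetries of the triplex
# taxonomy.

test_that("DNA enumeration has the right composition", {
  specs <- enumerate_dna_triplexes()
  tab <- specs_table(specs)
  expect_length(specs, 16L)
  expect_equal(anyDuplicated(tab$label), 0L)
  expect_equal(sum(tab$third_class == "R"), 12L)
  expect_equal(sum(tab$third_class == "Y"), 4L)
  expect_equal(sum(tab$glycosidic == "anti"), 8L)
  expect_equal(sum(tab$third_class == "R" & tab$glycosidic == "anti"), 6L)
  # 8 base topologies before the anti/syn doubling
  expect_equal(length(unique(sub("\\((a|s)\\)$", "", tab$label))), 8L)
  # deterministic order
  expect_identical(tab$label,
                   specs_table(enumerate_dna_triplexes())$label)
  # every Y spec carries protonated cytosines
  expect_true(all(tab$protonation[tab$third_class == "Y"] == "cytosine"))
})

test_that("hybrid enumeration gives the three collapsed R-loop cases", {
  hs <- enumerate_hybrid_triplexes()
  expect_length(hs, 3L)
  tab <- specs_table(hs)
  expect_setequal(tab$label, c("apY(a)", "pR(a)", "pR(+)-S(a)"))
  expect_true(all(tab$glycosidic == "anti"))
  # exactly one RNA strand each; the two DNA strands antiparallel
  for (s in hs) {
    expect_equal(sum(c(s$duplex_purine_chem, s$duplex_pyrimidine_chem,
                       s$third_chem) == "RNA"), 1L)
    dna_duplex_strand <- if (s$duplex_purine_chem == "DNA") "purine"
      else "pyrimidine"
    # third strand parallel to the RNA purine => antiparallel to the
    # DNA pyrimidine; antiparallel to the DNA purine directly otherwise
    if (dna_duplex_strand == "purine")
      expect_equal(s$orientation, "antiparallel")
  }
  # crossed with two starting forms: six build requests
  expect_equal(length(hs) * 2L, 6L)
})

test_that("labels round-trip and malformed labels name the bad token", {
  for (s in c(enumerate_dna_triplexes(), enumerate_hybrid_triplexes())) {
    p <- parse_label(s$label)
    expect_identical(format_label(p), s$label)
    expect_identical(p$orientation, s$orientation)
    expect_identical(p$shifted, s$shifted)
    expect_identical(p$glycosidic, s$glycosidic)
  }
  spec <- parse_label("pR(+)-S(a)")
  expect_identical(spec$third_class, "R")
  expect_identical(spec$orientation, "parallel")
  expect_true(spec$shifted)
  expect_identical(spec$protonation, "adenine")
  expect_identical(spec$glycosidic, "anti")
  py <- parse_label("pY(a)")
  expect_identical(py$protonation, "cytosine")
  expect_false(py$shifted)
  expect_error(parse_label("qZ(x)"), "orientation prefix")
  expect_error(parse_label("pZ(a)"), "strand class")
  expect_error(parse_label("pR(a)x"), "unexpected token")
  expect_error(parse_label("pY(+)(a)"), "R strands only")
  # grammatical but outside the canonical set
  expect_error(parse_label("pR(+)(a)"), "outside the canonical")
  expect_s3_class(parse_label("pR(+)(a)", strict = FALSE),
                  "triplex_spec")
})

test_that("counterpart maps are involutions with the published pairing", {
  specs <- enumerate_dna_triplexes()
  for (s in specs) {
    expect_identical(
      conformational_counterpart(conformational_counterpart(s))$label,
      s$label)
    expect_identical(
      directional_counterpart(directional_counterpart(s))$label,
      s$label)
  }
  expect_identical(conformational_counterpart(parse_label("pY(a)"))$label,
                   "apY(s)")
  expect_identical(conformational_counterpart(parse_label("pR(a)"))$label,
                   "apR-S(s)")
  expect_identical(directional_counterpart(parse_label("pY(a)"))$label,
                   "apY(a)")
  expect_identical(directional_counterpart(parse_label("pR(a)"))$label,
                   "apR-S(a)")
  expect_error(conformational_counterpart(
    enumerate_hybrid_triplexes()[[1L]]), "pure-DNA")
})

test_that("bond classes follow orientation x glycosidic", {
  expect_identical(bond_class(parse_label("pY(a)")), "H")
  expect_identical(bond_class(parse_label("apY(a)")), "RH")
  expect_identical(bond_class(parse_label("apY(s)")), "H")
  expect_identical(bond_class(parse_label("pR(s)")), "RH")
})

# the published triplet-type summary, encoded verbatim as label sets
.triplet_table <- list(
  list("C+.G:C", "H",  c("pY(a)", "apY(s)")),
  list("C+.G:C", "RH", c("pY(s)", "apY(a)")),
  list("G.G:C",  "H",  c("pR(a)", "apR-S(s)")),
  list("G.G:C",  "RH", c("pR(s)", "apR-S(a)")),
  list("A.G:C",  "H",  c("pR-S(a)", "apR(s)")),
  list("A.G:C",  "RH", c("pR-S(s)", "apR(a)")),
  list("A+.G:C", "H",  c("pR(+)-S(a)", "apR(+)(s)")),
  list("A+.G:C", "RH", c("pR(+)-S(s)", "apR(+)(a)")),
  list("T.A:T",  "H",  c("pY(a)", "apY(s)")),
  list("T.A:T",  "RH", c("pY(s)", "apY(a)")),
  list("G.A:T",  "H",  c("pR-S(a)", "pR(+)-S(a)", "apR(s)", "apR(+)(s)")),
  list("G.A:T",  "RH", c("pR-S(s)", "pR(+)-S(s)", "apR(a)", "apR(+)(a)")),
  list("A.A:T",  "H",  c("pR(a)", "pR-S(a)", "pR(+)-S(a)", "apR(s)",
                         "apR-S(s)", "apR(+)(s)")),
  list("A.A:T",  "RH", c("pR(s)", "pR-S(s)", "pR(+)-S(s)", "apR(a)",
                         "apR-S(a)", "apR(+)(a)"))
)

test_that("step types reproduce the triplet summary table", {
  specs <- enumerate_dna_triplexes()
  st_of <- lapply(specs, step_types)
  names(st_of) <- vapply(specs, `[[`, "", "label")
  for (row in .triplet_table) {
    triplet <- row[[1L]]; cls <- row[[2L]]; members <- row[[3L]]
    for (lab in names(st_of)) {
      st <- st_of[[lab]]
      has <- any(!is.na(st$triplet) & st$triplet == triplet &
                   st$bond_class == cls)
      expect_identical(has, lab %in% members,
                       info = paste(triplet, cls, lab))
    }
  }
})

test_that("step-type sequences follow the register", {
  st <- step_types(parse_label("pY(a)"))
  expect_identical(st$triplet,
                   rep(c("C+.G:C", "T.A:T", "T.A:T"), 3L))
  expect_true(all(st$bond_class == "H"))
  st2 <- step_types(parse_label("pR(s)"))
  expect_true(all(st2$bond_class == "RH"))
  # shifted purine register leaves one plane bare
  st3 <- step_types(parse_label("pR-S(a)"))
  expect_equal(sum(is.na(st3$third_res)), 1L)
  # protonated adenines sit exactly on the G planes
  st4 <- step_types(parse_label("pR(+)-S(a)"))
  expect_true(all(st4$protonated[!is.na(st4$triplet) &
                                   grepl("^A", st4$third_base) &
                                   grepl("G:C", st4$triplet)]))
})

test_that("conformational counterparts share step types, directional flip the class", {
  for (s in enumerate_dna_triplexes()) {
    st <- step_types(s)
    cc <- step_types(conformational_counterpart(s))
    dc <- step_types(directional_counterpart(s))
    # shifted registers trim one terminal plane: compare triplet types
    expect_setequal(unique(stats::na.omit(st$triplet)),
                    unique(stats::na.omit(cc$triplet)))
    expect_identical(unique(stats::na.omit(st$bond_class)),
                     unique(stats::na.omit(cc$bond_class)))
    expect_setequal(unique(stats::na.omit(st$triplet)),
                    unique(stats::na.omit(dc$triplet)))
    expect_true(unique(stats::na.omit(st$bond_class)) !=
                  unique(stats::na.omit(dc$bond_class)))
  }
})
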