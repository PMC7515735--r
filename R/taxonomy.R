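# Enumeration, labelling and symmetry relations of the GAA/TTC triple
# helices: 16 pure-DNA topologies (8 base schemes x anti/syn third strand)
# and the 3 DNA.RNA:DNA hybrid (collapsed R-loop) topologies.

#' Triplex topology specification
#'
#' A `triplex_spec` describes one triple-helix topology symbolically:
#' which strand chemistry forms the Watson-Crick duplex, whether the third
#' strand is the all-purine GAA (`R`) or all-pyrimidine TTC (`Y`) repeat,
#' its orientation relative to the duplex purine strand, its register
#' (shifted by one nucleotide or not), the protonation convention and the
#' glycosidic state of the third-strand bases.
#'
#' Pyrimidine third strands always carry N3-protonated cytosines (the
#' unprotonated cases cannot maintain Hoogsteen-type bonds to guanine and
#' are excluded from the canonical set); purine third strands may carry an
#' N1-protonated adenine on the position that meets a G:C pair.
#'
#' @param third_class `"R"` (GAA third strand) or `"Y"` (TTC).
#' @param orientation `"parallel"` or `"antiparallel"`, relative to the
#'   duplex purine (GAA) strand.
#' @param shifted logical; third-strand register offset by one nucleotide.
#' @param protonation `"none"`, `"cytosine"` or `"adenine"`.
#' @param glycosidic `"anti"` or `"syn"` (third-strand bases).
#' @param duplex_purine_chem,duplex_pyrimidine_chem `"DNA"` or `"RNA"`:
#'   chemistry of the two duplex strands (`"RNA"` for one of them makes a
#'   hybrid triplex).
#' @return An object of class `triplex_spec`.
#' @seealso [enumerate_dna_triplexes()], [parse_label()], [step_types()]
#' @export
triplex_spec <- function(third_class, orientation, shifted, protonation,
                         glycosidic,
                         duplex_purine_chem = "DNA",
                         duplex_pyrimidine_chem = "DNA") {
  third_class <- match.arg(third_class, c("R", "Y"))
  orientation <- match.arg(orientation, c("parallel", "antiparallel"))
  protonation <- match.arg(protonation, c("none", "cytosine", "adenine"))
  glycosidic <- match.arg(glycosidic, c("anti", "syn"))
  duplex_purine_chem <- match.arg(duplex_purine_chem, c("DNA", "RNA"))
  duplex_pyrimidine_chem <- match.arg(duplex_pyrimidine_chem, c("DNA", "RNA"))
  stopifnot(is.logical(shifted), length(shifted) == 1L)
  if (third_class == "Y" && protonation != "cytosine")
    stop("Y third strands always carry protonated cytosines")
  if (third_class == "R" && protonation == "cytosine")
    stop("R third strands have no cytosines to protonate")
  spec <- structure(
    list(third_class = third_class, orientation = orientation,
         shifted = shifted, protonation = protonation,
         glycosidic = glycosidic,
         duplex_purine_chem = duplex_purine_chem,
         duplex_pyrimidine_chem = duplex_pyrimidine_chem,
         third_chem = "DNA"),
    class = "triplex_spec")
  spec$label <- format_label(spec)
  spec
}

is_hybrid <- function(spec) {
  spec$duplex_purine_chem == "RNA" || spec$duplex_pyrimidine_chem == "RNA"
}

#' @export
print.triplex_spec <- function(x, ...) {
  duplex <- sprintf("%s(%s):%s(%s)",
                    tolower(substr(x$duplex_purine_chem, 1, 1)), "GAA",
                    tolower(substr(x$duplex_pyrimidine_chem, 1, 1)),
                    if (x$duplex_pyrimidine_chem == "RNA") "UUC" else "TTC")
  third <- if (x$third_class == "R") "d(GAA)" else "d(TTC+)"
  cat(sprintf("<triplex_spec> %s  [%s . %s, %s, %s%s, protonation: %s]\n",
              x$label, third, duplex, x$orientation, x$glycosidic,
              if (x$shifted) ", shifted" else "", x$protonation))
  invisible(x)
}

#' Format a triplex specification as its canonical label
#'
#' The label grammar is `[p|ap][R|Y][(+)]?[-S]?[(a)|(s)]`: orientation
#' prefix, third-strand class, optional adenine-protonation marker,
#' optional register shift, glycosidic state. Cytosine protonation of Y
#' strands is implicit.
#'
#' @param spec A [triplex_spec()].
#' @return A single character label, e.g. `"pR(+)-S(a)"`.
#' @export
format_label <- function(spec) {
  stopifnot(inherits(spec, "triplex_spec"))
  paste0(if (spec$orientation == "parallel") "p" else "ap",
         spec$third_class,
         if (spec$protonation == "adenine") "(+)" else "",
         if (spec$shifted) "-S" else "",
         if (spec$glycosidic == "anti") "(a)" else "(s)")
}

#' Parse a triplex label
#'
#' Inverse of [format_label()]: bijective on the enumerated DNA set.
#' Malformed labels raise an error naming the offending token.
#'
#' @param label Character label, e.g. `"pY(a)"`.
#' @param strict If `TRUE` (default) the parsed spec must belong to the
#'   canonical enumerated set ([enumerate_dna_triplexes()]); with
#'   `strict = FALSE` any grammatical label is accepted (an extension
#'   point for hypothetical topologies outside the canonical 16).
#' @return A [triplex_spec()].
#' @export
parse_label <- function(label, strict = TRUE) {
  stopifnot(is.character(label), length(label) == 1L)
  rest <- label
  eat <- function(pattern) {
    m <- regmatches(rest, regexpr(pattern, rest))
    if (length(m)) rest <<- substring(rest, nchar(m) + 1L)
    m
  }
  ori <- eat("^ap|^p")
  if (!length(ori)) stop("malformed triplex label '", label,
                         "': expected orientation prefix 'p' or 'ap'")
  cls <- eat("^[RY]")
  if (!length(cls)) stop("malformed triplex label '", label,
                         "': expected strand class 'R' or 'Y' at '",
                         rest, "'")
  prot <- length(eat("^\\(\\+\\)")) > 0L
  shifted <- length(eat("^-S")) > 0L
  gly <- eat("^\\((a|s)\\)")
  if (!length(gly)) stop("malformed triplex label '", label,
                         "': expected glycosidic suffix '(a)' or '(s)' at '",
                         rest, "'")
  if (nzchar(rest)) stop("malformed triplex label '", label,
                         "': unexpected token '", rest, "'")
  if (prot && cls == "Y")
    stop("malformed triplex label '", label,
         "': '(+)' marks adenine protonation and applies to R strands only")
  spec <- triplex_spec(
    third_class = cls,
    orientation = if (ori == "p") "parallel" else "antiparallel",
    shifted = shifted,
    protonation = if (cls == "Y") "cytosine" else
      if (prot) "adenine" else "none",
    glycosidic = if (gly == "(a)") "anti" else "syn")
  if (strict) {
    known <- vapply(enumerate_dna_triplexes(), `[[`, "", "label")
    if (!spec$label %in% known)
      stop("label '", label, "' is grammatical but outside the canonical ",
           "enumerated set; use strict = FALSE to allow it")
  }
  spec
}

# The 8 base DNA topologies (before anti/syn doubling), as label stems
.base_topologies <- function() {
  list(
    list("Y", "parallel",     FALSE, "cytosine"),
    list("Y", "antiparallel", FALSE, "cytosine"),
    list("R", "parallel",     FALSE, "none"),
    list("R", "antiparallel", FALSE, "none"),
    list("R", "parallel",     TRUE,  "none"),
    list("R", "antiparallel", TRUE,  "none"),
    list("R", "parallel",     TRUE,  "adenine"),
    list("R", "antiparallel", FALSE, "adenine"))
}

#' Enumerate the 16 pure-DNA GAA/TTC triplex topologies
#'
#' The eight non-equivalent triple-helix schemes (pY, apY, pR, apR, pR-S,
#' apR-S, pR(+)-S, apR(+)), each with the third strand in all-anti or
#' all-syn glycosidic state, give 16 distinct starting conformations:
#' 4 with a pyrimidine (TTC) third strand and 12 with a purine (GAA) one.
#'
#' Enumeration order is lexicographic by (class, orientation, shift,
#' protonation, glycosidic), so listings are reproducible.
#'
#' @return A list of 16 [triplex_spec()] objects with unique labels.
#' @export
enumerate_dna_triplexes <- function() {
  specs <- list()
  for (b in .base_topologies()) {
    for (g in c("anti", "syn")) {
      specs[[length(specs) + 1L]] <-
        triplex_spec(b[[1L]], b[[2L]], b[[3L]], b[[4L]], g)
    }
  }
  key <- vapply(specs, function(s) {
    paste(s$third_class, s$orientation, s$shifted, s$protonation,
          s$glycosidic, sep = "|")
  }, "")
  specs[order(key)]
}

#' Enumerate the 3 hybrid DNA.RNA:DNA (collapsed R-loop) triplexes
#'
#' With the two DNA strands of an R-loop kept antiparallel and the third
#' strand bonding to the purine strand of the hybrid duplex, only three
#' hybrid triplexes can form: d(TTC+).d(GAA):r(UUC) (apY),
#' d(GAA).r(GAA):d(TTC) (pR) and d(GA+A).r(GAA):d(TTC) (pR(+)-S), all
#' with the third strand in anti conformation.
#'
#' @return A list of 3 [triplex_spec()] objects.
#' @export
enumerate_hybrid_triplexes <- function() {
  list(
    triplex_spec("Y", "antiparallel", FALSE, "cytosine", "anti",
                 duplex_purine_chem = "DNA", duplex_pyrimidine_chem = "RNA"),
    triplex_spec("R", "parallel", FALSE, "none", "anti",
                 duplex_purine_chem = "RNA", duplex_pyrimidine_chem = "DNA"),
    triplex_spec("R", "parallel", TRUE, "adenine", "anti",
                 duplex_purine_chem = "RNA", duplex_pyrimidine_chem = "DNA"))
}

.assert_enumerated_dna <- function(spec) {
  if (!inherits(spec, "triplex_spec")) stop("not a triplex_spec")
  if (is_hybrid(spec))
    stop("counterpart maps are defined on the enumerated pure-DNA set")
  known <- vapply(enumerate_dna_triplexes(), `[[`, "", "label")
  if (!spec$label %in% known)
    stop("spec '", spec$label, "' is not in the enumerated DNA set")
}

#' Conformational counterpart of a triplex
#'
#' Two triplexes are conformational counterparts when they share the same
#' triple base steps but the third strand runs in the opposite direction
#' with all glycosidic angles flipped (e.g. pY(a) and apY(s)). They share
#' the same initial hydrogen-bond pattern and hence bond class. For purine
#' third strands the register toggles together with the direction
#' (pR pairs with apR-S, etc.); the pairing follows the published triplet
#' summary table.
#'
#' @param spec A [triplex_spec()] from the enumerated DNA set.
#' @return The counterpart [triplex_spec()]. The map is an involution.
#' @export
conformational_counterpart <- function(spec) {
  .assert_enumerated_dna(spec)
  triplex_spec(
    spec$third_class,
    if (spec$orientation == "parallel") "antiparallel" else "parallel",
    if (spec$third_class == "R") !spec$shifted else spec$shifted,
    spec$protonation,
    if (spec$glycosidic == "anti") "syn" else "anti")
}

#' Directional counterpart of a triplex
#'
#' Two triplexes are directional counterparts when they present the same
#' triple base steps with the third strand direction reversed but the
#' glycosidic state kept, so that every Hoogsteen-type (H) plane becomes
#' reverse-Hoogsteen-type (RH) and vice versa (e.g. pY(a) and apY(a)).
#' As with the conformational map, the register of purine third strands
#' toggles with the direction so that the triplet steps are preserved.
#'
#' @inheritParams conformational_counterpart
#' @return The counterpart [triplex_spec()]. The map is an involution.
#' @export
directional_counterpart <- function(spec) {
  .assert_enumerated_dna(spec)
  triplex_spec(
    spec$third_class,
    if (spec$orientation == "parallel") "antiparallel" else "parallel",
    if (spec$third_class == "R") !spec$shifted else spec$shifted,
    spec$protonation,
    spec$glycosidic)
}

# Sequences -------------------------------------------------------------

purine_seq <- function(n_repeats) rep(c("G", "A", "A"), n_repeats)

# complement of the purine strand, indexed by plane (1..n along the
# purine strand 5'->3'); the pyrimidine strand itself runs antiparallel
complement_base <- function(base, chem = "DNA") {
  unname(c(G = "C", A = if (chem == "RNA") "U" else "T")[base])
}
# Third-strand 5'->3' sequence. GAA for R strands. Y strands are TTC
# repeats; the repeat phase is chosen so that every cytosine meets a
# duplex guanine at the spec's register: CTT repeats for the parallel
# orientation, TTC for the antiparallel one (which reads CTT against the
# purine strand after reversal).
third_seq <- function(spec, n_repeats) {
  if (spec$third_class == "R") purine_seq(n_repeats)
  else if (spec$orientation == "parallel") rep(c("C", "T", "T"), n_repeats)
  else rep(c("T", "T", "C"), n_repeats)
}

# plane index (1..n along the duplex purine strand, 5'->3') ->
# third-strand residue index (1..n in the third strand's own 5'->3' order),
# NA where the register leaves a plane without a third-strand partner
# (shifted purine registers leave one overhanging residue and one bare
# plane; pyrimidine strands pair every plane).
plane_to_third <- function(spec, n) {
  i <- seq_len(n)
  r <- if (spec$orientation == "parallel") {
    if (spec$shifted) i + 1L else i
  } else {
    if (spec$shifted) n + 2L - i else n + 1L - i
  }
  r[r < 1L | r > n] <- NA_integer_
  r
}

# inverse register map: third residue -> plane index, possibly one step
# outside 1..n for the overhanging residue of shifted registers
third_to_plane <- function(spec, n) {
  r <- seq_len(n)
  if (spec$orientation == "parallel") {
    if (spec$shifted) r - 1L else r
  } else {
    if (spec$shifted) n + 2L - r else n + 1L - r
  }
}

#' Bond class of a triplex topology
#'
#' Hoogsteen-type (H) for parallel/anti and antiparallel/syn third
#' strands; reverse-Hoogsteen-type (RH) for the other two combinations.
#' The class is uniform across the planes of one triplex.
#'
#' @inheritParams conformational_counterpart
#' @return `"H"` or `"RH"`.
#' @export
bond_class <- function(spec) {
  stopifnot(inherits(spec, "triplex_spec"))
  if ((spec$orientation == "parallel") == (spec$glycosidic == "anti"))
    "H" else "RH"
}

#' Per-plane triplet step types of a triplex
#'
#' Walks the register of the specification along the duplex purine strand
#' and reports, for every base-triplet plane, the triplet identity (e.g.
#' `"C+.G:C"`, `"A.A:T"`) and its bond class. A shifted register leaves
#' one terminal plane without a third-strand partner (`NA` triplet).
#'
#' @inheritParams conformational_counterpart
#' @param n_repeats Number of GAA repeats (default 3, i.e. nine planes).
#' @return A data frame with columns `plane`, `third_res`, `third_base`,
#'   `protonated`, `triplet` and `bond_class`.
#' @export
step_types <- function(spec, n_repeats = 3L) {
  stopifnot(inherits(spec, "triplex_spec"))
  n <- 3L * n_repeats
  pur <- purine_seq(n_repeats)
  pyr_c <- c(G = "C", A = if (spec$duplex_pyrimidine_chem == "RNA") "U"
             else "T")
  third <- third_seq(spec, n_repeats)
  map <- plane_to_third(spec, n)
  tb <- ifelse(is.na(map), NA_character_, third[map])
  prot <- !is.na(tb) &
    ((spec$protonation == "cytosine" & tb == "C") |
     (spec$protonation == "adenine" & tb == "A" & pur == "G"))
  triplet <- ifelse(is.na(tb), NA_character_,
                    paste0(tb, ifelse(prot, "+", ""), ".", pur, ":",
                           pyr_c[pur]))
  data.frame(plane = seq_len(n), third_res = map, third_base = tb,
             protonated = prot, triplet = triplet,
             bond_class = ifelse(is.na(tb), NA_character_, bond_class(spec)),
             stringsAsFactors = FALSE)
}

#' Tabulate a set of triplex specifications
#'
#' @param specs A list of [triplex_spec()] objects.
#' @return A data frame with one row per spec.
#' @export
specs_table <- function(specs) {
  do.call(rbind, lapply(specs, function(s) {
    data.frame(label = s$label, third_class = s$third_class,
               orientation = s$orientation, shifted = s$shifted,
               protonation = s$protonation, glycosidic = s$glycosidic,
               duplex_purine_chem = s$duplex_purine_chem,
               duplex_pyrimidine_chem = s$duplex_pyrimidine_chem,
               bond_class = bond_class(s), stringsAsFactors = FALSE)
  }))
}
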