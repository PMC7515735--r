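# De-novo construction of idealized duplex and triplex starting models.
#
# Duplexes are generated with helical symmetry from per-form fiber
# parameters (twist, rise, x-displacement, inclination) applied to
# standard-reference-frame base pairs.  The backbone is a reduced
# sugar-phosphate trace (P, C1', O4', C2', plus O2' for RNA): every
# metric the package computes (plane fitting, hydrogen bonds, chi, Zp,
# groove widths, RMSD) is well defined on it.  The phosphate position in
# the base-pair frame is fixed per form; the values were derived once by
# solving the classic fiber constraints (phosphate radius, intra-strand
# P-P distance, canonical Zp) for each form and are frozen here.
#
# The third strand is placed plane-by-plane from idealized
# Hoogsteen/reverse-Hoogsteen triad templates (see triad_transform), so
# the built model starts with every template bond formed, all tilt
# angles near zero, and the register dictated by the spec.

#' Helical form parameters
#'
#' Fiber-type generation parameters for ideal B- and A-form helices:
#' twist (deg/step), rise (Angstrom/step), x-displacement of the pair
#' center from the helix axis, inclination of the pair plane, the
#' glycosidic torsion, and the phosphate position in the base-pair
#' reference frame.
#'
#' @param form `"B"` or `"A"`.
#' @return A list of parameters.
#' @export
helix_form_params <- function(form = c("B", "A")) {
  form <- match.arg(form)
  if (form == "B") {
    list(form = "B", twist = 36.0, rise = 3.38, dx = 0.0, incl = 0.0,
         chi = -117,
         p_local = .p_local_B)
  } else {
    list(form = "A", twist = 32.7, rise = 2.81, dx = -4.4, incl = 19.0,
         chi = -157,
         p_local = .p_local_A)
  }
}

# Phosphate coordinates in the base-pair reference frame, one per form.
# Frozen from solving (P radius, successive intra-strand P-P distance,
# canonical Zp) = (8.91 A, 6.7 A, 0.1 A) for B and (9.4 A, 5.9 A, 2.2 A)
# for A against this file's own helical generation; achieved
# (9.01, 6.51, 0.10) and (9.36, 5.97, 2.20). See methods vignette.
.p_local_B <- c(-3.188, 8.426, -1.590)
.p_local_A <- c(-3.201, 5.800, 0.053)

# pair frame (rotation, origin) of plane i under a form's helical symmetry
pair_frame_ideal <- function(i, fp) {
  Rz <- rot_z(fp$twist * (i - 1L))
  R <- Rz %*% rot_x(fp$incl)
  o <- as.numeric(Rz %*% c(fp$dx, 0, 0)) + c(0, 0, fp$rise * (i - 1L))
  list(R = R, o = o)
}

.FLIP <- diag(c(1, -1, -1))  # strand-II / base-flip operator (Rx(180))

wrap180 <- function(x) ((x + 180) %% 360) - 180

# Standard-frame coordinates of a full residue: base heavy atoms, polar
# hydrogens, and the reduced sugar-phosphate trace.  `syn` rotates the
# sugar/phosphate 180 degrees about the glycosidic bond (equivalently:
# the base is flipped by 180 about chi).
residue_std_atoms <- function(base, chem, protonated, fp,
                              glycosidic = "anti", with_p = TRUE) {
  xyz <- std_base(base, protonated = protonated, with_h = TRUE)
  gn <- .glyco_n[[base]]; cr <- .chi_ref[[base]]
  chi <- if (glycosidic == "anti") fp$chi else wrap180(fp$chi + 180)
  o4p <- nerf_place(xyz[cr, ], xyz[gn, ], xyz["C1'", ], 1.42, 108, chi)
  c2p <- nerf_place(xyz[cr, ], xyz[gn, ], xyz["C1'", ], 1.53, 114,
                    wrap180(chi + 119))
  sugar <- rbind("O4'" = o4p, "C2'" = c2p)
  if (chem == "RNA") {
    o2p <- nerf_place(xyz[gn, ], xyz["C1'", ], c2p, 1.41, 110, 155)
    sugar <- rbind(sugar, "O2'" = o2p)
  }
  out <- rbind(xyz, sugar)
  if (with_p) {
    p <- fp$p_local
    if (glycosidic == "syn") {
      ax <- xyz[gn, ] - xyz["C1'", ]
      p <- as.numeric(rot_axis(ax, 180) %*% (p - xyz["C1'", ])) +
        xyz["C1'", ]
    }
    out <- rbind(out, P = p)
  }
  out
}

.mk_atom_rows <- function(strand, res, base, chem, xyz) {
  data.frame(strand = strand, res = res, base = base, chem = chem,
             elety = rownames(xyz), x = xyz[, 1L], y = xyz[, 2L],
             z = xyz[, 3L], row.names = NULL, stringsAsFactors = FALSE)
}

#' Build an ideal Watson-Crick duplex
#'
#' Generates an antiparallel duplex with fiber helical symmetry in the
#' requested form. The purine strand is given 5' to 3'; the
#' complementary pyrimidine strand (T or U according to its chemistry)
#' is generated automatically.
#'
#' @param purine_seq Character string or vector over \{G, A\}.
#' @param form `"B"` or `"A"`.
#' @param chemistries Length-2 character vector: chemistry of the purine
#'   and pyrimidine strands (`"DNA"`/`"RNA"`).
#' @return A [triplex_model()] with strands A (purine) and B
#'   (pyrimidine).
#' @examples
#' dx <- build_duplex(strrep("GAA", 3))
#' @export
build_duplex <- function(purine_seq, form = "B",
                         chemistries = c("DNA", "DNA")) {
  if (length(purine_seq) == 1L && nchar(purine_seq[1L]) > 1L)
    purine_seq <- strsplit(purine_seq, "")[[1L]]
  if (!all(purine_seq %in% c("G", "A")))
    stop("purine_seq must contain only G and A, got: ",
         paste(setdiff(purine_seq, c("G", "A")), collapse = ","))
  fp <- helix_form_params(form)
  n <- length(purine_seq)
  chem_pur <- match.arg(chemistries[1L], c("DNA", "RNA"))
  chem_pyr <- match.arg(chemistries[2L], c("DNA", "RNA"))

  atoms <- NULL
  for (i in seq_len(n)) {
    fr <- pair_frame_ideal(i, fp)
    # strand I (purine), residue index = plane index
    std1 <- residue_std_atoms(purine_seq[i], chem_pur, FALSE, fp,
                              with_p = (i > 1L))
    atoms <- rbind(atoms, .mk_atom_rows(
      "A", i, purine_seq[i], chem_pur, apply_rt(std1, fr$R, fr$o)))
    # strand II (pyrimidine), residue index n+1-i (5'->3' runs plane n..1)
    pyb <- complement_base(purine_seq[i], chem_pyr)
    std2 <- residue_std_atoms(pyb, chem_pyr, FALSE, fp,
                              with_p = (i < n))
    atoms <- rbind(atoms, .mk_atom_rows(
      "B", n + 1L - i, pyb, chem_pyr,
      apply_rt(std2 %*% t(.FLIP), fr$R, fr$o)))
  }
  atoms <- atoms[order(match(atoms$strand, c("A", "B")), atoms$res), ]
  residues <- unique(atoms[, c("strand", "res", "base", "chem")])
  residues$protonated <- FALSE
  residues$glycosidic <- "anti"
  residues$usable <- TRUE
  strands <- data.frame(
    strand = c("A", "B"), role = c("purine", "pyrimidine"),
    chem = c(chem_pur, chem_pyr), n = n, stringsAsFactors = FALSE)
  m <- triplex_model(atoms, residues, strands)
  m$form <- form
  m
}

# periodically-extended GAA purine base at (possibly out-of-range) plane i
.gaa_base_at <- function(i) c("G", "A", "A")[((i - 1L) %% 3L) + 1L]

#' Build an idealized triple helix
#'
#' Builds the Watson-Crick duplex in the requested form, then places the
#' third strand in the major groove: each third-strand base is posed on
#' its triplet plane by the idealized Hoogsteen/reverse-Hoogsteen triad
#' template of its step type, at the register dictated by the spec, with
#' protonation applied where the spec calls for it and the sugar trace
#' attached in anti or syn. Every template hydrogen bond of the built
#' model is formed and all base tilt angles are near zero.
#'
#' @param spec A [triplex_spec()].
#' @param n_repeats Number of GAA repeats per strand (default 3: nine
#'   nucleotides per strand).
#' @param form Starting helical form, `"B"` or `"A"`.
#' @param clash_tol Heavy-atom steric floor in Angstrom; the model is
#'   checked and a warning raised if any non-bonded pair comes closer.
#' @return A [triplex_model()] with strands A (duplex purine), B (duplex
#'   pyrimidine) and C (third strand).
#' @examples
#' tri <- build_triplex(parse_label("pY(a)"))
#' @export
build_triplex <- function(spec, n_repeats = 3L, form = "B",
                          clash_tol = 2.0) {
  stopifnot(inherits(spec, "triplex_spec"), n_repeats >= 1L)
  fp <- helix_form_params(form)
  n <- 3L * n_repeats
  dup <- build_duplex(purine_seq(n_repeats), form = form,
                      chemistries = c(spec$duplex_purine_chem,
                                      spec$duplex_pyrimidine_chem))
  st <- step_types(spec, n_repeats)
  ip <- third_to_plane(spec, n)           # third residue -> plane
  tseq <- third_seq(spec, n_repeats)

  # 5'-terminal residue of the third strand (no phosphate): residue 1
  atoms <- dup$atoms
  for (r in seq_len(n)) {
    i_use <- ip[r]
    cls <- bond_class(spec)
    if (i_use < 1L || i_use > n) {
      # register overhang (shifted specs): continue the helix one
      # virtual plane beyond the duplex end
      pur_base <- .gaa_base_at(i_use)
      prot <- FALSE
      tb <- tseq[r]
      triplet <- paste0(tb, ".", pur_base, ":",
                        complement_base(pur_base))
    } else {
      tb <- st$third_base[i_use]
      prot <- st$protonated[i_use]
      triplet <- st$triplet[i_use]
    }
    tt <- triad_transform(triplet, cls)
    fr <- pair_frame_ideal(i_use, fp)
    std <- residue_std_atoms(tb, spec$third_chem, prot, fp,
                             glycosidic = spec$glycosidic,
                             with_p = FALSE)
    if (cls == "RH") std <- std %*% t(.FLIP)
    in_pair <- apply_rt(std, tt$R, tt$t)
    atoms <- rbind(atoms, .mk_atom_rows(
      "C", r, tb, spec$third_chem, apply_rt(in_pair, fr$R, fr$o)))
  }
  # Third-strand phosphates: the triad placement perturbs the base frames
  # plane by plane, so the duplex's frame-local phosphate would collide
  # with the preceding sugar. Place P between successive glycosidic
  # attachment points instead, at the backbone radius from the helix
  # axis (the axis is global z at build time).
  c1 <- vapply(seq_len(n), function(r) {
    a <- atoms[atoms$strand == "C" & atoms$res == r &
                 atoms$elety == "C1'", c("x", "y", "z")]
    as.numeric(a[1L, ])
  }, numeric(3L))
  for (r in 2:n) {
    mid <- (c1[, r - 1L] + c1[, r]) / 2
    u <- vunit(c(mid[1L], mid[2L], 0))
    p <- c(9.0 * u[1L], 9.0 * u[2L], mid[3L])
    atoms <- rbind(atoms, data.frame(
      strand = "C", res = r, base = tseq[r], chem = spec$third_chem,
      elety = "P", x = p[1L], y = p[2L], z = p[3L],
      stringsAsFactors = FALSE))
  }
  atoms <- .relax_third_trace(atoms, n)
  atoms <- atoms[order(match(atoms$strand, c("A", "B", "C")), atoms$res), ]
  residues <- unique(atoms[, c("strand", "res", "base", "chem")])
  prot_res <- rep(FALSE, nrow(residues))
  third_rows <- residues$strand == "C"
  prot_by_res <- logical(n)
  ok <- !is.na(st$third_res)
  prot_by_res[st$third_res[ok]] <- st$protonated[ok]
  prot_res[third_rows] <- prot_by_res[residues$res[third_rows]]
  residues$protonated <- prot_res
  residues$glycosidic <- ifelse(third_rows, spec$glycosidic, "anti")
  residues$usable <- TRUE
  strands <- data.frame(
    strand = c("A", "B", "C"), role = c("purine", "pyrimidine", "third"),
    chem = c(spec$duplex_purine_chem, spec$duplex_pyrimidine_chem,
             spec$third_chem),
    n = n, stringsAsFactors = FALSE)
  m <- triplex_model(atoms, residues, strands, spec = spec)
  m$form <- form
  cl <- count_clashes(m, clash_tol)
  if (cl > 0L)
    warning(sprintf("built model has %d heavy-atom pair(s) closer than %.1f A",
                    cl, clash_tol), call. = FALSE)
  m
}

# Deterministic clearance pass over the third-strand trace: the sugar
# may rotate a little about the glycosidic bond (staying inside its
# anti/syn well) and each phosphate relaxes locally, so that the reduced
# backbone does not collide with neighbouring residues.
.relax_third_trace <- function(atoms, n) {
  xyz_of <- function(sel) as.matrix(atoms[sel, c("x", "y", "z")])
  heavy <- !grepl("^H", .elesy_of(atoms$elety))
  for (r in seq_len(n)) {
    own <- atoms$strand == "C" & atoms$res == r
    sug <- own & atoms$elety %in% c("O4'", "C2'", "O2'")
    if (!any(sug)) next
    base_r <- atoms$base[own][1L]
    gn <- .glyco_n[[base_r]]
    c1 <- as.numeric(atoms[own & atoms$elety == "C1'", c("x", "y", "z")])
    nn <- as.numeric(atoms[own & atoms$elety == gn, c("x", "y", "z")])
    others <- heavy & !own &
      abs(atoms$res - r) <= 1L & atoms$strand == "C"
    if (!any(others)) next
    O <- xyz_of(others)
    best <- NULL
    for (off in c(0, as.vector(rbind(-1, 1) %o% seq(5, 45, by = 5)))) {
      S <- sweep(sweep(xyz_of(sug), 2L, c1) %*%
                   t(rot_axis(nn - c1, off)), 2L, c1, "+")
      clr <- min(sqrt(outer(rowSums(S^2), rowSums(O^2), "+") -
                        2 * S %*% t(O)))
      if (is.null(best) || clr > best$clr + 1e-9) best <- list(S = S,
                                                              clr = clr)
      if (best$clr >= 2.1 && off == 0) break
    }
    atoms[sug, c("x", "y", "z")] <- best$S
  }
  for (r in 2:n) {
    psel <- atoms$strand == "C" & atoms$res == r & atoms$elety == "P"
    if (!any(psel)) next
    p0 <- as.numeric(atoms[psel, c("x", "y", "z")])
    others <- heavy & !psel & !(atoms$strand == "C" & atoms$res == r)
    O <- xyz_of(others)
    near <- sqrt(colSums((t(O) - p0)^2)) < 6
    if (!any(near)) next
    On <- O[near, , drop = FALSE]
    obj <- function(p) {
      d <- sqrt(colSums((t(On) - p)^2))
      sum(pmax(0, 2.2 - d)^2) + 0.02 * sum((p - p0)^2)
    }
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    atoms[psel, c("x", "y", "z")] <- opt$par
  }
  atoms
}

#' Count steric clashes in a model
#'
#' Number of heavy-atom pairs from different residues closer than the
#' steric floor.
#'
#' @param model A [triplex_model()].
#' @param tol Distance floor in Angstrom (default 2.0).
#' @return Integer count.
#' @export
count_clashes <- function(model, tol = 2.0) {
  at <- model$atoms
  heavy <- !grepl("^H", .elesy_of(at$elety))
  xyz <- axyz(model)[heavy, , drop = FALSE]
  rid <- paste(at$strand[heavy], at$res[heavy])
  d <- as.matrix(stats::dist(xyz))
  same <- outer(rid, rid, "==")
  sum(d < tol & !same & upper.tri(d))
}

#' Geometric refinement of template hydrogen bonds
#'
#' A lightweight deterministic refinement (no dynamics): third-strand
#' residues are iteratively translated as rigid bodies down the gradient
#' of the squared template-bond length violations until every template
#' donor-acceptor pair sits at its ideal distance or no further progress
#' is possible. Reports bonds that remain unsatisfiable.
#'
#' @param model A triplex [triplex_model()] with a spec attached.
#' @param target Ideal heavy-atom donor-acceptor distance (Angstrom).
#' @param max_iter,step_size Iteration controls.
#' @param tol Convergence threshold on the root-mean-square violation.
#' @return The refined model, with attributes `violations` (per-bond
#'   residual distances) and `converged`.
#' @export
idealize_hbonds <- function(model, target = HB_IDEAL, max_iter = 200L,
                            step_size = 0.25, tol = 0.05) {
  spec <- model$spec
  if (is.null(spec)) stop("model carries no triplex_spec")
  bonds <- template_bond_atoms(model)
  if (!nrow(bonds)) stop("no template bonds for this model")
  at <- model$atoms
  xyz <- axyz(model)
  key <- paste(at$strand, at$res, at$elety)
  ia <- match(paste(bonds$third_strand, bonds$third_res, bonds$third_atom),
              key)
  ib <- match(paste(bonds$duplex_strand, bonds$duplex_res,
                    bonds$duplex_atom), key)
  keep <- !is.na(ia) & !is.na(ib)
  bonds <- bonds[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  third_res_of_atom <- ifelse(at$strand == "C", at$res, NA_integer_)

  score <- function(xyz) {
    d <- sqrt(rowSums((xyz[ia, , drop = FALSE] -
                         xyz[ib, , drop = FALSE])^2))
    sum((d - target)^2)
  }
  best <- xyz; best_s <- score(xyz); stall <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((xyz[ia, , drop = FALSE] -
                         xyz[ib, , drop = FALSE])^2))
    if (sqrt(mean((d - target)^2)) < tol) { converged <- TRUE; break }
    # per third-strand residue translation
    for (r in unique(bonds$third_res)) {
      bsel <- bonds$third_res == r
      u <- xyz[ib[bsel], , drop = FALSE] - xyz[ia[bsel], , drop = FALSE]
      dn <- sqrt(rowSums(u^2))
      grad <- colSums(u / dn * (dn - target))
      move <- step_size * grad / max(1, vnorm(grad))
      rsel <- which(third_res_of_atom == r)
      xyz[rsel, ] <- sweep(xyz[rsel, , drop = FALSE], 2L, move, "+")
    }
    s <- score(xyz)
    if (s < best_s - 1e-9) { best <- xyz; best_s <- s; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= 10L) break
  }
  if (!converged && stall >= 10L)
    warning("hydrogen-bond idealization stalled; returning best-so-far",
            call. = FALSE)
  axyz(model) <- best
  d <- sqrt(rowSums((best[ia, , drop = FALSE] -
                       best[ib, , drop = FALSE])^2))
  attr(model, "violations") <-
    data.frame(bonds[, c("plane", "third_atom", "duplex_atom")],
               distance = d, satisfied = abs(d - target) < 10 * tol)
  attr(model, "converged") <- converged
  model
}

# Template bond list of a built triplex, with atom addresses resolved to
# the model's strands/residues.
template_bond_atoms <- function(model, n_repeats = NULL) {
  spec <- model$spec
  n <- model$strands$n[1L]
  if (is.null(n_repeats)) n_repeats <- n %/% 3L
  st <- step_types(spec, n_repeats)
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  sC <- strand_of_role(model, "third")
  out <- NULL
  for (i in seq_len(nrow(st))) {
    if (is.na(st$third_res[i])) next
    bonds <- template_bonds(st$triplet[i], st$bond_class[i])
    for (b in bonds) {
      on_pyr <- identical(b$duplex_base, "pyrimidine")
      out <- rbind(out, data.frame(
        plane = st$plane[i],
        third_strand = sC, third_res = st$third_res[i],
        third_atom = b$third,
        duplex_strand = if (on_pyr) sB else sA,
        duplex_res = if (on_pyr) n + 1L - st$plane[i] else st$plane[i],
        duplex_atom = b$duplex,
        donor = b$donor, stringsAsFactors = FALSE))
    }
  }
  out
}
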