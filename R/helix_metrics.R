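# Duplex characterization: fitted base-pair reference frames, base-pair
# step parameters, the Zp phosphate parameter, A/B-form classification,
# superposition RMSD, base-step overlap areas and triplex groove widths.
#
# Frames follow the standard fitted-frame construction: each base gets a
# frame by least-squares superposition of its standard-reference-frame
# ring atoms onto the observed ring; the strand-II frame is flipped about
# its x-axis; the pair frame is the geodesic mean of the two. Step
# parameters use the symmetric mid-step (CEHS-style) decomposition.

# rotation + origin of one base's fitted standard frame
fit_base_frame <- function(model, strand, res) {
  rr <- residue_row(model, strand, res)
  if (!nrow(rr)) stop("no residue ", strand, ":", res)
  ring <- .base_rings[[rr$base]]
  obs <- res_xyz(model, strand, res, ring)
  if (nrow(obs) < length(ring))
    stop("residue ", strand, ":", res, " lacks ring atoms for frame fit")
  std <- .base_heavy[[rr$base]][ring, , drop = FALSE]
  k <- kabsch(std[rownames(obs), , drop = FALSE], obs)
  list(R = k$R, o = as.numeric(k$t), rmsd = k$rmsd)
}

# base-pair frames along the duplex planes of a model (duplex or triplex)
pair_frames <- function(model) {
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  n <- model$strands$n[model$strands$strand == sA]
  lapply(seq_len(n), function(i) {
    f1 <- fit_base_frame(model, sA, i)
    f2 <- fit_base_frame(model, sB, n + 1L - i)
    R2 <- f2$R %*% .FLIP
    list(R = rot_mid(f1$R, R2), o = (f1$o + f2$o) / 2, plane = i)
  })
}

# symmetric mid-step decomposition of one base-pair step
.step_decompose <- function(f1, f2) {
  z1 <- f1$R[, 3L]; z2 <- f2$R[, 3L]
  cr <- vcross(z1, z2)
  s <- vnorm(cr)
  gamma <- rad2deg(atan2(s, sum(z1 * z2)))
  if (s > 1e-9) {
    hinge <- cr / s
    R1p <- rot_axis(hinge, gamma / 2) %*% f1$R
    R2p <- rot_axis(hinge, -gamma / 2) %*% f2$R
  } else {
    hinge <- f1$R[, 2L]
    R1p <- f1$R; R2p <- f2$R
  }
  zm <- R1p[, 3L]
  sang <- function(a, b, ax) {
    rad2deg(atan2(sum(vcross(a, b) * ax), sum(a * b)))
  }
  twist <- sang(R1p[, 1L], R2p[, 1L], zm)
  Rm <- rot_mid(R1p, R2p)
  om <- (f1$o + f2$o) / 2
  disp <- as.numeric(t(Rm) %*% (f2$o - f1$o))
  phi <- sang(Rm[, 2L], hinge, zm)
  # helical (screw) decomposition
  M <- f2$R %*% t(f1$R)
  dec <- rot_decompose(M)
  ax <- dec$axis
  if (sum(ax * zm) < 0) { ax <- -ax; dec$angle <- -dec$angle }
  list(twist = twist,
       roll = gamma * cos(deg2rad(phi)),
       tilt = gamma * sin(deg2rad(phi)),
       shift = disp[1L], slide = disp[2L], rise = disp[3L],
       helical_twist = abs(dec$angle),
       helical_rise = sum((f2$o - f1$o) * ax),
       helical_axis = ax, Rm = Rm, om = om)
}

#' Base-pair step parameters of a duplex
#'
#' Twist, roll, tilt, shift, slide and rise per base-pair step, plus the
#' helical (screw-axis) twist and rise, per-pair inclination relative to
#' the local helical axis, and the per-step Zp phosphate parameter.
#' Works on a bare duplex or on the Watson-Crick duplex part of a
#' triplex model.
#'
#' @param model A [triplex_model()].
#' @return A data frame with one row per step and a final attribute-free
#'   summary available via `colMeans`.
#' @export
step_parameters <- function(model) {
  pf <- pair_frames(model)
  n <- length(pf)
  if (n < 2L) stop("need at least two base pairs")
  zp_v <- zp(model)$per_step
  out <- NULL
  for (i in seq_len(n - 1L)) {
    d <- .step_decompose(pf[[i]], pf[[i + 1L]])
    incl <- rad2deg(asin(max(-1, min(1,
      sum(pf[[i]]$R[, 2L] * d$helical_axis)))))
    out <- rbind(out, data.frame(
      step = i, twist = d$twist, roll = d$roll, tilt = d$tilt,
      shift = d$shift, slide = d$slide, rise = d$rise,
      helical_twist = d$helical_twist, helical_rise = d$helical_rise,
      inclination = incl, Zp = zp_v[i]))
  }
  out
}

#' Zp: mean phosphate z-coordinate in the dimer reference frame
#'
#' For every base-pair step, the z-coordinates of the two 3'-phosphorus
#' atoms of the step (one per strand) are measured in the step's
#' mid-frame and averaged. Zp discriminates helical families: > 1.5
#' Angstrom for A-form steps, < 0.5 for B-form.
#'
#' @param model A [triplex_model()] whose duplex strands carry P atoms.
#' @return List with `per_step` (possibly containing `NA` where a
#'   phosphate is missing) and `mean` (over defined steps).
#' @export
zp <- function(model) {
  pf <- pair_frames(model)
  n <- length(pf)
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  p_of <- function(strand, res) {
    m <- res_xyz(model, strand, res, "P")
    if (nrow(m)) m[1L, ] else NULL
  }
  per <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- .step_decompose(pf[[i]], pf[[i + 1L]])
    # 3' phosphates of the step: strand I residue i+1; strand II residue
    # paired with plane i (strand II resno = n + 1 - plane)
    pA <- p_of(sA, i + 1L)
    pB <- p_of(sB, n + 1L - i)
    # strand II is expressed in the dyad-flipped mid-frame (y, z negated),
    # as for all strand-symmetric step parameters
    zs <- c(if (!is.null(pA)) sum((pA - d$om) * d$Rm[, 3L]),
            if (!is.null(pB)) -sum((pB - d$om) * d$Rm[, 3L]))
    if (length(zs)) per[i] <- mean(zs)
  }
  list(per_step = per, mean = mean(per, na.rm = TRUE))
}

#' Classify a duplex on the A/B spectrum
#'
#' Uses the two discriminating parameters: a step is A-form if
#' slide < -0.8 Angstrom and Zp > 1.5, B-form if slide > -0.8 and
#' Zp < 0.5, otherwise intermediate. The aggregate call applies the same
#' rule to the mean slide and mean Zp.
#'
#' @param model A [triplex_model()], or a data frame from
#'   [step_parameters()].
#' @return List with `per_step` (character vector) and `aggregate`.
#' @export
classify_form <- function(model) {
  params <- if (is.data.frame(model)) model else step_parameters(model)
  rule <- function(slide, zp) {
    if (is.na(slide) || is.na(zp)) return(NA_character_)
    if (slide < -0.8 && zp > 1.5) "A"
    else if (slide > -0.8 && zp < 0.5) "B"
    else "intermediate"
  }
  per <- mapply(rule, params$slide, params$Zp)
  list(per_step = per,
       aggregate = rule(mean(params$slide), mean(params$Zp, na.rm = TRUE)))
}

#' Least-squares superposition RMSD between two models
#'
#' Atoms are paired by (strand, residue, atom name) over the chosen
#' selection; rotation and translation are removed by superposition.
#'
#' @param model_a,model_b Two [triplex_model()] objects.
#' @param selection `"heavy"`, `"backbone"` (P, C1', O4', C2') or
#'   `"all"`.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(model_a, model_b, selection = c("heavy", "backbone",
                                                     "all")) {
  selection <- match.arg(selection)
  pick <- function(m) {
    at <- m$atoms
    keep <- switch(selection,
      all = rep(TRUE, nrow(at)),
      heavy = !grepl("^H", .elesy_of(at$elety)),
      backbone = at$elety %in% c("P", "C1'", "O4'", "C2'"))
    at <- at[keep, ]
    at$key <- paste(at$strand, at$res, at$elety)
    at
  }
  a <- pick(model_a); b <- pick(model_b)
  common <- intersect(a$key, b$key)
  if (length(common) != nrow(a) || length(common) != nrow(b))
    stop("atom selections do not pair up: ", nrow(a), " vs ", nrow(b),
         " atoms, ", length(common), " shared")
  A <- as.matrix(a[match(common, a$key), c("x", "y", "z")])
  B <- as.matrix(b[match(common, b$key), c("x", "y", "z")])
  kabsch(A, B)$rmsd
}

# -- overlap areas -------------------------------------------------------

# Sutherland-Hodgman clipping of convex polygon `subj` by convex `clip`
# (both n x 2, counter-clockwise)
.clip_polygon <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    e <- b - a
    side <- function(p) e[1L] * (p[2L] - a[2L]) - e[2L] * (p[1L] - a[1L])
    inp <- out; out <- NULL
    np <- nrow(inp)
    for (j in seq_len(np)) {
      p <- inp[j, ]; q <- inp[if (j == np) 1L else j + 1L, ]
      sp <- side(p); sq <- side(q)
      if (sp >= 0) out <- rbind(out, p)
      if ((sp >= 0) != (sq >= 0)) {
        t <- sp / (sp - sq)
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

.poly_area <- function(p) {
  if (is.null(p) || nrow(p) < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# ccw convex hull (n x 2) via grDevices::chull
.hull2d <- function(p) {
  h <- grDevices::chull(p)
  p[rev(h), , drop = FALSE]  # chull returns clockwise; reverse to ccw
}

# base-pair outline (heavy base atoms of both bases) projected on a frame
.pair_polygon <- function(model, plane, R, o) {
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  n <- model$strands$n[model$strands$strand == sA]
  get <- function(strand, res) {
    rr <- residue_row(model, strand, res)
    ats <- setdiff(rownames(.base_heavy[[rr$base]]), "C1'")
    res_xyz(model, strand, res, ats)
  }
  pts <- rbind(get(sA, plane), get(sB, n + 1L - plane))
  loc <- sweep(pts, 2L, o) %*% R  # into frame coordinates
  .hull2d(loc[, 1:2, drop = FALSE])
}

#' Base-step overlap areas
#'
#' Area of intersection of successive base-pair outlines (convex hulls of
#' the base heavy atoms) projected onto the mean plane of the step, the
#' overlap-area convention of standard helix-analysis tools.
#'
#' @param model A [triplex_model()] with a Watson-Crick duplex.
#' @param inner_only If `TRUE` the reported total excludes the two
#'   terminal steps.
#' @return List with `per_step` (Angstrom^2) and `total`.
#' @export
step_overlap_area <- function(model, inner_only = TRUE) {
  pf <- pair_frames(model)
  n <- length(pf)
  per <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- .step_decompose(pf[[i]], pf[[i + 1L]])
    p1 <- .pair_polygon(model, i, d$Rm, d$om)
    p2 <- .pair_polygon(model, i + 1L, d$Rm, d$om)
    if (is.null(p1) || is.null(p2) || nrow(p1) < 3L || nrow(p2) < 3L) {
      warning("degenerate base polygon at step ", i, call. = FALSE)
      per[i] <- 0
      next
    }
    per[i] <- .poly_area(.clip_polygon(p1, p2))
  }
  keep <- if (inner_only && n > 3L) 2:(n - 2L) else seq_len(n - 1L)
  list(per_step = per, total = sum(per[keep]), inner_steps = keep)
}

#' Groove widths of a triple helix
#'
#' A triplex has three grooves; their widths are reported as the minimal
#' inter-strand P-P distance for each strand pairing minus the
#' conventional 5.8 Angstrom phosphate-exclusion correction, labelled
#' `third_purine`, `third_pyrimidine` and `duplex_minor`.
#'
#' @param model A triplex [triplex_model()] with phosphates.
#' @return Named numeric vector of the three widths (Angstrom).
#' @export
groove_widths <- function(model) {
  pxyz <- function(role) {
    s <- strand_of_role(model, role)
    sel <- model$atoms$strand == s & model$atoms$elety == "P"
    axyz(model)[sel, , drop = FALSE]
  }
  pa <- pxyz("purine"); pb <- pxyz("pyrimidine"); pc <- pxyz("third")
  min_pp <- function(x, y) {
    d <- outer(seq_len(nrow(x)), seq_len(nrow(y)),
               Vectorize(function(i, j) vnorm(x[i, ] - y[j, ])))
    min(d)
  }
  c(third_purine = min_pp(pc, pa) - 5.8,
    third_pyrimidine = min_pp(pc, pb) - 5.8,
    duplex_minor = min_pp(pa, pb) - 5.8)
}
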