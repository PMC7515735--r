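# Nucleobase chemistry: idealized base geometry in the standard base
# reference frame (origin on the pseudo-dyad in the base-pair plane, x
# toward the major groove, y toward the strand-I backbone, z along the
# base normal), donor/acceptor tables, polar-hydrogen construction and
# the aromatic ring areas used by the stacking metric.
#
# Base heavy-atom coordinates are the conventional standard-reference-frame
# values (z = 0 plane); C1' is included so that a placed base carries its
# glycosidic attachment point.

.base_heavy <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346, 0),
    N9  = c(-1.291, 4.498, 0),
    C8  = c( 0.024, 4.897, 0),
    N7  = c( 0.877, 3.902, 0),
    C5  = c( 0.071, 2.771, 0),
    C6  = c( 0.369, 1.398, 0),
    N6  = c( 1.611, 0.909, 0),
    N1  = c(-0.668, 0.532, 0),
    C2  = c(-1.912, 1.023, 0),
    N3  = c(-2.320, 2.290, 0),
    C4  = c(-1.267, 3.124, 0)),
  G = rbind(
    "C1'" = c(-2.477, 5.399, 0),
    N9  = c(-1.289, 4.551, 0),
    C8  = c( 0.023, 4.962, 0),
    N7  = c( 0.870, 3.969, 0),
    C5  = c( 0.071, 2.833, 0),
    C6  = c( 0.424, 1.460, 0),
    O6  = c( 1.554, 0.955, 0),
    N1  = c(-0.700, 0.641, 0),
    C2  = c(-1.999, 1.087, 0),
    N2  = c(-2.949, 0.139, 0),
    N3  = c(-2.342, 2.364, 0),
    C4  = c(-1.265, 3.177, 0)),
  C = rbind(
    "C1'" = c(-2.477, 5.402, 0),
    N1  = c(-1.285, 4.542, 0),
    C2  = c(-1.472, 3.158, 0),
    O2  = c(-2.628, 2.709, 0),
    N3  = c(-0.391, 2.344, 0),
    C4  = c( 0.837, 2.868, 0),
    N4  = c( 1.875, 2.027, 0),
    C5  = c( 1.056, 4.275, 0),
    C6  = c(-0.023, 5.068, 0)),
  T = rbind(
    "C1'" = c(-2.481, 5.354, 0),
    N1  = c(-1.284, 4.500, 0),
    C2  = c(-1.462, 3.135, 0),
    O2  = c(-2.562, 2.608, 0),
    N3  = c(-0.298, 2.407, 0),
    C4  = c( 0.994, 2.897, 0),
    O4  = c( 1.944, 2.119, 0),
    C5  = c( 1.106, 4.338, 0),
    C7  = c( 2.466, 4.961, 0),
    C6  = c(-0.024, 5.057, 0)),
  U = rbind(
    "C1'" = c(-2.481, 5.354, 0),
    N1  = c(-1.284, 4.500, 0),
    C2  = c(-1.462, 3.131, 0),
    O2  = c(-2.563, 2.608, 0),
    N3  = c(-0.302, 2.397, 0),
    C4  = c( 0.989, 2.884, 0),
    O4  = c( 1.935, 2.094, 0),
    C5  = c( 1.089, 4.311, 0),
    C6  = c(-0.024, 5.053, 0))
)

# aromatic ring atoms used for plane fitting and frame fitting
.base_rings <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# heavy-atom bond topology within the base (for lone pairs / H geometry)
.base_bonds <- list(
  A = list(N9 = c("C8", "C4", "C1'"), C8 = c("N9", "N7"), N7 = c("C8", "C5"),
           C5 = c("N7", "C6", "C4"), C6 = c("C5", "N6", "N1"), N6 = "C6",
           N1 = c("C6", "C2"), C2 = c("N1", "N3"), N3 = c("C2", "C4"),
           C4 = c("N3", "C5", "N9")),
  G = list(N9 = c("C8", "C4", "C1'"), C8 = c("N9", "N7"), N7 = c("C8", "C5"),
           C5 = c("N7", "C6", "C4"), C6 = c("C5", "O6", "N1"), O6 = "C6",
           N1 = c("C6", "C2"), C2 = c("N1", "N2", "N3"), N2 = "C2",
           N3 = c("C2", "C4"), C4 = c("N3", "C5", "N9")),
  C = list(N1 = c("C2", "C6", "C1'"), C2 = c("N1", "O2", "N3"), O2 = "C2",
           N3 = c("C2", "C4"), C4 = c("N3", "N4", "C5"), N4 = "C4",
           C5 = c("C4", "C6"), C6 = c("C5", "N1")),
  T = list(N1 = c("C2", "C6", "C1'"), C2 = c("N1", "O2", "N3"), O2 = "C2",
           N3 = c("C2", "C4"), C4 = c("N3", "O4", "C5"), O4 = "C4",
           C5 = c("C4", "C7", "C6"), C7 = "C5", C6 = c("C5", "N1")),
  U = list(N1 = c("C2", "C6", "C1'"), C2 = c("N1", "O2", "N3"), O2 = "C2",
           N3 = c("C2", "C4"), C4 = c("N3", "O4", "C5"), O4 = "C4",
           C5 = c("C4", "C6"), C6 = c("C5", "N1"))
)

.glyco_n <- c(A = "N9", G = "N9", C = "N1", T = "N1", U = "N1")
.chi_ref <- c(A = "C4", G = "C4", C = "C2", T = "C2", U = "C2")

#' Aromatic ring areas used by the effective-stacking metric
#'
#' Fixed per-base ring areas in square Angstrom: 4.95 for the pyrimidines
#' (T, C and U) and 8.29 for the purines (A and G).
#' @keywords internal
.A0 <- c(A = 8.29, G = 8.29, T = 4.95, C = 4.95, U = 4.95)

N_H_BOND <- 1.01

# Polar (N-H) hydrogens in the same frame as `xyz` (a heavy-atom matrix of
# one base). Returns a matrix (possibly 0-row) of hydrogen coordinates.
polar_hydrogens <- function(base, xyz, protonated = FALSE) {
  H <- NULL
  n_of <- function(at) xyz[at, ]
  normal <- fit_plane_normal(xyz[.base_rings[[base]], ])
  amino <- function(N, C, h1, h2) {
    u <- vunit(n_of(C) - n_of(N))
    a <- n_of(N) + N_H_BOND * as.numeric(rot_axis(normal, 120) %*% u)
    b <- n_of(N) + N_H_BOND * as.numeric(rot_axis(normal, -120) %*% u)
    m <- rbind(a, b); rownames(m) <- c(h1, h2); m
  }
  ring_h <- function(N, nb1, nb2, h) {
    d <- -(vunit(n_of(nb1) - n_of(N)) + vunit(n_of(nb2) - n_of(N)))
    m <- rbind(n_of(N) + N_H_BOND * vunit(d)); rownames(m) <- h; m
  }
  if (base == "A") {
    H <- amino("N6", "C6", "H61", "H62")
    if (protonated) H <- rbind(H, ring_h("N1", "C6", "C2", "H1"))
  } else if (base == "G") {
    H <- rbind(ring_h("N1", "C6", "C2", "H1"), amino("N2", "C2", "H21", "H22"))
  } else if (base == "C") {
    H <- amino("N4", "C4", "H41", "H42")
    if (protonated) H <- rbind(H, ring_h("N3", "C2", "C4", "H3"))
  } else if (base %in% c("T", "U")) {
    H <- ring_h("N3", "C2", "C4", "H3")
  }
  H
}

# Base coordinates in the standard frame, optionally flipped over
# (rotation of 180 degrees about x: the reverse-Hoogsteen presentation)
# and with polar hydrogens appended.
std_base <- function(base, protonated = FALSE, flip = FALSE, with_h = TRUE) {
  xyz <- .base_heavy[[base]]
  if (is.null(xyz)) stop("unknown base: ", base)
  if (with_h) xyz <- rbind(xyz, polar_hydrogens(base, xyz, protonated))
  if (flip) xyz <- xyz %*% diag(c(1, -1, -1))
  xyz
}

# Hydrogen-bond donor table: donor heavy atom -> its hydrogen names
hb_donors <- function(base, protonated = FALSE) {
  d <- switch(base,
    A = list(N6 = c("H61", "H62")),
    G = list(N1 = "H1", N2 = c("H21", "H22")),
    C = list(N4 = c("H41", "H42")),
    T = list(N3 = "H3"),
    U = list(N3 = "H3"))
  if (protonated && base == "A") d$N1 <- "H1"
  if (protonated && base == "C") d$N3 <- "H3"
  d
}

hb_acceptors <- function(base, protonated = FALSE) {
  a <- switch(base,
    A = c("N7", "N1", "N3"),
    G = c("N7", "O6", "N3"),
    C = c("O2", "N3"),
    T = c("O2", "O4"),
    U = c("O2", "O4"))
  if (protonated && base == "A") a <- setdiff(a, "N1")
  if (protonated && base == "C") a <- setdiff(a, "N3")
  a
}

# In-plane lone-pair (approach) direction of an acceptor atom: away from
# the mean direction of its bonded heavy neighbours.
lone_pair_dir <- function(base, atom, xyz) {
  nbs <- .base_bonds[[base]][[atom]]
  nbs <- setdiff(nbs, "C1'")
  if (is.null(nbs) || !length(nbs)) stop("no topology for ", base, ":", atom)
  d <- -rowSums(vapply(nbs, function(nb) vunit(xyz[nb, ] - xyz[atom, ]),
                       numeric(3L)))
  vunit(d)
}

.tk_env <- new.env(parent = emptyenv())

#' Hydrogen-bond triad templates
#'
#' Returns the registry of initial Hoogsteen-type (H) and
#' reverse-Hoogsteen-type (RH) hydrogen-bond templates for every base
#' triplet, plus the named variant patterns observed to replace them in
#' stable trajectories. Shipped as an editable JSON data file under
#' `extdata` so the chemistry stays auditable.
#'
#' @return A list with elements `triads` (per-triad `H`/`RH` bond lists;
#'   each bond names the third-strand atom, the duplex atom, which duplex
#'   base carries it, and which side donates) and `variants` (named
#'   alternative patterns per triad, used by [classify_plane_pattern()]).
#' @export
hbond_templates <- function() {
  if (is.null(.tk_env$templates)) {
    path <- system.file("extdata", "hbond_templates.json",
                        package = "triplexkit", mustWork = TRUE)
    .tk_env$templates <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  .tk_env$templates
}

# "C+.G:C" -> triad key "C+.G"
triad_key <- function(triplet) sub(":.*$", "", triplet)

# Template bonds for a triplet + bond class, as a list of bonds
template_bonds <- function(triplet, class) {
  tri <- hbond_templates()$triads[[triad_key(triplet)]]
  if (is.null(tri)) stop("no triad template for ", triplet)
  tri[[class]]
}

HB_IDEAL <- 2.90  # idealized heavy-atom donor-acceptor distance, Angstrom

# Rigid placement of the third-strand base of one triplet relative to the
# standard frame of the duplex purine it bonds to.  The template bonds are
# turned into point correspondences (donor and its hydrogen onto the
# acceptor's lone-pair direction at the ideal distance) and solved by
# superposition; the result is cached per (triplet, class).
triad_transform <- function(triplet, class) {
  key <- paste0(triplet, "|", class)
  if (!is.null(.tk_env$triads[[key]])) return(.tk_env$triads[[key]])

  parts <- strsplit(triad_key(triplet), ".", fixed = TRUE)[[1L]]
  third_base <- sub("\\+$", "", parts[1L])
  third_prot <- grepl("\\+$", parts[1L])
  pur <- parts[2L]

  mob <- std_base(third_base, protonated = third_prot, flip = (class == "RH"))
  ref <- std_base(pur, with_h = TRUE)
  bonds <- template_bonds(triplet, class)

  # Each bond contributes correspondences; amino donors offer two hydrogens,
  # so every assignment is tried and the lowest-residual fit kept.
  per_bond <- lapply(bonds, function(b) {
    if (identical(b$donor, "third")) {
      # moving donor + its hydrogen onto the duplex acceptor lone pair
      lp <- lone_pair_dir(pur, b$duplex, .base_heavy[[pur]])
      tgt_d <- ref[b$duplex, ] + HB_IDEAL * lp
      tgt_h <- ref[b$duplex, ] + (HB_IDEAL - N_H_BOND) * lp
      hs <- hb_donors(third_base, third_prot)[[b$third]]
      lapply(hs, function(h) list(P = rbind(mob[b$third, ], mob[h, ]),
                                  Q = rbind(tgt_d, tgt_h)))
    } else {
      # duplex donor: each of its hydrogens defines a candidate site for
      # the moving acceptor; the moving acceptor's lone pair must point
      # back along the bond
      hs <- hb_donors(pur)[[b$duplex]]
      lp_m <- lone_pair_dir(third_base, b$third, mob)
      lapply(hs, function(h) {
        u <- vunit(ref[h, ] - ref[b$duplex, ])
        list(P = rbind(mob[b$third, ],
                       mob[b$third, ] + (HB_IDEAL - N_H_BOND) * lp_m),
             Q = rbind(ref[b$duplex, ] + HB_IDEAL * u,
                       ref[b$duplex, ] + N_H_BOND * u))
      })
    }
  })
  combos <- expand.grid(lapply(per_bond, seq_along))
  k <- NULL
  for (ci in seq_len(nrow(combos))) {
    P <- NULL; Q <- NULL
    for (bi in seq_along(per_bond)) {
      pick <- per_bond[[bi]][[combos[ci, bi]]]
      P <- rbind(P, pick$P); Q <- rbind(Q, pick$Q)
    }
    # out-of-plane anchors keep the fitted rotation in the triplet plane
    cp <- colMeans(P); cq <- colMeans(Q)
    P <- rbind(P, cp + c(0, 0, 3), cp - c(0, 0, 3))
    Q <- rbind(Q, cq + c(0, 0, 3), cq - c(0, 0, 3))
    fit <- kabsch(P, Q)
    if (is.null(k) || fit$rmsd < k$rmsd) k <- fit
  }

  # In-plane refinement: the point correspondences over-constrain the
  # bond lengths (real Hoogsteen triads do not have perfectly lone-pair-
  # aligned bonds), so polish (theta, tx, ty) against the actual
  # donor-acceptor distances with soft alignment regularizers.
  # alignment weight per bond: ring N-H donors have a rigid direction and
  # dominate the pose (near-linear in real Hoogsteen triads); amino
  # donors tolerate more bending
  w_ring <- 3; w_amino <- 0.4
  w_clash <- 2
  # steric reference: both duplex bases of the plane (pyrimidine flipped
  # into the pair frame), heavy atoms only
  pyr_base <- c(G = "C", A = "T")[[pur]]
  clash_ref <- rbind(.base_heavy[[pur]],
                     .base_heavy[[pyr_base]] %*% diag(c(1, -1, -1)))
  mob_heavy <- mob[!grepl("^H", rownames(mob)), , drop = FALSE]
  bond_terms <- lapply(bonds, function(b) {
    if (identical(b$donor, "third")) {
      hs <- hb_donors(third_base, third_prot)[[b$third]]
      list(kind = "third_donor", d_mob = b$third, h_mob = hs,
           w = if (length(hs) == 1L) w_ring else w_amino,
           a_ref = ref[b$duplex, ],
           lp_ref = lone_pair_dir(pur, b$duplex, .base_heavy[[pur]]))
    } else {
      hs <- hb_donors(pur)[[b$duplex]]
      list(kind = "duplex_donor", a_mob = b$third, w = w_amino,
           d_ref = ref[b$duplex, ],
           h_ref = lapply(hs, function(h) ref[h, ]),
           lp_mob = lone_pair_dir(third_base, b$third, mob))
    }
  })
  objective <- function(par) {
    Rz <- rot_z(rad2deg(par[1L]))
    tr <- c(par[2L], par[3L], 0)
    val <- 0
    for (bt in bond_terms) {
      if (bt$kind == "third_donor") {
        D <- as.numeric(Rz %*% mob[bt$d_mob, ]) + tr
        d <- vnorm(D - bt$a_ref)
        val <- val + 4 * pmax(0, abs(d - HB_IDEAL) - 0.15)^2
        u <- (bt$a_ref - D) / d
        co <- max(vapply(bt$h_mob, function(h) {
          H <- as.numeric(Rz %*% mob[h, ]) + tr
          sum(u * vunit(H - D))
        }, 0))
        val <- val + bt$w * (1 - co) + 0.15 * (1 - sum(-u * bt$lp_ref))
      } else {
        A <- as.numeric(Rz %*% mob[bt$a_mob, ]) + tr
        d <- vnorm(A - bt$d_ref)
        val <- val + 4 * pmax(0, abs(d - HB_IDEAL) - 0.15)^2
        u <- (A - bt$d_ref) / d
        co <- max(vapply(bt$h_ref, function(H) {
          sum(u * vunit(H - bt$d_ref))
        }, 0))
        lp <- as.numeric(Rz %*% bt$lp_mob)
        val <- val + bt$w * (1 - co) + 0.15 * (1 - sum(-u * lp))
      }
    }
    mobT <- sweep(mob_heavy %*% t(Rz), 2L, tr, "+")
    dd <- sqrt(outer(rowSums(mobT^2), rowSums(clash_ref^2), "+") -
                 2 * mobT %*% t(clash_ref))
    val + w_clash * sum(pmax(0, 2.8 - dd)^2)
  }
  # global search: the Kabsch pose plus a grid of rotations, each with a
  # translation start that puts the first bond on target
  par0 <- c(atan2(k$R[2L, 1L], k$R[1L, 1L]), k$t[1L], k$t[2L])
  starts <- list(par0)
  b1 <- bond_terms[[1L]]
  anchor_mob <- if (b1$kind == "third_donor") b1$d_mob else b1$a_mob
  anchor_tgt <- if (b1$kind == "third_donor")
    b1$a_ref + HB_IDEAL * b1$lp_ref else
    b1$d_ref + HB_IDEAL * vunit(b1$h_ref[[1L]] - b1$d_ref)
  for (th in deg2rad(seq(0, 345, by = 15))) {
    t0 <- anchor_tgt - as.numeric(rot_z(rad2deg(th)) %*% mob[anchor_mob, ])
    starts[[length(starts) + 1L]] <- c(th, t0[1L], t0[2L])
  }
  opt <- NULL
  for (s in starts) {
    o <- stats::optim(s, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }

  # Robustness polish: maximize the worst detection margin over the
  # template bonds, scoring distance and angle in comparable units (the
  # cutoffs are 3.5 A / 140 deg; thermal jitter of ~0.1 A per atom moves
  # a bond length by ~0.14 A and a bond angle by ~7.5 deg), so the built
  # pose tolerates noise on every bond rather than perfecting a subset.
  margin_of <- function(par) {
    Rz <- rot_z(rad2deg(par[1L]))
    tr <- c(par[2L], par[3L], 0)
    worst <- Inf; lp_reg <- 0
    hda <- function(D, H, A) {  # actual donor-hydrogen-acceptor angle
      angle3(D, H, A)
    }
    for (bt in bond_terms) {
      if (bt$kind == "third_donor") {
        D <- as.numeric(Rz %*% mob[bt$d_mob, ]) + tr
        d <- vnorm(D - bt$a_ref)
        u <- (bt$a_ref - D) / d
        ang <- max(vapply(bt$h_mob, function(h) {
          hda(D, as.numeric(Rz %*% mob[h, ]) + tr, bt$a_ref)
        }, 0))
        lp_reg <- lp_reg + (1 - sum(-u * bt$lp_ref))
      } else {
        A <- as.numeric(Rz %*% mob[bt$a_mob, ]) + tr
        d <- vnorm(A - bt$d_ref)
        u <- (A - bt$d_ref) / d
        ang <- max(vapply(bt$h_ref, function(H) {
          hda(bt$d_ref, H, A)
        }, 0))
        lp_reg <- lp_reg + (1 - sum(-u * as.numeric(Rz %*% bt$lp_mob)))
      }
      m <- min((3.5 - d) / 0.14, (d - 2.55) / 0.14, (ang - 140) / 7.5)
      worst <- min(worst, m)
    }
    mobT <- sweep(mob_heavy %*% t(Rz), 2L, tr, "+")
    dd <- sqrt(outer(rowSums(mobT^2), rowSums(clash_ref^2), "+") -
                 2 * mobT %*% t(clash_ref))
    -worst + w_clash * sum(pmax(0, 2.8 - dd)^2) + 0.05 * lp_reg
  }
  o2 <- stats::optim(opt$par, margin_of, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-12))
  if (o2$value < margin_of(opt$par)) opt <- o2
  Rfin <- rot_z(rad2deg(opt$par[1L]))
  tfin <- c(opt$par[2L], opt$par[3L], 0)
  out <- list(R = Rfin, t = tfin, residual = opt$value,
              flip = (class == "RH"),
              third_base = third_base, third_prot = third_prot)
  if (is.null(.tk_env$triads)) .tk_env$triads <- list()
  .tk_env$triads[[key]] <- out
  out
}
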