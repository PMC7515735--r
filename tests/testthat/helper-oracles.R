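# Shared fixtures and independent oracles for the test suite.

# cache of built models so repeated tests do not rebuild
.fixtures <- new.env(parent = emptyenv())

built <- function(label, form = "B", n_repeats = 3L) {
  key <- paste(label, form, n_repeats)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- suppressWarnings(
      build_triplex(parse_label(label), n_repeats = n_repeats,
                    form = form))
  .fixtures[[key]]
}

built_duplex <- function(form = "B", chem = c("DNA", "DNA"),
                         n_repeats = 3L) {
  key <- paste("dx", form, paste(chem, collapse = ""), n_repeats)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_duplex(strrep("GAA", n_repeats),
                                     form = form, chemistries = chem)
  .fixtures[[key]]
}

# rigid-body transform of a whole model (rotation about an arbitrary
# axis + translation), for invariance tests
rigid_move <- function(model, axis = c(1, 2, 3), angle = 35,
                       shift = c(4, -7, 11)) {
  R <- triplexkit:::rot_axis(axis, angle)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  model$atoms[, c("x", "y", "z")] <-
    sweep(xyz %*% t(R), 2L, shift, "+")
  model
}

# Oracle 1: brute-force effective hydrogen-bond number -------------------
# Enumerate ALL donor/acceptor atom pairs under the raw cutoffs, then
# filter to same-plane third-strand/duplex pairs; no reuse of the
# package's candidate machinery.
brute_force_heff <- function(model, d_cut = 3.5, ang_cut = 140) {
  at <- model$atoms
  res <- model$residues
  spec <- model$spec
  n <- model$strands$n[1]
  role <- structure(model$strands$role, names = model$strands$strand)
  p2t <- triplexkit:::plane_to_third(spec, n)
  plane_of <- function(s, r) {
    switch(role[[s]], purine = r, pyrimidine = n + 1 - r,
           third = { i <- which(p2t == r); if (length(i)) i else NA })
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  total <- 0L
  per <- integer(n)
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      ri <- res[i, ]; rj <- res[j, ]
      if (ri$strand == rj$strand && ri$res == rj$res) next
      # donor on residue i, acceptor on residue j
      third_i <- role[[ri$strand]] == "third"
      third_j <- role[[rj$strand]] == "third"
      if (third_i == third_j) next
      dn <- triplexkit:::hb_donors(ri$base, ri$protonated)
      ac <- triplexkit:::hb_acceptors(rj$base, rj$protonated)
      sel_i <- at$strand == ri$strand & at$res == ri$res
      sel_j <- at$strand == rj$strand & at$res == rj$res
      for (d in names(dn)) for (a in ac) {
        ii <- which(sel_i & at$elety == d)
        jj <- which(sel_j & at$elety == a)
        if (!length(ii) || !length(jj)) next
        dd <- sqrt(sum((xyz[ii, ] - xyz[jj, ])^2))
        if (dd > d_cut) next
        ok <- FALSE
        for (h in dn[[d]]) {
          hh <- which(sel_i & at$elety == h)
          if (!length(hh)) next
          u <- xyz[ii, ] - xyz[hh, ]; v <- xyz[jj, ] - xyz[hh, ]
          ang <- acos(min(1, max(-1, sum(u * v) /
            sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
          if (ang >= ang_cut) ok <- TRUE
        }
        if (!ok) next
        pi_ <- plane_of(ri$strand, ri$res)
        pj_ <- plane_of(rj$strand, rj$res)
        if (!is.na(pi_) && !is.na(pj_) && pi_ == pj_) {
          total <- total + 1L
          per[pi_] <- per[pi_] + 1L
        }
      }
    }
  }
  list(total = total, per_plane = per)
}

# Oracle 2: quaternion (Horn) superposition RMSD -------------------------
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Oracle 3: Monte-Carlo area of intersection of two convex polygons ------
mc_overlap_area <- function(p1, p2, n_pts = 2e5, seed = 42) {
  inside <- function(pts, poly) {
    np <- nrow(poly)
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(np)) {
      a <- poly[i, ]; b <- poly[if (i == np) 1 else i + 1, ]
      cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
        (b[2] - a[2]) * (pts[, 1] - a[1])
      ok <- ok & cr >= -1e-12
    }
    ok
  }
  set.seed(seed)
  lo <- pmin(apply(p1, 2, min), apply(p2, 2, min))
  hi <- pmax(apply(p1, 2, max), apply(p2, 2, max))
  pts <- cbind(runif(n_pts, lo[1], hi[1]), runif(n_pts, lo[2], hi[2]))
  frac <- mean(inside(pts, p1) & inside(pts, p2))
  frac * prod(hi - lo)
}

# minimal two-residue model with a parametric donor-H-acceptor geometry:
# thymine N3-H donor at the origin, adenine N7 acceptor placed at
# distance `d` (donor-acceptor) and donor-H-acceptor angle `ang`
probe_geometry_model <- function(d, ang) {
  hvec <- c(1.01, 0, 0)
  w <- c(cos(pi * (180 - ang) / 180), sin(pi * (180 - ang) / 180), 0)
  # acceptor position: |D-A| = d with the prescribed angle at H
  # solve length L along w from H
  # |H + L w| = d  (D at origin)
  h <- hvec
  qa <- 1; qb <- 2 * sum(h * w); qc <- sum(h^2) - d^2
  L <- (-qb + sqrt(qb^2 - 4 * qa * qc)) / 2
  acc <- h + L * w
  atoms <- data.frame(
    strand = c("C", "C", "A"), res = c(1L, 1L, 1L),
    base = c("T", "T", "A"), chem = "DNA",
    elety = c("N3", "H3", "N7"),
    x = c(0, h[1], acc[1]), y = c(0, h[2], acc[2]),
    z = c(0, h[3], acc[3]), stringsAsFactors = FALSE)
  residues <- data.frame(
    strand = c("C", "A"), res = 1L, base = c("T", "A"), chem = "DNA",
    protonated = FALSE, glycosidic = "anti", stringsAsFactors = FALSE)
  strands <- data.frame(strand = c("C", "A"),
                        role = c("third", "purine"),
                        chem = "DNA", n = 1L, stringsAsFactors = FALSE)
  triplex_model(atoms, residues, strands)
}

# apply the one-step helix transform (36 deg twist + 3.38 A rise) to the
# third strand of a built B-form model: every third-strand bond then
# links residue r to the duplex bases of plane r+1 with unchanged local
# geometry
shift_third_strand_one_plane <- function(model) {
  sel <- model$atoms$strand == "C"
  R <- triplexkit:::rot_z(36)
  xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  model$atoms[sel, c("x", "y", "z")] <-
    sweep(xyz %*% t(R), 2L, c(0, 0, 3.38), "+")
  model
}
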