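# Hydrogen-bond detection (3.5 Angstrom donor-acceptor / 140 degree
# donor-H-acceptor cutoffs), triplet-plane assignment, the effective
# hydrogen-bond number H_eff (the per-plane-filtered count of
# third-strand/duplex bonds), and classification of per-plane bond
# patterns against the H/RH templates and their named variants.

HB_DIST_CUTOFF <- 3.5   # heavy-atom donor-acceptor distance, Angstrom
HB_ANGLE_CUTOFF <- 140  # donor-hydrogen-acceptor angle, degrees

#' Plane assignment of a triplex model
#'
#' Maps every base-triplet plane (indexed 5' to 3' along the duplex
#' purine strand) to its three residues: the duplex purine, the duplex
#' pyrimidine and the third-strand residue at the spec's register (`NA`
#' where a shifted register leaves a plane bare).
#'
#' @param spec A [triplex_spec()].
#' @param n Number of planes (residues per strand).
#' @return Data frame with columns `plane`, `purine_res`, `pyrimidine_res`
#'   and `third_res`.
#' @export
plane_assignment <- function(spec, n = 9L) {
  data.frame(plane = seq_len(n),
             purine_res = seq_len(n),
             pyrimidine_res = n + 1L - seq_len(n),
             third_res = plane_to_third(spec, n))
}

# residue -> plane lookup for annotation; returns integer or NA
.plane_of_residue <- function(pa, strand_role, res) {
  switch(strand_role,
    purine = res,
    pyrimidine = pa$plane[match(res, pa$pyrimidine_res)],
    third = pa$plane[match(res, pa$third_res)],
    NA_integer_)
}

# donor (heavy, hydrogen) and acceptor atom tables of a model
.hb_sites <- function(model) {
  at <- model$atoms
  res <- model$residues
  donors <- NULL; acceptors <- NULL
  for (i in seq_len(nrow(res))) {
    rr <- res[i, ]
    sel <- at$strand == rr$strand & at$res == rr$res
    names_here <- at$elety[sel]
    idx_here <- which(sel)
    dn <- hb_donors(rr$base, rr$protonated)
    for (d in names(dn)) {
      if (!d %in% names_here) next
      for (h in dn[[d]]) {
        if (!h %in% names_here) next
        donors <- rbind(donors, data.frame(
          strand = rr$strand, res = rr$res, base = rr$base,
          donor = d, hydrogen = h,
          i_d = idx_here[match(d, names_here)],
          i_h = idx_here[match(h, names_here)],
          stringsAsFactors = FALSE))
      }
      if (!any(dn[[d]] %in% names_here))
        warning("donor ", rr$strand, ":", rr$res, ":", d,
                " has no hydrogen; skipped", call. = FALSE)
    }
    for (a in hb_acceptors(rr$base, rr$protonated)) {
      if (!a %in% names_here) next
      acceptors <- rbind(acceptors, data.frame(
        strand = rr$strand, res = rr$res, base = rr$base, acceptor = a,
        i_a = idx_here[match(a, names_here)], stringsAsFactors = FALSE))
    }
  }
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in a structure model
#'
#' All donor-acceptor heavy-atom pairs from different residues that
#' satisfy both the distance cutoff (donor-acceptor, default 3.5
#' Angstrom) and the angle cutoff (donor-hydrogen-acceptor, default 140
#' degrees). Records are annotated with the triplet-plane index of each
#' partner when the model carries a [triplex_spec()].
#'
#' @param model A [triplex_model()].
#' @param d_cut,ang_cut Detection cutoffs.
#' @param strict If `TRUE`, a donor without its hydrogen raises an error
#'   instead of a warning.
#' @return Data frame of bond records in deterministic order (strand,
#'   residue, atom), with columns including `distance`, `angle`,
#'   `donor_plane`, `acceptor_plane`, `same_plane`,
#'   `third_strand_involved` and `duplex_internal`.
#' @export
detect_hbonds <- function(model, d_cut = HB_DIST_CUTOFF,
                          ang_cut = HB_ANGLE_CUTOFF, strict = FALSE) {
  sites <- if (strict) {
    withCallingHandlers(.hb_sites(model),
      warning = function(w) stop(conditionMessage(w), call. = FALSE))
  } else .hb_sites(model)
  dn <- sites$donors; ac <- sites$acceptors
  if (is.null(dn) || is.null(ac)) return(.empty_bond_table())
  xyz <- axyz(model)
  # all donor x acceptor combinations, different residues
  id <- rep(seq_len(nrow(dn)), each = nrow(ac))
  ia <- rep(seq_len(nrow(ac)), times = nrow(dn))
  diff_res <- !(dn$strand[id] == ac$strand[ia] & dn$res[id] == ac$res[ia])
  id <- id[diff_res]; ia <- ia[diff_res]
  D <- xyz[dn$i_d[id], , drop = FALSE]
  H <- xyz[dn$i_h[id], , drop = FALSE]
  A <- xyz[ac$i_a[ia], , drop = FALSE]
  dist <- sqrt(rowSums((D - A)^2))
  keep <- dist <= d_cut
  id <- id[keep]; ia <- ia[keep]
  D <- D[keep, , drop = FALSE]; H <- H[keep, , drop = FALSE]
  A <- A[keep, , drop = FALSE]; dist <- dist[keep]
  u <- D - H; v <- A - H
  ang <- rad2deg(acos(pmin(1, pmax(-1,
    rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))))))
  keep <- ang >= ang_cut
  id <- id[keep]; ia <- ia[keep]; dist <- dist[keep]; ang <- ang[keep]
  if (!length(id)) return(.empty_bond_table())

  out <- data.frame(
    donor_strand = dn$strand[id], donor_res = dn$res[id],
    donor_base = dn$base[id], donor_atom = dn$donor[id],
    hydrogen = dn$hydrogen[id],
    acceptor_strand = ac$strand[ia], acceptor_res = ac$res[ia],
    acceptor_base = ac$base[ia], acceptor_atom = ac$acceptor[ia],
    distance = dist, angle = ang, stringsAsFactors = FALSE)
  # a donor-acceptor heavy pair counts once even if two hydrogens qualify
  pairkey <- paste(out$donor_strand, out$donor_res, out$donor_atom,
                   out$acceptor_strand, out$acceptor_res,
                   out$acceptor_atom)
  out <- out[order(pairkey, -out$angle), ]
  out <- out[!duplicated(paste(out$donor_strand, out$donor_res,
                               out$donor_atom, out$acceptor_strand,
                               out$acceptor_res, out$acceptor_atom)), ]

  spec <- model$spec
  n <- model$strands$n[1L]
  role_of <- structure(model$strands$role, names = model$strands$strand)
  if (!is.null(spec)) {
    pa <- plane_assignment(spec, n)
    out$donor_plane <- mapply(function(s, r)
      .plane_of_residue(pa, role_of[[s]], r), out$donor_strand,
      out$donor_res)
    out$acceptor_plane <- mapply(function(s, r)
      .plane_of_residue(pa, role_of[[s]], r), out$acceptor_strand,
      out$acceptor_res)
  } else {
    out$donor_plane <- NA_integer_; out$acceptor_plane <- NA_integer_
  }
  out$third_strand_involved <- role_of[out$donor_strand] == "third" |
    role_of[out$acceptor_strand] == "third"
  out$duplex_internal <- !out$third_strand_involved
  out$same_plane <- !is.na(out$donor_plane) & !is.na(out$acceptor_plane) &
    out$donor_plane == out$acceptor_plane
  out <- out[order(out$donor_strand, out$donor_res, out$donor_atom,
                   out$acceptor_strand, out$acceptor_res,
                   out$acceptor_atom), ]
  rownames(out) <- NULL
  out
}

.empty_bond_table <- function() {
  data.frame(donor_strand = character(), donor_res = integer(),
             donor_base = character(), donor_atom = character(),
             hydrogen = character(), acceptor_strand = character(),
             acceptor_res = integer(), acceptor_base = character(),
             acceptor_atom = character(), distance = numeric(),
             angle = numeric(), donor_plane = integer(),
             acceptor_plane = integer(), third_strand_involved = logical(),
             duplex_internal = logical(), same_plane = logical(),
             stringsAsFactors = FALSE)
}

#' Effective hydrogen-bond number of the third strand
#'
#' \eqn{H^{eff}_i} counts only the hydrogen bonds that the third-strand
#' base of plane i forms with the duplex bases of the *same* plane;
#' inter-plane bonds (which do not stabilize the triplex geometry) and
#' Watson-Crick duplex-internal bonds are excluded.
#' \eqn{H^{eff} = \sum_i H^{eff}_i}.
#'
#' @param model A [triplex_model()] with a spec.
#' @param bonds Optional precomputed [detect_hbonds()] table.
#' @param exclude_terminal Drop the two terminal planes from the total
#'   (mirrors restraint conventions against end fraying); default
#'   `FALSE`.
#' @return List with `total` and `per_plane` (named by plane index).
#' @export
effective_hbonds <- function(model, bonds = NULL,
                             exclude_terminal = FALSE) {
  if (is.null(model$spec)) stop("model carries no triplex_spec")
  if (is.null(bonds)) bonds <- detect_hbonds(model)
  n <- model$strands$n[1L]
  per <- integer(n); names(per) <- seq_len(n)
  sel <- bonds$third_strand_involved & bonds$same_plane &
    !bonds$duplex_internal
  if (any(sel)) {
    tab <- table(bonds$donor_plane[sel])
    per[names(tab)] <- as.integer(tab)
  }
  keep <- if (exclude_terminal) 2:(n - 1L) else seq_len(n)
  list(total = sum(per[keep]), per_plane = per)
}

# canonical signature of a set of third-strand/duplex bonds on one plane
.pattern_signature <- function(third_atom, duplex_atom, duplex_role) {
  if (!length(third_atom)) return("")
  paste(sort(paste0(third_atom, "-", duplex_atom,
                    ifelse(duplex_role == "pyrimidine", "(Y)", ""))),
        collapse = "+")
}

.bonds_signature <- function(bonds) {
  # bonds: list of template-bond entries
  .pattern_signature(
    vapply(bonds, `[[`, "", "third"),
    vapply(bonds, `[[`, "", "duplex"),
    vapply(bonds, function(b)
      if (identical(b$duplex_base, "pyrimidine")) "pyrimidine" else
        "purine", ""))
}

#' Classify the hydrogen-bond pattern of one plane
#'
#' Matches the observed set of third-strand/duplex donor-acceptor pairs
#' on a plane against the initial H/RH template for the plane's triplet
#' type and the registry of named variant patterns; anything else is
#' reported verbatim as a novel pattern.
#'
#' @param plane_bonds Rows of a [detect_hbonds()] table belonging to one
#'   plane (third-strand bonds only are considered).
#' @param triplet Triplet type string, e.g. `"C+.G:C"`.
#' @param class `"H"` or `"RH"`.
#' @return List with `pattern` (`"initial"`, a variant name,
#'   `"none"`, or `"novel:<signature>"`) and `flag`
#'   (`"initial"`, `"variant"` or `"none"`).
#' @export
classify_plane_pattern <- function(plane_bonds, triplet, class) {
  pb <- plane_bonds[plane_bonds$third_strand_involved &
                      plane_bonds$same_plane, , drop = FALSE]
  # which side of each bond is the third strand (chain C by convention)
  third_atom <- ifelse(pb$donor_strand == "C", pb$donor_atom,
                       pb$acceptor_atom)
  duplex_atom <- ifelse(pb$donor_strand == "C", pb$acceptor_atom,
                        pb$donor_atom)
  duplex_strand <- ifelse(pb$donor_strand == "C", pb$acceptor_strand,
                          pb$donor_strand)
  duplex_role <- ifelse(duplex_strand == "B", "pyrimidine", "purine")
  sig <- .pattern_signature(third_atom, duplex_atom, duplex_role)
  if (sig == "") return(list(pattern = "none", flag = "none"))
  tri_key <- triad_key(triplet)
  init_sig <- .bonds_signature(template_bonds(triplet, class))
  if (identical(sig, init_sig))
    return(list(pattern = paste0("initial ", class, "-type"),
                flag = "initial"))
  vars <- hbond_templates()$variants[[tri_key]]
  for (v in vars) {
    if (identical(sig, .bonds_signature(v$bonds)))
      return(list(pattern = v$name, flag = "variant"))
  }
  list(pattern = paste0("novel:", sig), flag = "variant")
}

#' Per-plane hydrogen-bond pattern occupancies along a trajectory
#'
#' Classifies the bond pattern of one plane in every frame and reports
#' the per-frame sequence plus aggregate occupancy fractions (which sum
#' to 1 over the observed patterns).
#'
#' @param traj A [triplex_traj()] (or list of models).
#' @param plane Plane index.
#' @param frames Optional frame subset.
#' @return List with `timeline` (character per frame) and `occupancy`
#'   (named numeric, sums to 1).
#' @export
pattern_timeline <- function(traj, plane, frames = NULL) {
  traj <- as_traj(traj)
  spec <- traj$model$spec
  if (is.null(spec)) stop("trajectory carries no triplex_spec")
  n <- traj$model$strands$n[1L]
  st <- step_types(spec, n %/% 3L)
  triplet <- st$triplet[plane]
  cls <- st$bond_class[plane]
  if (is.na(triplet)) stop("plane ", plane,
                           " has no third-strand partner at this register")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  tl <- vapply(frames, function(f) {
    m <- traj_frame(traj, f)
    b <- detect_hbonds(m)
    pb <- b[!is.na(b$donor_plane) & !is.na(b$acceptor_plane) &
              b$donor_plane == plane & b$acceptor_plane == plane, ,
            drop = FALSE]
    classify_plane_pattern(pb, triplet, cls)$pattern
  }, "")
  occ <- table(tl) / length(tl)
  list(timeline = tl, occupancy = sort(c(occ), decreasing = TRUE))
}
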