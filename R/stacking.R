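# Mean-field pi-pi stacking metric for the third strand of a triplex:
# per-plane tilt angle alpha, effective ring area
# A_eff = A0 (cos alpha - sin alpha) with a 45-degree cutoff and the
# hydrogen-bond coupling rule (A_eff forced to zero on planes with no
# in-plane third-strand bond), geometric-mean step stacking
# S_eff_i = sqrt(A_eff_i A_eff_{i+1}), and the total S_eff.

#' Least-squares base-plane normal of one residue
#'
#' Unit normal of the aromatic ring atoms (both rings for purines), with
#' the sign canonicalized against the ring circulation so the normal is
#' equivariant under rigid rotation.
#'
#' @param model A [triplex_model()].
#' @param strand,res Residue address.
#' @return Unit 3-vector.
#' @export
base_plane_normal <- function(model, strand, res) {
  rr <- residue_row(model, strand, res)
  if (!nrow(rr)) stop("no residue ", strand, ":", res)
  ring <- res_xyz(model, strand, res, .base_rings[[rr$base]])
  fit_plane_normal(ring)
}

# pooled Watson-Crick pair normal of one plane
wc_plane_normal <- function(model, plane) {
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  n <- model$strands$n[model$strands$strand == sA]
  ra <- residue_row(model, sA, plane)
  rb <- residue_row(model, sB, n + 1L - plane)
  ring <- rbind(res_xyz(model, sA, plane, .base_rings[[ra$base]]),
                res_xyz(model, sB, n + 1L - plane, .base_rings[[rb$base]]))
  fit_plane_normal(ring)
}

#' Tilt angle alpha of a third-strand base
#'
#' Unsigned angle between the third-strand base normal and the pooled
#' Watson-Crick pair normal of the same plane, folded into [0, 90]
#' degrees (antiparallel normals describe the same stacking geometry).
#'
#' @param model A [triplex_model()] with a spec.
#' @param plane Plane index (must have a third-strand partner).
#' @return Angle in degrees.
#' @export
alpha_angle <- function(model, plane) {
  spec <- model$spec
  if (is.null(spec)) stop("model carries no triplex_spec")
  n <- model$strands$n[1L]
  r3 <- plane_to_third(spec, n)[plane]
  if (is.na(r3)) stop("plane ", plane, " has no third-strand residue")
  n3 <- base_plane_normal(model, strand_of_role(model, "third"), r3)
  nw <- wc_plane_normal(model, plane)
  a <- rad2deg(acos(min(1, max(-1, abs(sum(n3 * nw))))))
  a
}

#' Effective stacking area of a third-strand base
#'
#' \eqn{A^{eff}_i = A^0_i (\cos\alpha_i - \sin\alpha_i)}, where
#' \eqn{A^0_i} is the aromatic ring area of the base (4.95 Angstrom^2
#' for T/C/U, 8.29 for A/G) and \eqn{\alpha_i} the tilt angle. The
#' projection term rewards parallel stacking and the sine term penalizes
#' T-shaped stacking. Two forcing rules apply: \eqn{A^{eff}_i = 0}
#' whenever \eqn{\alpha_i > 45°}, and whenever the base forms no
#' in-plane hydrogen bond with the duplex (\eqn{H^{eff}_i = 0}) — a
#' perfectly stacked but detached strand scores zero.
#'
#' @param base Base letter(s) (`A`, `G`, `C`, `T`, `U`).
#' @param alpha Tilt angle(s), degrees in [0, 90].
#' @param h_eff Per-plane hydrogen-bond count(s).
#' @return Effective area(s), Angstrom^2.
#' @export
effective_area <- function(base, alpha, h_eff) {
  a0 <- .A0[base]
  if (any(is.na(a0))) stop("unknown base in: ",
                           paste(unique(base), collapse = ","))
  val <- unname(a0) * (cos(deg2rad(alpha)) - sin(deg2rad(alpha)))
  val[alpha > 45] <- 0
  val[h_eff == 0] <- 0
  pmax(val, 0)
}

#' Step stacking areas and their total
#'
#' \eqn{S^{eff}_i = \sqrt{A^{eff}_i A^{eff}_{i+1}}} between consecutive
#' third-strand bases, and \eqn{S^{eff} = \sum_i S^{eff}_i}.
#'
#' @param a_eff Per-base effective areas along the third strand.
#' @return List with `per_step` (length `n - 1`) and `total`.
#' @export
effective_stacking <- function(a_eff) {
  n <- length(a_eff)
  if (n < 2L) {
    warning("fewer than two planes: no stacking steps", call. = FALSE)
    return(list(per_step = numeric(0), total = 0))
  }
  per <- sqrt(a_eff[-n] * a_eff[-1L])
  list(per_step = per, total = sum(per))
}

#' Full third-strand stability metrics of one conformation
#'
#' Computes, for every third-strand residue: the plane it sits on, its
#' in-plane hydrogen-bond count \eqn{H^{eff}_i}, tilt angle
#' \eqn{\alpha_i}, effective area \eqn{A^{eff}_i} (with the 45-degree
#' and hydrogen-bond forcing rules), then the step stackings and the
#' totals \eqn{H^{eff}} and \eqn{S^{eff}}.
#'
#' @param model A [triplex_model()] with a spec.
#' @param bonds Optional precomputed [detect_hbonds()] table.
#' @param exclude_terminal Exclude the terminal planes from the totals.
#' @return List with `per_plane` (data frame: `third_res`, `plane`,
#'   `h_eff`, `alpha`, `a_eff`), `s_eff_steps`, `h_eff` and `s_eff`.
#' @export
stacking_metrics <- function(model, bonds = NULL,
                             exclude_terminal = FALSE) {
  spec <- model$spec
  if (is.null(spec)) stop("model carries no triplex_spec")
  n <- model$strands$n[1L]
  hb <- effective_hbonds(model, bonds = bonds)
  i_plane <- third_to_plane(spec, n)
  tseq <- model$residues$base[model$residues$strand ==
                                strand_of_role(model, "third")]
  sC <- strand_of_role(model, "third")
  h_eff <- alpha <- a_eff <- numeric(n)
  for (r in seq_len(n)) {
    i <- i_plane[r]
    if (i < 1L || i > n) {
      h_eff[r] <- 0; alpha[r] <- NA_real_; a_eff[r] <- 0
      next
    }
    if (!has_ring_atoms(model, sC, r)) {
      # damaged/truncated residue: excluded from the metric
      h_eff[r] <- 0; alpha[r] <- NA_real_; a_eff[r] <- 0
      next
    }
    h_eff[r] <- hb$per_plane[i]
    alpha[r] <- alpha_angle(model, i)
    a_eff[r] <- effective_area(tseq[r], alpha[r], h_eff[r])
  }
  keep_res <- rep(TRUE, n)
  if (exclude_terminal) {
    term <- i_plane %in% c(1L, n) | i_plane < 1L | i_plane > n
    keep_res <- !term
  }
  a_use <- ifelse(keep_res, a_eff, 0)
  st <- effective_stacking(a_use)
  list(per_plane = data.frame(third_res = seq_len(n), plane = i_plane,
                              h_eff = h_eff, alpha = alpha,
                              a_eff = a_eff),
       s_eff_steps = st$per_step,
       h_eff = sum(h_eff[keep_res]),
       s_eff = st$total)
}

#' Theoretical metric maxima of a triplex topology
#'
#' The template hydrogen-bond count (upper reference for \eqn{H^{eff}})
#' and the coplanar fully-bonded stacking bound
#' \eqn{\sum_i \sqrt{A^0_i A^0_{i+1}}} (upper bound for \eqn{S^{eff}}),
#' used to normalize stability scores across base compositions.
#'
#' @param spec A [triplex_spec()].
#' @param n_repeats Repeats per strand.
#' @param exclude_terminal Match the metric option.
#' @return List with `h_max` and `s_max`.
#' @export
metric_maxima <- function(spec, n_repeats = 3L, exclude_terminal = FALSE) {
  st <- step_types(spec, n_repeats)
  n <- 3L * n_repeats
  nb <- vapply(seq_len(n), function(i) {
    if (is.na(st$triplet[i])) return(0L)
    length(template_bonds(st$triplet[i], st$bond_class[i]))
  }, 0L)
  i_plane <- third_to_plane(spec, n)
  tseq <- third_seq(spec, n_repeats)
  a0 <- unname(.A0[tseq])
  ok <- i_plane >= 1L & i_plane <= n
  if (exclude_terminal) ok <- ok & !(i_plane %in% c(1L, n))
  a0[!ok] <- 0
  keep_planes <- if (exclude_terminal) setdiff(which(!is.na(st$triplet)),
                                               c(1L, n))
    else which(!is.na(st$triplet))
  list(h_max = sum(nb[keep_planes]),
       s_max = sum(sqrt(a0[-n] * a0[-1L])))
}
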