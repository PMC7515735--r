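# Trajectory orchestration: per-frame H_eff / S_eff metrics, the 2-D
# stability histograms, and the stable/marginal/unstable call.

# Precomputed per-topology machinery for fast per-frame evaluation:
# same-plane third-strand/duplex donor-acceptor candidates and ring-atom
# index sets for the tilt angles.
.traj_machinery <- function(model) {
  spec <- model$spec
  n <- model$strands$n[1L]
  sites <- .hb_sites(model)
  pa <- plane_assignment(spec, n)
  role_of <- structure(model$strands$role, names = model$strands$strand)
  plane_of <- function(strand, res)
    .plane_of_residue(pa, role_of[[strand]], res)
  dn <- sites$donors; ac <- sites$acceptors
  dn$plane <- mapply(plane_of, dn$strand, dn$res)
  ac$plane <- mapply(plane_of, ac$strand, ac$res)
  dn$third <- role_of[dn$strand] == "third"
  ac$third <- role_of[ac$strand] == "third"
  id <- rep(seq_len(nrow(dn)), each = nrow(ac))
  ia <- rep(seq_len(nrow(ac)), times = nrow(dn))
  keep <- (dn$third[id] != ac$third[ia]) &
    !is.na(dn$plane[id]) & !is.na(ac$plane[ia]) &
    dn$plane[id] == ac$plane[ia]
  cand <- data.frame(i_d = dn$i_d[id[keep]], i_h = dn$i_h[id[keep]],
                     i_a = ac$i_a[ia[keep]], plane = dn$plane[id[keep]])
  # unique heavy donor-acceptor pair ids (bifurcated pairs stay distinct,
  # two hydrogens of one amino donor do not double count)
  cand$pair <- paste(cand$i_d, cand$i_a)

  third_strand <- strand_of_role(model, "third")
  i_plane <- third_to_plane(spec, n)
  at <- model$atoms
  ring_idx <- function(strand, res) {
    rr <- residue_row(model, strand, res)
    which(at$strand == strand & at$res == res &
            at$elety %in% .base_rings[[rr$base]])
  }
  sA <- strand_of_role(model, "purine")
  sB <- strand_of_role(model, "pyrimidine")
  planes <- lapply(seq_len(n), function(i) list(
    wc = c(ring_idx(sA, i), ring_idx(sB, n + 1L - i))))
  third_rings <- lapply(seq_len(n), function(r) ring_idx(third_strand, r))
  tseq <- model$residues$base[model$residues$strand == third_strand]
  list(cand = cand, planes = planes, third_rings = third_rings,
       i_plane = i_plane, tseq = tseq, n = n)
}

.plane_normal_xyz <- function(X) {
  ctr <- colMeans(X)
  ev <- eigen(crossprod(sweep(X, 2L, ctr)), symmetric = TRUE)
  ev$vectors[, 3L]
}

# metrics of one coordinate frame given precomputed machinery
.frame_metrics_fast <- function(xyz, mach, d_cut = HB_DIST_CUTOFF,
                                ang_cut = HB_ANGLE_CUTOFF,
                                exclude_terminal = FALSE) {
  cd <- mach$cand
  n <- mach$n
  h_per <- integer(n)
  if (nrow(cd)) {
    D <- xyz[cd$i_d, , drop = FALSE]
    H <- xyz[cd$i_h, , drop = FALSE]
    A <- xyz[cd$i_a, , drop = FALSE]
    dist <- sqrt(rowSums((D - A)^2))
    u <- D - H; v <- A - H
    ang <- rad2deg(acos(pmin(1, pmax(-1, rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))))))
    hit <- dist <= d_cut & ang >= ang_cut
    if (any(hit)) {
      ok <- cd[hit, c("pair", "plane")]
      ok <- ok[!duplicated(ok$pair), ]
      tab <- table(factor(ok$plane, levels = seq_len(n)))
      h_per <- as.integer(tab)
    }
  }
  alpha <- a_eff <- numeric(n)
  h_res <- integer(n)
  for (r in seq_len(n)) {
    i <- mach$i_plane[r]
    if (i < 1L || i > n) { alpha[r] <- NA_real_; next }
    h_res[r] <- h_per[i]
    n3 <- .plane_normal_xyz(xyz[mach$third_rings[[r]], , drop = FALSE])
    nw <- .plane_normal_xyz(xyz[mach$planes[[i]]$wc, , drop = FALSE])
    alpha[r] <- rad2deg(acos(min(1, abs(sum(n3 * nw)))))
    a_eff[r] <- effective_area(mach$tseq[r], alpha[r], h_res[r])
  }
  keep <- rep(TRUE, n)
  if (exclude_terminal)
    keep <- mach$i_plane > 1L & mach$i_plane < n
  a_use <- ifelse(keep, a_eff, 0)
  s_steps <- sqrt(a_use[-n] * a_use[-1L])
  list(h_per = h_res, alpha = alpha, a_eff = a_eff, s_steps = s_steps,
       h_eff = sum(h_res[keep]), s_eff = sum(s_steps))
}

#' Per-frame stability metrics of a trajectory
#'
#' Computes, for every selected frame, the per-plane effective
#' hydrogen-bond numbers, tilt angles and effective areas, the per-step
#' stackings, and the frame totals \eqn{H^{eff}} and \eqn{S^{eff}}.
#'
#' @param traj A [triplex_traj()], or a list of identically-topologized
#'   [triplex_model()]s (topology drift raises an error naming the
#'   frame).
#' @param frame_range Optional integer range of frames (e.g. `51:100`
#'   to emulate analysing only the tail of a run); default all frames.
#' @param exclude_terminal Exclude terminal planes from the totals.
#' @return An object of class `frame_metrics`: a list with `frames`
#'   (data frame `frame`, `h_eff`, `s_eff`), matrices `h_per_plane`,
#'   `alpha`, `a_eff`, `s_steps` (one row per frame) and the spec.
#' @export
analyze_trajectory <- function(traj, frame_range = NULL,
                               exclude_terminal = FALSE) {
  traj <- as_traj(traj)
  if (is.null(traj$model$spec)) stop("trajectory carries no triplex_spec")
  mach <- .traj_machinery(traj$model)
  frames <- if (is.null(frame_range)) seq_len(n_frames(traj)) else
    frame_range
  stopifnot(all(frames >= 1L), all(frames <= n_frames(traj)))
  n <- mach$n
  h_eff <- s_eff <- numeric(length(frames))
  hp <- al <- ae <- matrix(NA_real_, length(frames), n)
  ss <- matrix(NA_real_, length(frames), n - 1L)
  for (k in seq_along(frames)) {
    xyz <- matrix(traj$xyz[frames[k], ], ncol = 3L, byrow = TRUE)
    fm <- .frame_metrics_fast(xyz, mach,
                              exclude_terminal = exclude_terminal)
    h_eff[k] <- fm$h_eff; s_eff[k] <- fm$s_eff
    hp[k, ] <- fm$h_per; al[k, ] <- fm$alpha; ae[k, ] <- fm$a_eff
    ss[k, ] <- fm$s_steps
  }
  structure(list(
    frames = data.frame(frame = frames, h_eff = h_eff, s_eff = s_eff),
    h_per_plane = hp, alpha = al, a_eff = ae, s_steps = ss,
    spec = traj$model$spec, exclude_terminal = exclude_terminal),
    class = "frame_metrics")
}

#' @export
print.frame_metrics <- function(x, ...) {
  cat(sprintf(
    "<frame_metrics> %d frames [%s]  H_eff: %.1f +/- %.1f  S_eff: %.1f +/- %.1f\n",
    nrow(x$frames), x$spec$label, mean(x$frames$h_eff),
    stats::sd(x$frames$h_eff), mean(x$frames$s_eff),
    stats::sd(x$frames$s_eff)))
  invisible(x)
}

#' @export
as.data.frame.frame_metrics <- function(x, ...) x$frames

#' Two-dimensional stability histogram
#'
#' Histogram of the per-frame effective stacking area against the
#' effective hydrogen-bond number. Binning is deterministic:
#' left-closed bins `[k, k + width)` starting at zero, integer width on
#' the H axis and 1 Angstrom^2 on the S axis by default.
#'
#' @param metrics A [analyze_trajectory()] result.
#' @param h_bin,s_bin Bin widths.
#' @return An object of class `triplex_hist2d` with `counts` (H bins x
#'   S bins), `h_edges`, `s_edges` and provenance fields. Counts sum to
#'   the number of frames analysed.
#' @export
histogram2d <- function(metrics, h_bin = 1, s_bin = 1) {
  stopifnot(inherits(metrics, "frame_metrics"))
  h <- metrics$frames$h_eff; s <- metrics$frames$s_eff
  h_edges <- seq(0, (max(0, h) %/% h_bin + 1) * h_bin, by = h_bin)
  s_edges <- seq(0, (max(0, s) %/% s_bin + 1) * s_bin, by = s_bin)
  hi <- findInterval(h, h_edges, rightmost.closed = FALSE)
  si <- findInterval(s, s_edges, rightmost.closed = FALSE)
  counts <- matrix(0L, length(h_edges) - 1L, length(s_edges) - 1L)
  for (k in seq_along(hi))
    counts[hi[k], si[k]] <- counts[hi[k], si[k]] + 1L
  structure(list(counts = counts, h_edges = h_edges, s_edges = s_edges,
                 n_frames = length(h),
                 frame_range = range(metrics$frames$frame),
                 spec_label = metrics$spec$label),
            class = "triplex_hist2d")
}

#' @export
print.triplex_hist2d <- function(x, ...) {
  cat(sprintf("<triplex_hist2d> %s: %d frames, %d x %d bins\n",
              x$spec_label, x$n_frames, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Stability call from the upper-right-quadrant occupancy
#'
#' More stable triplexes populate the upper right of the (H_eff, S_eff)
#' plane. The score is the fraction of frames with
#' \eqn{H^{eff} \ge h^* H_{max}} and \eqn{S^{eff} \ge s^* S_{max}},
#' where the maxima are the per-spec theoretical references
#' ([metric_maxima()]); the call is monotone in the score. Stability
#' judgements of this kind are usually made visually from the
#' histograms; these numeric cut points are an explicit, reproducible
#' proxy.
#'
#' @param x A `frame_metrics` object (or a `triplex_hist2d`; bins whose
#'   lower edges reach the thresholds are counted).
#' @param spec The [triplex_spec()] (taken from `x` when present).
#' @param h_star,s_star Quadrant thresholds as fractions of the maxima.
#' @param stable_cut,unstable_cut Score cut points: `>= stable_cut` is
#'   stable, `< unstable_cut` unstable, otherwise marginal.
#' @param n_repeats Repeats per strand (for the maxima).
#' @return List with `call` (`"stable"`, `"marginal"` or `"unstable"`),
#'   `score`, `h_max`, `s_max`.
#' @export
stability_call <- function(x, spec = NULL, h_star = 0.5, s_star = 0.5,
                           stable_cut = 0.8, unstable_cut = 0.2,
                           n_repeats = 3L) {
  if (inherits(x, "frame_metrics")) {
    spec <- x$spec
    mm <- metric_maxima(spec, n_repeats,
                        exclude_terminal = isTRUE(x$exclude_terminal))
    ok <- x$frames$h_eff >= h_star * mm$h_max &
      x$frames$s_eff >= s_star * mm$s_max
    score <- mean(ok)
  } else if (inherits(x, "triplex_hist2d")) {
    if (is.null(spec)) stop("supply the spec alongside a histogram")
    mm <- metric_maxima(spec, n_repeats)
    hlo <- x$h_edges[-length(x$h_edges)]
    slo <- x$s_edges[-length(x$s_edges)]
    sel <- outer(hlo >= h_star * mm$h_max, slo >= s_star * mm$s_max,
                 FUN = "&")
    score <- sum(x$counts[sel]) / x$n_frames
  } else stop("x must be frame_metrics or triplex_hist2d")
  call <- if (score >= stable_cut) "stable"
    else if (score < unstable_cut) "unstable"
    else "marginal"
  list(call = call, score = score, h_max = mm$h_max, s_max = mm$s_max)
}
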