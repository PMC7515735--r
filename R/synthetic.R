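# Labelled synthetic trajectory generator. Emulates the four behaviours
# seen in triplex dynamics so the analysis pipeline can be exercised and
# validated without molecular-dynamics input: a stable triplex (thermal
# jitter only), progressive detachment of the third strand, individual
# base flip-out events, and the pathological "perfectly stacked but
# detached" third strand that the coupled metrics must score as zero.

#' Synthetic trajectory scenario configuration
#'
#' @param scenario One of `"stable"`, `"detaching"`, `"flipping"`,
#'   `"stacked_detached"`.
#' @param n_frames Number of frames (>= 1).
#' @param jitter_sigma Isotropic per-atom Gaussian noise, Angstrom
#'   (applied independently per frame; frame 1 is the exact build).
#' @param detach_rate Rigid third-strand displacement per frame along
#'   the groove-exit direction (Angstrom/frame; `detaching` only). The
#'   default 0.15 makes a 100-frame detaching run lose its bonds within
#'   the first handful of frames, keeping the scenario cleanly separated
#'   from the stable one.
#' @param flip_schedule Data frame with columns `plane`, `start_frame`,
#'   `rotation` (degrees about the glycosidic bond). Default for the
#'   `flipping` scenario: planes 3 to 7 flip by 90 degrees from frame 11
#'   on — a majority of planes, so the scenario is a ground-truth
#'   unstable case.
#' @param seed Integer seed; identical seeds give identical
#'   trajectories.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("stable", "detaching",
                                         "flipping", "stacked_detached"),
                            n_frames = 100L, jitter_sigma = 0.1,
                            detach_rate = 0.15, flip_schedule = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_frames >= 1L, jitter_sigma >= 0, detach_rate >= 0)
  if (is.null(flip_schedule) && scenario == "flipping")
    flip_schedule <- data.frame(plane = 3:7, start_frame = 11L,
                                rotation = 90)
  structure(list(scenario = scenario, n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma, detach_rate = detach_rate,
                 flip_schedule = flip_schedule, seed = as.integer(seed)),
            class = "scenario_config")
}

# groove-exit direction: from the duplex helix axis through the
# third-strand centroid, perpendicular to the axis
.groove_exit_dir <- function(model) {
  sC <- strand_of_role(model, "third")
  dup <- model$atoms$strand != sC
  xyz <- axyz(model)
  ctr_dup <- colMeans(xyz[dup, , drop = FALSE])
  # helix axis: dominant direction of the duplex pair centers; for built
  # models this is the global z axis, recovered here from the geometry
  pf <- pair_frames(model)
  origins <- t(vapply(pf, `[[`, numeric(3L), "o"))
  ax <- vunit(origins[nrow(origins), ] - origins[1L, ])
  ctr3 <- colMeans(xyz[!dup, , drop = FALSE])
  v <- ctr3 - ctr_dup
  vunit(v - sum(v * ax) * ax)
}

#' Generate a labelled synthetic trajectory
#'
#' Frame 1 is the idealized build of the spec; subsequent frames add
#' independent per-atom Gaussian jitter plus the scenario transform
#' (rigid displacement of the third strand, scheduled base flips about
#' the glycosidic bond, or a constant stacked-but-detached displacement,
#' which is applied to every frame including the first). Per-frame,
#' per-plane ground-truth labels (attached / flipped) are evaluated on
#' the noise-free transformed geometry.
#'
#' @param spec A [triplex_spec()].
#' @param config A [scenario_config()].
#' @param n_repeats,form Passed to [build_triplex()].
#' @return A [triplex_traj()] with `labels` (data frame `frame`,
#'   `plane`, `attached`, `flipped`) and the config attached.
#' @export
generate_trajectory <- function(spec, config, n_repeats = 3L,
                                form = "B") {
  stopifnot(inherits(config, "scenario_config"))
  model <- suppressWarnings(build_triplex(spec, n_repeats, form))
  n <- model$strands$n[1L]
  at <- model$atoms
  x0 <- axyz(model)
  third_sel <- at$strand == strand_of_role(model, "third")
  exit_dir <- .groove_exit_dir(model)

  fs <- config$flip_schedule
  if (!is.null(fs)) {
    i_plane <- third_to_plane(spec, n)
    if (any(!fs$plane %in% which(!is.na(plane_to_third(spec, n)))))
      stop("flip_schedule refers to a plane without a third-strand ",
           "residue")
    fs$third_res <- plane_to_third(spec, n)[fs$plane]
  }

  # glycosidic axes for flips (from the clean build)
  flip_info <- NULL
  if (!is.null(fs)) {
    flip_info <- lapply(seq_len(nrow(fs)), function(k) {
      r <- fs$third_res[k]
      rr <- residue_row(model, "C", r)
      sel <- third_sel & at$res == r &
        at$elety %in% c(rownames(.base_heavy[[rr$base]]), "H1", "H3",
                        "H21", "H22", "H41", "H42", "H61", "H62")
      sel <- sel & at$elety != "C1'"
      c1 <- as.numeric(at[third_sel & at$res == r &
                            at$elety == "C1'", c("x", "y", "z")])
      nn <- as.numeric(at[third_sel & at$res == r &
                            at$elety == .glyco_n[[rr$base]],
                          c("x", "y", "z")])
      list(sel = which(sel), origin = c1,
           R = rot_axis(nn - c1, fs$rotation[k]),
           start = fs$start_frame[k], plane = fs$plane[k])
    })
  }

  # stacked_detached: a rigid translation along the helix axis clears
  # the whole duplex (a sideways rigid move cannot, because the strand
  # wraps around it), keeping the internal stacking geometry exactly
  sd_vec <- c(0, 0, 1) * (n * 3.38 + 10)
  clean_frame <- function(f) {
    xyz <- x0
    move <- switch(config$scenario,
      stable = NULL,
      detaching = config$detach_rate * (f - 1L) * exit_dir,
      flipping = NULL,
      stacked_detached = sd_vec)
    if (!is.null(move) && vnorm(move) > 0)
      xyz[third_sel, ] <- sweep(xyz[third_sel, , drop = FALSE], 2L,
                                move, "+")
    if (!is.null(flip_info)) {
      for (fl in flip_info) {
        if (f >= fl$start) {
          xyz[fl$sel, ] <- sweep(
            sweep(xyz[fl$sel, , drop = FALSE], 2L, fl$origin) %*%
              t(fl$R), 2L, fl$origin, "+")
        }
      }
    }
    xyz
  }

  # ground-truth labels from the noise-free geometry
  tb <- template_bond_atoms(model)
  key <- paste(at$strand, at$res, at$elety)
  ia <- match(paste(tb$third_strand, tb$third_res, tb$third_atom), key)
  ib <- match(paste(tb$duplex_strand, tb$duplex_res, tb$duplex_atom), key)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  nf <- config$n_frames
  xyz_mat <- matrix(NA_real_, nf, 3L * nrow(at))
  labels <- NULL
  for (f in seq_len(nf)) {
    cx <- clean_frame(f)
    d <- sqrt(rowSums((cx[ia, , drop = FALSE] - cx[ib, , drop = FALSE])^2))
    att <- tapply(d <= HB_DIST_CUTOFF, tb$plane, any)
    flipped_planes <- if (!is.null(fs))
      fs$plane[f >= fs$start_frame] else integer(0)
    labels <- rbind(labels, data.frame(
      frame = f, plane = as.integer(names(att)),
      attached = as.logical(att),
      flipped = as.integer(names(att)) %in% flipped_planes))
    if (f > 1L && config$jitter_sigma > 0)
      cx <- cx + matrix(stats::rnorm(length(cx), 0, config$jitter_sigma),
                        ncol = 3L)
    xyz_mat[f, ] <- as.numeric(t(cx))
  }
  triplex_traj(model, xyz_mat, labels = labels, config = config)
}
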