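# Structure data model shared by all geometric modules, plus PDB
# reading/writing (delegated to bio3d). Coordinates are Angstrom;
# residue and frame indexing is 1-based in R, PDB serials on write follow
# PDB conventions. Chains map to strands: A = duplex purine, B = duplex
# pyrimidine, C = third strand.

#' Assemble a structure model
#'
#' Low-level constructor for the container every geometric operation
#' consumes: a flat atom table plus residue- and strand-level metadata.
#'
#' @param atoms Data frame with columns `strand`, `res` (1-based index
#'   within the strand, 5' to 3'), `base`, `chem`, `elety` (PDB atom
#'   name), `x`, `y`, `z`.
#' @param residues Data frame with columns `strand`, `res`, `base`,
#'   `chem`, `protonated`, `glycosidic`.
#' @param strands Data frame with columns `strand`, `role`
#'   (`"purine"`, `"pyrimidine"` or `"third"`), `chem`, `n`.
#' @param spec Optional [triplex_spec()] the model realizes.
#' @param frame_index Frame number for trajectory members (1-based).
#' @return An object of class `triplex_model`.
#' @export
triplex_model <- function(atoms, residues, strands, spec = NULL,
                          frame_index = 1L) {
  stopifnot(all(c("strand", "res", "base", "chem", "elety",
                  "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  dup <- duplicated(atoms[, c("strand", "res", "elety")])
  if (any(dup)) stop("duplicate atom name within a residue: ",
                     paste(atoms$elety[dup][1L]))
  structure(list(atoms = atoms, residues = residues, strands = strands,
                 spec = spec, frame_index = frame_index),
            class = "triplex_model")
}

#' @export
print.triplex_model <- function(x, ...) {
  cat(sprintf("<triplex_model> %d strand(s), %d residues, %d atoms%s\n",
              nrow(x$strands), nrow(x$residues), nrow(x$atoms),
              if (!is.null(x$spec)) paste0("  [", x$spec$label, "]") else ""))
  for (i in seq_len(nrow(x$strands)))
    cat(sprintf("  %s: %-10s %s  n=%d\n", x$strands$strand[i],
                x$strands$role[i], x$strands$chem[i], x$strands$n[i]))
  invisible(x)
}

# coordinate matrix (n_atoms x 3)
axyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

`axyz<-` <- function(model, value) {
  model$atoms[, c("x", "y", "z")] <- value
  model
}

# atom selection -> coordinate matrix with elety rownames
res_xyz <- function(model, strand, res, elety = NULL) {
  sel <- model$atoms$strand == strand & model$atoms$res == res
  if (!is.null(elety)) sel <- sel & model$atoms$elety %in% elety
  m <- axyz(model)[sel, , drop = FALSE]
  rownames(m) <- model$atoms$elety[sel]
  m
}

residue_row <- function(model, strand, res) {
  model$residues[model$residues$strand == strand &
                   model$residues$res == res, , drop = FALSE]
}

strand_of_role <- function(model, role) {
  s <- model$strands$strand[model$strands$role == role]
  if (!length(s)) stop("model has no strand with role '", role, "'")
  s[1L]
}

# does a residue have the ring atoms needed for plane/frame fitting?
has_ring_atoms <- function(model, strand, res) {
  rr <- residue_row(model, strand, res)
  if (!nrow(rr)) return(FALSE)
  ring <- .base_rings[[rr$base]]
  all(ring %in% model$atoms$elety[model$atoms$strand == strand &
                                    model$atoms$res == res])
}

# Trajectories ----------------------------------------------------------

#' Bundle a topology and per-frame coordinates into a trajectory
#'
#' @param model A [triplex_model()] providing the shared topology.
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms` columns
#'   (x1, y1, z1, x2, ...).
#' @param labels Optional per-frame ground-truth annotations.
#' @param config Optional generator configuration (see
#'   [scenario_config()]).
#' @return An object of class `triplex_traj`.
#' @export
triplex_traj <- function(model, xyz, labels = NULL, config = NULL) {
  stopifnot(inherits(model, "triplex_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(model$atoms))
    stop("xyz has ", ncol(xyz), " columns; topology has ",
         nrow(model$atoms), " atoms")
  structure(list(model = model, xyz = xyz, labels = labels,
                 config = config),
            class = "triplex_traj")
}

#' @export
print.triplex_traj <- function(x, ...) {
  cat(sprintf("<triplex_traj> %d frames x %d atoms%s\n", nrow(x$xyz),
              nrow(x$model$atoms),
              if (!is.null(x$config))
                paste0("  [", x$config$scenario, " scenario]") else ""))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure model
#' @param traj A [triplex_traj()].
#' @param i Frame index (1-based).
#' @return A [triplex_model()] with `frame_index = i`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- traj$model
  axyz(m) <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  m$frame_index <- i
  m
}

#' Combine a list of identically-topologized models into a trajectory
#' @param models List of [triplex_model()] objects sharing one topology.
#' @return A [triplex_traj()].
#' @export
as_traj <- function(models) {
  if (inherits(models, "triplex_traj")) return(models)
  if (inherits(models, "triplex_model")) models <- list(models)
  ref <- models[[1L]]
  key <- function(m) paste(m$atoms$strand, m$atoms$res, m$atoms$elety,
                           collapse = ";")
  rk <- key(ref)
  xyz <- matrix(NA_real_, length(models), 3L * nrow(ref$atoms))
  for (i in seq_along(models)) {
    if (!identical(key(models[[i]]), rk))
      stop("topology drift at frame ", i,
           ": atom list differs from frame 1")
    xyz[i, ] <- as.numeric(t(axyz(models[[i]])))
  }
  triplex_traj(ref, xyz)
}

# PDB I/O ----------------------------------------------------------------

.elesy_of <- function(elety) {
  s <- gsub("[^A-Za-z]", "", elety)
  ifelse(grepl("^H", s), "H", substr(s, 1L, 1L))
}

.resid_of <- function(base, chem, protonated = FALSE, custom_names = FALSE) {
  if (custom_names && protonated) return(paste0("D", base, "P"))
  if (chem == "DNA") paste0("D", base) else base
}

#' Write models or a trajectory to a (multi-model) PDB file
#'
#' Frames are delimited by MODEL/ENDMDL records; chains follow the
#' strand convention (A purine, B pyrimidine, C third strand).
#' Protonated residues keep standard residue names (the extra proton is
#' the H3/H1 atom); `custom_names = TRUE` emits DCP/DAP instead, for
#' force-field workflows that want distinct residue types.
#'
#' @param x A [triplex_model()], a list of them, or a [triplex_traj()].
#' @param file Output path.
#' @param custom_names Use DCP/DAP residue names for protonated residues.
#' @return Invisibly, the file path.
#' @export
write_triplex_pdb <- function(x, file, custom_names = FALSE) {
  traj <- as_traj(x)
  m <- traj$model
  at <- m$atoms
  resmeta <- m$residues
  pk <- paste(at$strand, at$res)
  rk <- paste(resmeta$strand, resmeta$res)
  prot <- resmeta$protonated[match(pk, rk)]
  resid <- mapply(.resid_of, at$base, at$chem, prot,
                  MoreArgs = list(custom_names = custom_names))
  # residue numbering restarts at 1 in each chain
  bio3d::write.pdb(file = file, xyz = traj$xyz,
                   resno = at$res, resid = resid, chain = at$strand,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   elesy = .elesy_of(at$elety))
  invisible(file)
}

# quick structural sanity pass over raw PDB text so parse failures carry
# a line number
.scan_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    coords <- suppressWarnings(as.numeric(
      c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
        substr(lines[i], 47, 54))))
    if (any(is.na(coords)))
      stop("unparseable coordinates in '", basename(path), "' line ", i,
           ": ", lines[i])
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB file into structure models
#'
#' Chains are mapped to strands; strand roles are inferred from base
#' composition (the all-purine chain is the duplex purine strand; when
#' two pyrimidine chains are present, chain order A/B/C decides which is
#' the duplex pyrimidine). Cytosines carrying an H3 atom and adenines
#' carrying H1 are flagged protonated; the glycosidic state is inferred
#' from the chi torsion where sugar atoms allow it. Residues missing
#' ring atoms are flagged unusable with a warning and are skipped by the
#' geometric metrics.
#'
#' @param path PDB file; MODEL/ENDMDL blocks delimit frames.
#' @param spec Optional [triplex_spec()] to attach to the models.
#' @return A list of [triplex_model()] objects (one per frame; a single
#'   frame still yields a length-1 list).
#' @export
read_triplex_pdb <- function(path, spec = NULL) {
  .scan_pdb_lines(path)
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  chains <- unique(at$chain)
  # per-chain 1-based residue index in file order
  atoms <- NULL; residues <- NULL; strands <- NULL
  for (ch in chains) {
    sel <- at$chain == ch
    resno <- at$resno[sel]
    idx <- match(resno, unique(resno))
    resid <- at$resid[sel]
    base <- sub("^D", "", resid)
    base <- sub("P$", "", base)   # DCP/DAP custom names
    chem <- ifelse(grepl("^D", resid) | base == "T", "DNA", "RNA")
    atoms <- rbind(atoms, data.frame(
      strand = ch, res = idx, base = base, chem = chem,
      elety = at$elety[sel], x = at$x[sel], y = at$y[sel], z = at$z[sel],
      stringsAsFactors = FALSE))
  }
  for (ch in unique(atoms$strand)) {
    sa <- atoms[atoms$strand == ch, ]
    for (r in unique(sa$res)) {
      ra <- sa[sa$res == r, ]
      base <- ra$base[1L]
      prot <- (base == "C" && "H3" %in% ra$elety) ||
        (base == "A" && "H1" %in% ra$elety)
      residues <- rbind(residues, data.frame(
        strand = ch, res = r, base = base, chem = ra$chem[1L],
        protonated = prot, glycosidic = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  # strand roles by composition
  roles <- character(length(chains))
  comp <- vapply(chains, function(ch) {
    b <- residues$base[residues$strand == ch]
    if (all(b %in% c("A", "G"))) "purine" else "pyrimidine"
  }, "")
  pur_chains <- chains[comp == "purine"]
  if (length(chains) == 2L) {
    roles <- ifelse(comp == "purine", "purine", "pyrimidine")
  } else if (length(chains) >= 3L) {
    # chain order A/B/C: first two are the duplex
    roles <- c("purine", "pyrimidine", "third")[seq_along(chains)]
    if (comp[2L] == "purine" && comp[1L] != "purine")
      roles[1:2] <- c("pyrimidine", "purine")
  } else roles <- comp
  strands <- data.frame(
    strand = chains, role = roles,
    chem = vapply(chains, function(ch)
      residues$chem[residues$strand == ch][1L], ""),
    n = vapply(chains, function(ch)
      sum(residues$strand == ch), 0L), stringsAsFactors = FALSE)

  model0 <- triplex_model(atoms, residues, strands, spec = spec)
  # glycosidic state + usability
  for (i in seq_len(nrow(model0$residues))) {
    rr <- model0$residues[i, ]
    chi <- tryCatch(chi_torsion(model0, rr$strand, rr$res),
                    error = function(e) NA_real_)
    model0$residues$glycosidic[i] <-
      if (is.na(chi)) NA_character_
      else if (chi > -90 && chi <= 90) "syn" else "anti"
    if (!has_ring_atoms(model0, rr$strand, rr$res)) {
      warning("residue ", rr$strand, ":", rr$res, " (", rr$base,
              ") lacks ring atoms; flagged unusable", call. = FALSE)
      model0$residues$usable[i] <- FALSE
    } else model0$residues$usable[i] <- TRUE
  }

  nfr <- nrow(p$xyz)
  lapply(seq_len(nfr), function(f) {
    mm <- model0
    axyz(mm) <- matrix(p$xyz[f, ], ncol = 3L, byrow = TRUE)
    mm$frame_index <- f
    mm
  })
}

#' Glycosidic chi torsion of one residue
#'
#' O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines, in degrees.
#' Syn conformations fall in (-90, 90].
#'
#' @param model A [triplex_model()].
#' @param strand,res Residue address.
#' @return Torsion in degrees.
#' @export
chi_torsion <- function(model, strand, res) {
  rr <- residue_row(model, strand, res)
  if (!nrow(rr)) stop("no residue ", strand, ":", res)
  gn <- .glyco_n[[rr$base]]
  cr <- .chi_ref[[rr$base]]
  xyz <- res_xyz(model, strand, res)
  need <- c("O4'", "C1'", gn, cr)
  if (!all(need %in% rownames(xyz)))
    stop("residue ", strand, ":", res, " lacks atoms for chi (",
         paste(setdiff(need, rownames(xyz)), collapse = ","), ")")
  torsion4(xyz["O4'", ], xyz["C1'", ], xyz[gn, ], xyz[cr, ])
}
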