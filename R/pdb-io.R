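#' Read a C-alpha trajectory from a multi-model PDB file
#'
#' Reads every MODEL of a PDB file, keeps the C-alpha atoms (optionally of
#' one chain) in file order, and returns the coordinates in Angstrom.
#' Residue numbers of the selected beads are preserved as an attribute.
#'
#' @param path PDB file with one MODEL per frame.
#' @param chain optional chain identifier to select (e.g. `"A"`).
#' @param frame_dt time between models in ns (default 1).
#' @param temperature,replica optional metadata labels.
#' @return a [calpha_trajectory()].
#' @export
read_calpha_trajectory <- function(path, chain = NULL, frame_dt = 1,
                                   temperature = NA_character_,
                                   replica = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- if (is.null(chain)) bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
         else bio3d::atom.select(pdb, elety = "CA", chain = chain, verbose = FALSE)
  if (length(sel$atom) == 0) stop("no CA atoms in ", path, call. = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nf <- nrow(xyz); nb <- length(sel$atom)
  coords <- array(NA_real_, dim = c(nf, nb, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  traj <- calpha_trajectory(coords, temperature = temperature,
                            replica = replica, frame_dt = frame_dt)
  attr(traj, "resno") <- pdb$atom$resno[sel$atom]
  traj
}

#' Write a C-alpha trajectory as a multi-model PDB file
#'
#' One MODEL per frame, CA-only ATOM records, plus a JSON sidecar
#' (`<path>.json`) recording temperature, replica, frame time step and
#' the generating seed if known. PDB coordinates carry 3 decimal places,
#' so a write/read round trip is exact to 1e-3 Angstrom.
#'
#' @param traj a [calpha_trajectory()].
#' @param path output PDB path.
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_calpha_trajectory <- function(traj, path, seed = NULL) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  nb <- n_beads(traj); nf <- n_frames(traj)
  xyz <- t(vapply(seq_len(nf), function(f) as.numeric(t(traj$coords[f, , ])),
                  numeric(3 * nb)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(nb), resid = rep("ALA", nb),
                   eleno = seq_len(nb), elety = rep("CA", nb),
                   chain = rep("A", nb))
  jsonlite::write_json(list(temperature = traj$temperature,
                            replica = traj$replica,
                            frame_dt_ns = traj$frame_dt,
                            bond_length = traj$bond_length,
                            n_frames = nf, n_beads = nb, seed = seed),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

# read every *.pdb in a directory as one ensemble, using the sidecars for
# metadata when present
read_ensemble_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(paths) == 0) stop("no PDB files under ", dir, call. = FALSE)
  out <- list()
  for (p in paths) {
    meta <- list(temperature = NA_character_, replica = NA_integer_,
                 frame_dt_ns = 1)
    side <- paste0(p, ".json")
    if (file.exists(side))
      meta <- utils::modifyList(meta, jsonlite::read_json(side))
    tr <- read_calpha_trajectory(p, frame_dt = meta$frame_dt_ns,
                                 temperature = meta$temperature,
                                 replica = meta$replica)
    out[[sub("\\.pdb$", "", basename(p))]] <- tr
  }
  out
}
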