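# Readers and writers: plain tabular trajectory files, multi-model PDB
# (Cα extraction via bio3d), measure/profile TSV output with seed and
# config-hash headers, and a tiny FNV-1a hash for the headers.

# FNV-1a 32-bit over a character string; returned as 8 hex digits.
# Arithmetic kept inside double precision: xor touches only the low byte
# (the data byte is < 256) and the modular multiply is split 16/16.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s) %% 256
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configHash <- function(...) {
  .fnv1a(paste(deparse(list(...)), collapse = ""))
}

#' Read a trajectory from a plain tabular file
#'
#' Expected columns: frame, residue, x, y, z (whitespace-, tab- or
#' comma-separated; header optional). Frame 0, when present, is taken as
#' the frame0 reference structure and excluded from the observation
#' frames.
#'
#' @param path file path.
#' @param frameInterval ps between frames (default 50).
#' @return a [Trajectory-class].
#' @export
readTrajectoryTable <- function(path, frameInterval = 50) {
  dt <- as.data.frame(data.table::fread(path, header = "auto"))
  if (ncol(dt) != 5L)
    stop("expected 5 columns: frame, residue, x, y, z")
  names(dt) <- c("frame", "residue", "x", "y", "z")
  ids <- sort(unique(dt$residue))
  frames <- sort(unique(dt$frame))
  hasRef <- 0 %in% frames
  obsFrames <- frames[frames != 0]
  dt <- dt[order(dt$frame, dt$residue), , drop = FALSE]
  nr <- length(ids)
  obs <- dt[dt$frame != 0, , drop = FALSE]
  if (nrow(obs) != length(obsFrames) * nr)
    stop("incomplete trajectory table: every residue must appear in ",
         "every frame")
  x <- array(0, dim = c(length(obsFrames), nr, 3L))
  m <- as.matrix(obs[, c("x", "y", "z")])
  for (ax in 1:3)
    x[, , ax] <- matrix(m[, ax], nrow = length(obsFrames), byrow = TRUE)
  f0 <- if (hasRef) {
    ref <- dt[dt$frame == 0, , drop = FALSE]
    unname(as.matrix(ref[order(ref$residue), c("x", "y", "z")]))
  } else NULL
  trajectory(x, frame0 = f0, ids = ids, frameInterval = frameInterval)
}

#' Write a trajectory to a plain tabular file
#'
#' Inverse of [readTrajectoryTable()]: frame0 is written as frame 0,
#' observation frames as 1..n.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path (TSV).
#' @return invisibly, the path.
#' @export
writeTrajectoryTable <- function(traj, path) {
  x <- coords(traj)
  nf <- dim(x)[1L]; nr <- dim(x)[2L]
  ids <- residueIds(traj)
  frame <- rep(0:nf, each = nr)
  residue <- rep(ids, nf + 1L)
  xyz <- rbind(frame0(traj),
               matrix(aperm(x, c(2L, 1L, 3L)), ncol = 3L))
  dt <- data.table::data.table(frame = frame, residue = residue,
                               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read Cα coordinates from a multi-model PDB file
#'
#' Extracts the Cα atoms of every MODEL in the file; the first model is
#' used as frame0 unless `firstModelIsReference = FALSE`.
#'
#' @param path PDB file path.
#' @param frameInterval ps between frames (default 50).
#' @param firstModelIsReference treat model 1 as the frame0 reference and
#'   exclude it from the observations (default FALSE: all models are
#'   frames, frame0 is a copy of the first).
#' @return a [Trajectory-class].
#' @export
readTrajectoryPDB <- function(path, frameInterval = 50,
                              firstModelIsReference = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nModels <- nrow(xyz)
  nr <- length(sel$atom)
  ids <- pdb$atom$resno[sel$atom]
  x <- array(0, dim = c(nModels, nr, 3L))
  for (m in seq_len(nModels))
    x[m, , ] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
  if (firstModelIsReference && nModels > 2L) {
    f0 <- x[1L, , ]
    x <- x[-1L, , , drop = FALSE]
    trajectory(x, frame0 = f0, ids = ids, frameInterval = frameInterval)
  } else {
    trajectory(x, ids = ids, frameInterval = frameInterval)
  }
}

# Standard header lines for text outputs.
.outputHeader <- function(seed, ...) {
  c(sprintf("# trajcompare v%s",
            as.character(utils::packageVersion("trajcompare"))),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config: %s", .configHash(...)),
    "# note: pv_ks0 conversion uses block-size n as a descriptive,",
    "#       non-calibrated device")
}

#' Write measure panels and profiles of a comparison result as TSV
#'
#' Two files are produced in `dir`: `<group>_panels.tsv` (one row per
#' residue or residue pair per block pairing) and `<group>_profiles.tsv`
#' (block-averaged per-residue profiles with pv and log10(pv)). Each file
#' carries the master seed and a config hash in comment headers.
#'
#' @param result a [ComparisonResult-class].
#' @param dir output directory (created if absent).
#' @return character vector of the two file paths, invisibly.
#' @export
writeResultTSV <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- .outputHeader(result@seed, result@group@name, result@cutoff)
  paths <- file.path(dir, paste0(result@group@name,
                                 c("_panels.tsv", "_profiles.tsv")))
  for (i in 1:2) {
    df <- if (i == 1L) result@panels else result@profiles
    con <- file(paths[i], "w")
    writeLines(hdr, con)
    utils::write.table(format(df, digits = 10, trim = TRUE,
                              scientific = NA),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(paths)
}
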