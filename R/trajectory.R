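# Slab-trajectory container and plain-text trajectory I/O (LAMMPS-dump and
# XYZ dialects). No established R package reads LAMMPS dump files, so the
# parsers live here; both dialects carry the molecule-id column the contact
# and valency analyses require.

#' Construct a slab trajectory
#'
#' A direct-coexistence ("slab") trajectory: frames of bead coordinates in an
#' orthogonal periodic box elongated along z, at a single temperature. All
#' frames share the same beads (molecule ids and masses).
#'
#' @param frames List of n_beads x 3 numeric matrices (Angstrom).
#' @param mol Integer vector, molecule id per bead.
#' @param mass Numeric vector, mass per bead (Da).
#' @param box Numeric length-3, box edge lengths (Angstrom); z is the
#'   elongated axis.
#' @param temperature Temperature (K).
#' @return A `slab_trajectory`.
#' @export
slab_trajectory <- function(frames, mol, mass, box, temperature) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(frames[[1L]])
  for (f in frames) {
    stopifnot(is.matrix(f), ncol(f) == 3L, nrow(f) == n)
  }
  stopifnot(length(mol) == n, length(mass) == n, length(box) == 3L,
            all(box > 0), is.numeric(temperature), length(temperature) == 1L)
  if (box[3L] < box[1L] || box[3L] < box[2L]) {
    stop("slab box must be elongated along z (box z >= box x, box y)")
  }
  structure(
    list(frames = frames, mol = as.integer(mol), mass = as.numeric(mass),
         box = as.numeric(box), temperature = temperature),
    class = "slab_trajectory"
  )
}

#' @export
print.slab_trajectory <- function(x, ...) {
  cat("slab_trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1L]]), "beads,", length(unique(x$mol)), "molecules\n")
  cat(sprintf("  box %.1f x %.1f x %.1f A, T = %g K\n",
              x$box[1L], x$box[2L], x$box[3L], x$temperature))
  invisible(x)
}

#' Write a trajectory to disk
#'
#' `"lammpsdump"` writes standard dump blocks with
#' `ITEM: ATOMS id mol type x y z` and orthogonal `pp pp pp` box bounds.
#' `"xyz"` writes an XYZ-style dialect whose comment line carries
#' `box=<x>,<y>,<z> temperature=<K>` and whose atom lines are
#' `<mol> <x> <y> <z>` (the element column holds the molecule id).
#'
#' @param traj A `slab_trajectory`.
#' @param path Output file.
#' @param format `"lammpsdump"` or `"xyz"`.
#' @export
write_trajectory <- function(traj, path, format = c("lammpsdump", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "slab_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$frames[[1L]])
  for (i in seq_along(traj$frames)) {
    xyz <- traj$frames[[i]]
    if (format == "lammpsdump") {
      writeLines(c(
        "ITEM: TIMESTEP", as.character(i - 1L),
        "ITEM: NUMBER OF ATOMS", as.character(n),
        "ITEM: BOX BOUNDS pp pp pp",
        sprintf("0 %.10g", traj$box[1L]),
        sprintf("0 %.10g", traj$box[2L]),
        sprintf("0 %.10g", traj$box[3L]),
        "ITEM: ATOMS id mol type x y z"
      ), con)
      writeLines(sprintf("%d %d 1 %.10g %.10g %.10g",
                         seq_len(n), traj$mol,
                         xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    } else {
      writeLines(c(
        as.character(n),
        sprintf("box=%.10g,%.10g,%.10g temperature=%.10g",
                traj$box[1L], traj$box[2L], traj$box[3L], traj$temperature)
      ), con)
      writeLines(sprintf("%d %.10g %.10g %.10g",
                         traj$mol, xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Accepts the LAMMPS-dump and XYZ dialects written by [write_trajectory()].
#' The format is inferred from the first line unless given.
#'
#' @param path Trajectory file.
#' @param format `"auto"`, `"lammpsdump"` or `"xyz"`.
#' @param mass Per-bead masses (Da); defaults to 110 Da per bead if absent.
#' @param temperature Temperature (K); required for LAMMPS dumps (the dump
#'   carries none), read from the comment line for XYZ when present.
#' @param box Box lengths, only needed if the file lacks them.
#' @return A `slab_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "lammpsdump", "xyz"),
                            mass = NULL, temperature = NULL, box = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  if (format == "auto") {
    format <- if (grepl("^ITEM:", lines[1L])) "lammpsdump" else "xyz"
  }
  if (format == "lammpsdump") {
    parsed <- .read_lammpsdump(lines)
    if (is.null(temperature)) {
      stop("temperature must be supplied when reading LAMMPS dump files")
    }
  } else {
    parsed <- .read_xyz(lines)
    if (is.null(temperature)) temperature <- parsed$temperature
    if (is.null(temperature)) {
      stop("temperature not found in file; supply `temperature`")
    }
  }
  if (is.null(box)) box <- parsed$box
  if (is.null(box)) stop("box lengths not found in file; supply `box`")
  n <- nrow(parsed$frames[[1L]])
  if (is.null(mass)) mass <- rep(110, n)
  slab_trajectory(parsed$frames, parsed$mol, mass, box, temperature)
}

.read_lammpsdump <- function(lines) {
  frames <- list()
  mol <- NULL
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i])) stop("malformed dump at line ", i)
    n <- as.integer(lines[i + 3L])
    bx <- vapply(lines[(i + 5L):(i + 7L)], function(l) {
      v <- as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
      v[2L] - v[1L]
    }, numeric(1L))
    header <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i + 8L]), "\\s+")[[1L]]
    body <- lines[(i + 9L):(i + 8L + n)]
    dat <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                  nrow = n, byrow = TRUE)
    colnames(dat) <- header
    if (!all(c("id", "mol", "x", "y", "z") %in% header)) {
      stop("dump file must provide id, mol, x, y, z columns")
    }
    ord <- order(dat[, "id"])
    dat <- dat[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <- unname(dat[, c("x", "y", "z")])
    if (is.null(mol)) mol <- as.integer(dat[, "mol"])
    box <- unname(bx)
    i <- i + 9L + n
  }
  list(frames = frames, mol = mol, box = box, temperature = NULL)
}

.read_xyz <- function(lines) {
  frames <- list()
  mol <- NULL
  box <- NULL
  temperature <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1L]
    bm <- regmatches(comment,
                     regexec("box=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                             comment))[[1L]]
    if (length(bm) == 4L) box <- as.numeric(bm[2:4])
    tm <- regmatches(comment,
                     regexec("temperature=([0-9.eE+-]+)", comment))[[1L]]
    if (length(tm) == 2L) temperature <- as.numeric(tm[2L])
    body <- lines[(i + 2L):(i + 1L + n)]
    dat <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                  nrow = n, byrow = TRUE)
    if (ncol(dat) != 4L) stop("xyz dialect requires: mol x y z")
    frames[[length(frames) + 1L]] <- dat[, 2:4, drop = FALSE]
    if (is.null(mol)) mol <- as.integer(dat[, 1L])
    i <- i + 2L + n
  }
  list(frames = frames, mol = mol, box = box, temperature = temperature)
}
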