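#' Particle trajectory in a periodic box
#'
#' @param coords Numeric array (n_frames x n_particles x 3), coordinates in nm.
#' @param box Box edge lengths in nm (length 3, or one value recycled).
#' @param species Optional per-particle type labels (constant across frames).
#' @return Object of class \code{trajectory}.
#' @export
trajectory <- function(coords, box, species = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  box <- rep(as.numeric(box), length.out = 3)
  if (any(box <= 0)) stop("box lengths must be positive")
  n <- dim(coords)[2]
  if (is.null(species)) species <- rep("AR", n)
  if (length(species) != n) stop("one species label per particle")
  structure(list(coords = coords, box = box, species = species),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d particles, box (%.3f %.3f %.3f) nm\n",
              n_frames(x), n_particles(x), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A \code{trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an N x 3 coordinate matrix
#'
#' @param traj A \code{trajectory}.
#' @param i Frame index.
#' @return Numeric matrix (particles x 3) in nm.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Write a trajectory in XYZ format
#'
#' Plain multi-frame XYZ: particle count, comment line, then one
#' \code{element x y z} line per particle.  Units are selectable because XYZ
#' is conventionally in Angstrom while this package works in nm.
#'
#' @param traj A \code{trajectory}.
#' @param path Output file.
#' @param units \code{"angstrom"} (default, coordinates multiplied by 10) or
#'   \code{"nm"}.
#' @export
write_xyz <- function(traj, path, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  fac <- if (units == "angstrom") 10 else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    pos <- get_frame(traj, f) * fac
    writeLines(c(as.character(n_particles(traj)),
                 sprintf("frame %d; box %.6f %.6f %.6f %s", f,
                         traj$box[1] * fac, traj$box[2] * fac,
                         traj$box[3] * fac, units)), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", traj$species,
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file.
#' @param box Box edge lengths (in the same units as the file); required
#'   because XYZ carries no box record (the comment line written by
#'   \code{\link{write_xyz}} is parsed if \code{box} is NULL).
#' @param units Units of the file coordinates; converted to nm.
#' @return A \code{trajectory} (nm).
#' @export
read_xyz <- function(path, box = NULL, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  fac <- if (units == "angstrom") 0.1 else 1
  lines <- readLines(path)
  frames <- list()
  species <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    species <- vapply(parts, `[[`, "", 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- pos * fac
    if (is.null(box)) {
      m <- regmatches(comment,
                      regexec("box ([0-9.eE+-]+) ([0-9.eE+-]+) ([0-9.eE+-]+)",
                              comment))[[1]]
      if (length(m) == 4) box <- as.numeric(m[2:4])  # file units
    }
    i <- i + 2 + n
  }
  if (is.null(box)) stop("box not given and not found in comment lines")
  coords <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, box * fac, species)
}

#' Write a trajectory in GRO format
#'
#' Gromos87 fixed-width coordinate format: positions in nm, box vector on the
#' last line of each frame.  Frames are concatenated.
#'
#' @param traj A \code{trajectory}.
#' @param path Output file.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_particles(traj)
  for (f in seq_len(n_frames(traj))) {
    pos <- get_frame(traj, f)
    writeLines(c(sprintf("solvdecomp frame %d", f), sprintf("%5d", n)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(n) %% 100000, traj$species,
                       substr(traj$species, 1, 5), seq_len(n) %% 100000,
                       pos[, 1], pos[, 2], pos[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[1], traj$box[2],
                       traj$box[3]), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO trajectory
#'
#' @param path GRO file (nm positions, box on the last line of each frame).
#' @return A \code{trajectory}.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  species <- NULL
  box <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i + 1]))
    body <- lines[(i + 2):(i + 1 + n)]
    species <- trimws(substr(body, 6, 10))
    pos <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44)))
    frames[[length(frames) + 1]] <- pos
    box <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])[1:3]
    i <- i + 3 + n
  }
  coords <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, box, species)
}
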