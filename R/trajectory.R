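#' Trajectory of same-topology P1 frames
#'
#' Ordered frames sharing atom count and ordering. Coordinates are stored
#' fractionally together with per-frame cell parameters, so frames can be
#' wrapped/unwrapped and converted exactly.
#'
#' @param labels Character vector of site labels (shared by all frames).
#' @param elements Character vector of element symbols.
#' @param frac 3-dimensional array `[frame, atom, xyz]` of fractional
#'   coordinates.
#' @param cells Matrix with one row per frame, columns
#'   `a, b, c, alpha, beta, gamma`.
#' @param timestep_ps Time between stored frames in picoseconds.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(labels, elements, frac, cells, timestep_ps = NA_real_) {
  frac <- as.array(frac)
  if (length(dim(frac)) != 3 || dim(frac)[3] != 3) {
    stop("frac must be an [frame, atom, 3] array")
  }
  cells <- matrix(as.numeric(cells), ncol = 6,
                  dimnames = list(NULL, c("a", "b", "c", "alpha", "beta", "gamma")))
  if (nrow(cells) != dim(frac)[1]) stop("one cell row per frame required")
  if (dim(frac)[2] != length(labels) || length(labels) != length(elements)) {
    stop("labels/elements must match the atom dimension")
  }
  structure(list(labels = as.character(labels), elements = as.character(elements),
                 frac = frac, cells = cells, timestep_ps = timestep_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s) x %d atoms", n_frames(x), length(x$labels)))
  if (!is.na(x$timestep_ps)) cat(sprintf(", dt = %g ps", x$timestep_ps))
  cat("\n")
  invisible(x)
}

#' @rdname trajectory
#' @param x A trajectory.
#' @export
n_frames <- function(x) dim(x$frac)[1]

#' Extract one frame as a crystal
#'
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @param name Name for the resulting structure.
#' @return A P1 [crystal()].
#' @export
traj_frame <- function(traj, i, name = sprintf("frame_%d", i)) {
  stopifnot(i >= 1, i <= n_frames(traj))
  sites <- data.frame(label = traj$labels, element = traj$elements,
                      fx = traj$frac[i, , 1], fy = traj$frac[i, , 2],
                      fz = traj$frac[i, , 3], stringsAsFactors = FALSE)
  crystal(traj$cells[i, ], sites, name = name)
}

# Assemble a trajectory from a list of same-ordering P1 crystals.
frames_to_trajectory <- function(frames, timestep_ps = NA_real_) {
  stopifnot(length(frames) >= 1)
  labs <- frames[[1]]$sites$label
  for (f in frames) {
    if (!identical(f$sites$label, labs)) stop("frames disagree in atom labels/order")
  }
  n <- length(frames)
  frac <- array(NA_real_, c(n, length(labs), 3))
  cells <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    frac[i, , ] <- crystal_frac(frames[[i]])
    cells[i, ] <- as.numeric(frames[[i]]$cell)
  }
  trajectory(labs, frames[[1]]$sites$element, frac, cells, timestep_ps)
}

cell_from_lattice_vectors <- function(m) {
  lens <- sqrt(rowSums(m^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  unit_cell(lens[1], lens[2], lens[3],
            ang(m[2, ], m[3, ]), ang(m[1, ], m[3, ]), ang(m[1, ], m[2, ]))
}

#' Read an extended-XYZ trajectory
#'
#' Expects the common dialect: per frame an atom count line, a comment line
#' carrying `Lattice="ax ay az bx by bz cx cy cz"` (row-major lattice
#' vectors, Angstrom), then one `element x y z` line per atom in fixed
#' order. Cartesian positions are converted to fractional against the
#' frame's own lattice.
#'
#' @param path File path.
#' @param timestep_ps Frame spacing metadata to attach.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, timestep_ps = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  labels <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed extended-XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
    if (length(lat) == 0) stop("frame at line ", i, " lacks a Lattice field")
    nums <- as.numeric(strsplit(trimws(gsub('Lattice="|"', "", lat)), "[[:space:]]+")[[1]])
    if (length(nums) != 9) stop("Lattice field must hold 9 numbers")
    lm <- matrix(nums, 3, 3, byrow = TRUE)
    rows <- lines[seq(i + 2L, i + 1L + nat)]
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    el <- vapply(toks, `[[`, "", 1)
    cart <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    cell <- cell_from_lattice_vectors(lm)
    # re-express against the package's lower-triangular convention: only
    # fractional coordinates are stored, so orientation drops out
    frac <- cart %*% solve(lm)
    k <- length(frames) + 1L
    # a 5th column, if present, carries site labels (written by
    # write_xyz_trajectory as a label:S:1 property)
    lab <- if (all(lengths(toks) >= 5)) vapply(toks, `[[`, "", 5)
           else paste0(el, seq_along(el))
    sites <- data.frame(label = lab, element = el, fx = frac[, 1],
                        fy = frac[, 2], fz = frac[, 3], stringsAsFactors = FALSE)
    frames[[k]] <- crystal(cell, sites, name = sprintf("frame_%d", k))
    i <- i + 2L + nat
  }
  frames_to_trajectory(frames, timestep_ps)
}

#' Write a trajectory as extended XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return The lines written, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path = NULL) {
  lines <- character()
  for (i in seq_len(n_frames(traj))) {
    m <- cell_matrix(traj$cells[i, ])
    cart <- traj$frac[i, , , drop = TRUE] %*% m
    if (is.null(dim(cart))) cart <- matrix(cart, ncol = 3)
    lines <- c(lines,
      as.character(length(traj$labels)),
      sprintf('Lattice="%s" Properties=species:S:1:pos:R:3:label:S:1 Frame=%d',
              paste(sprintf("%.8f", t(m)), collapse = " "), i - 1L),
      sprintf("%-3s %16.8f %16.8f %16.8f %s", traj$elements, cart[, 1],
              cart[, 2], cart[, 3], traj$labels)
    )
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
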