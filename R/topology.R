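# Covalent radii (Angstrom), Cordero-style consensus values for the
# elements that occur in small-molecule organic crystals. Embedded so bond
# perception is deterministic and dependency-free.
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39,
  Fe = 1.32, Zn = 1.22, Cu = 1.32, Mn = 1.39
)

#' Covalent radius lookup
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (any(is.na(r))) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Perceive bonds, molecules and methyl groups
#'
#' Two sites are bonded iff their minimum-image distance does not exceed
#' the sum of covalent radii plus `tolerance`. Molecules are the connected
#' components of the bond graph. A methyl group is a carbon bonded to
#' exactly three hydrogens and exactly one heavy atom.
#'
#' @param x A P1 [crystal()].
#' @param tolerance Distance slack in Angstrom added to the radius sum.
#' @return An object of class `"topology"`: list with `bonds` (two-column
#'   character matrix of site labels), `molecules` (list of character
#'   vectors partitioning the site labels) and `methyl_groups` (list of
#'   `list(carbon =, hydrogens =)`).
#' @export
perceive_bonds <- function(x, tolerance = 0.40) {
  stopifnot(inherits(x, "crystal"))
  if (!is_p1(x)) stop("perceive_bonds expects a P1 crystal; call to_p1() first")
  n <- nrow(x$sites)
  lab <- x$sites$label
  radii <- covalent_radius(x$sites$element)
  d <- min_image_dist(crystal_frac(x), crystal_frac(x), x$cell)
  thresh <- outer(radii, radii, "+") + tolerance
  adj <- d <= thresh
  diag(adj) <- FALSE
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  bonds <- cbind(lab[pairs[, 1]], lab[pairs[, 2]])
  colnames(bonds) <- c("i", "j")

  # connected components by label propagation
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  molecules <- unname(split(lab, comp))
  molecules <- molecules[order(vapply(molecules, function(m) min(match(m, lab)), 1L))]

  methyls <- list()
  is_h <- x$sites$element == "H"
  for (ci in which(x$sites$element == "C")) {
    nb <- which(adj[ci, ])
    hs <- nb[is_h[nb]]
    heavy <- nb[!is_h[nb]]
    if (length(hs) == 3 && length(heavy) == 1) {
      methyls[[length(methyls) + 1L]] <- list(carbon = lab[ci],
                                              hydrogens = lab[hs],
                                              heavy_neighbour = lab[heavy])
    }
  }
  structure(list(bonds = bonds, molecules = molecules, methyl_groups = methyls),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d bonds, %d molecule(s), %d methyl group(s)\n",
              nrow(x$bonds), length(x$molecules), length(x$methyl_groups)))
  invisible(x)
}

# labels of bonded neighbours of a given label
bonded_neighbours <- function(topo, label) {
  unique(c(topo$bonds[topo$bonds[, 1] == label, 2],
           topo$bonds[topo$bonds[, 2] == label, 1]))
}
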