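#' Unit cell
#'
#' Construct a validated unit cell from lengths (Angstrom) and angles
#' (degrees).
#'
#' @param a,b,c Cell edge lengths in Angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each strictly between 0
#'   and 180.
#' @return A named numeric vector of class `"unit_cell"` with elements
#'   `a, b, c, alpha, beta, gamma`.
#' @examples
#' unit_cell(10, 10, 10)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  storage.mode(cell) <- "double"
  if (any(!is.finite(cell))) stop("cell parameters must be finite numbers")
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  class(cell) <- "unit_cell"
  if (cell_volume(cell) <= 0) stop("cell parameters give non-positive volume")
  cell
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6) stop("a cell needs 6 parameters (a, b, c, alpha, beta, gamma)")
  unit_cell(x[1], x[2], x[3], x[4], x[5], x[6])
}

#' Cell matrix (lattice vectors as rows)
#'
#' Lower-triangular convention: the a vector lies along Cartesian x and the
#' b vector in the xy plane, so `cart = frac %*% cell_matrix(cell)`.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 numeric matrix whose rows are the lattice vectors in
#'   Angstrom.
#' @export
cell_matrix <- function(cell) {
  cell <- as_unit_cell(cell)
  d2r <- pi / 180
  ca <- cos(cell[["alpha"]] * d2r)
  cb <- cos(cell[["beta"]] * d2r)
  cg <- cos(cell[["gamma"]] * d2r)
  sg <- sin(cell[["gamma"]] * d2r)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  cx <- cc * cb
  cy <- cc * (ca - cb * cg) / sg
  cz2 <- cc^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell: lattice vectors are coplanar")
  rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(cx, cy, sqrt(cz2))
  )
}

#' @rdname cell_matrix
#' @export
cell_volume <- function(cell) {
  cell <- as_unit_cell(cell)
  d2r <- pi / 180
  ca <- cos(cell[["alpha"]] * d2r)
  cb <- cos(cell[["beta"]] * d2r)
  cg <- cos(cell[["gamma"]] * d2r)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  prod(cell[1:3]) * sqrt(arg)
}

#' Perpendicular widths of a cell
#'
#' Distance between opposite faces along each axis: volume divided by the
#' area of the face spanned by the other two lattice vectors. This is the
#' quantity that must exceed twice the interaction cut-off when building
#' simulation supercells, and differs from the edge length for oblique
#' cells.
#'
#' @param cell A [unit_cell()].
#' @return Numeric vector of the three perpendicular widths in Angstrom.
#' @export
cell_perp_widths <- function(cell) {
  m <- cell_matrix(cell)
  v <- abs(det(m))
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  areas <- c(
    sqrt(sum(cross(m[2, ], m[3, ])^2)),
    sqrt(sum(cross(m[3, ], m[1, ])^2)),
    sqrt(sum(cross(m[1, ], m[2, ])^2))
  )
  v / areas
}

#' Fractional/Cartesian conversion
#'
#' @param frac,cart Nx3 matrices (or length-3 vectors) of coordinates.
#' @param cell A [unit_cell()].
#' @return Nx3 matrix of converted coordinates.
#' @export
frac_to_cart <- function(frac, cell) {
  frac <- to_coord_matrix(frac)
  frac %*% cell_matrix(cell)
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cart, cell) {
  cart <- to_coord_matrix(cart)
  cart %*% solve(cell_matrix(cell))
}

to_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Wrap fractional coordinates into [0, 1)
#'
#' @param frac Nx3 matrix of fractional coordinates (may be unwrapped).
#' @return Matrix with every entry mapped to the canonical [0,1) image.
#' @export
wrap_frac <- function(frac) {
  frac <- to_coord_matrix(frac)
  frac - floor(frac)
}

# All minimum-image Cartesian distances between two fractional coordinate
# sets (rows). Searches the 27 neighbouring images, which is exact for the
# compact, not-too-oblique cells this package handles.
min_image_dist <- function(frac_a, frac_b, cell) {
  frac_a <- to_coord_matrix(frac_a)
  frac_b <- to_coord_matrix(frac_b)
  m <- cell_matrix(cell)
  na <- nrow(frac_a); nb <- nrow(frac_b)
  shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
  d2 <- matrix(Inf, na, nb)
  # wrap the raw difference first so shifts of -1..1 suffice
  for (i in seq_len(na)) {
    df <- sweep(frac_b, 2, frac_a[i, ])
    df <- df - round(df)
    best <- rep(Inf, nb)
    for (k in seq_len(nrow(shifts))) {
      dc <- sweep(df, 2, shifts[k, ], "+") %*% m
      best <- pmin(best, rowSums(dc^2))
    }
    d2[i, ] <- best
  }
  sqrt(d2)
}
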