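#' Crystal structure
#'
#' The structural currency of the package: a unit cell plus labelled atomic
#' sites in fractional coordinates, with textual symmetry operators
#' (identity only once expanded to P1).
#'
#' @param cell A [unit_cell()] or length-6 numeric vector.
#' @param sites data.frame with columns `label` (unique character),
#'   `element` (chemical symbol), `fx`, `fy`, `fz` (fractional coordinates,
#'   may be unwrapped) and optionally `occ` (occupancy in (0, 1], default 1).
#' @param symmetry Character vector of `x,y,z`-style operators; defaults to
#'   identity (P1).
#' @param z_value Molecules per unit cell (Z), or `NA` if unknown.
#' @param z_prime Molecules per asymmetric unit (Z'), or `NA`.
#' @param name Structure identifier.
#' @return An object of class `"crystal"`.
#' @export
crystal <- function(cell, sites, symmetry = "x,y,z", z_value = NA_integer_,
                    z_prime = NA_real_, name = "crystal") {
  cell <- as_unit_cell(cell)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("label", "element", "fx", "fy", "fz")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(sites$occ)) sites$occ <- 1
  sites$label <- as.character(sites$label)
  sites$element <- as.character(sites$element)
  for (col in c("fx", "fy", "fz", "occ")) sites[[col]] <- as.numeric(sites[[col]])
  if (anyDuplicated(sites$label)) {
    stop("duplicate site labels: ",
         paste(unique(sites$label[duplicated(sites$label)]), collapse = ", "))
  }
  if (any(sites$occ <= 0 | sites$occ > 1)) stop("occupancies must lie in (0, 1]")
  rownames(sites) <- NULL
  structure(
    list(cell = cell, sites = sites, symmetry = as.character(symmetry),
         z_value = z_value, z_prime = z_prime, name = as.character(name)),
    class = "crystal"
  )
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("<crystal> %s: %d sites, %d symmetry op(s)\n", x$name,
              nrow(x$sites), length(x$symmetry)))
  cat(sprintf("  cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              x$cell[["a"]], x$cell[["b"]], x$cell[["c"]],
              x$cell[["alpha"]], x$cell[["beta"]], x$cell[["gamma"]]))
  if (!is.na(x$z_value)) cat(sprintf("  Z = %d\n", x$z_value))
  invisible(x)
}

is_p1 <- function(x) {
  length(x$symmetry) == 1 && identical(parse_symop(x$symmetry[[1]]),
                                       list(rot = diag(3), trans = c(0, 0, 0)))
}

crystal_frac <- function(x) {
  m <- as.matrix(x$sites[, c("fx", "fy", "fz")])
  dimnames(m) <- list(x$sites$label, NULL)
  m
}

crystal_cart <- function(x) {
  frac_to_cart(crystal_frac(x), x$cell)
}

set_frac <- function(x, frac) {
  frac <- to_coord_matrix(frac)
  stopifnot(nrow(frac) == nrow(x$sites))
  x$sites$fx <- frac[, 1]
  x$sites$fy <- frac[, 2]
  x$sites$fz <- frac[, 3]
  x
}

#' Canonicalize fractional coordinates
#'
#' Maps all site coordinates to the [0, 1) cell image. Stored coordinates
#' are otherwise allowed to be unwrapped (e.g. averaged trajectories).
#'
#' @param x A [crystal()].
#' @return The crystal with wrapped coordinates.
#' @export
canonicalize <- function(x) {
  set_frac(x, wrap_frac(crystal_frac(x)))
}

# Parse an "x, y, z"-style symmetry operator into rotation + translation
# acting on fractional coordinate columns: frac' = frac %*% t(rot) + trans.
parse_symop <- function(op) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(op)), ",")[[1]]
  if (length(parts) != 3) stop("cannot parse symmetry operator: '", op, "'")
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    if (length(toks) == 0) stop("cannot parse symmetry operator: '", op, "'")
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (grepl("^[0-9]+/[0-9]+$", body)) {
        nums <- as.numeric(strsplit(body, "/")[[1]])
        trans[i] <- trans[i] + sign * nums[1] / nums[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else if (grepl("^([0-9.]+|[0-9]+/[0-9]+)?\\*?[xyz]$", body)) {
        coef <- 1
        var <- substr(body, nchar(body), nchar(body))
        pre <- sub("\\*?[xyz]$", "", body)
        if (nzchar(pre)) {
          coef <- if (grepl("/", pre)) {
            nums <- as.numeric(strsplit(pre, "/")[[1]]); nums[1] / nums[2]
          } else as.numeric(pre)
        }
        rot[i, axes[[var]]] <- rot[i, axes[[var]]] + sign * coef
      } else {
        stop("cannot parse symmetry operator term '", tok, "' in '", op, "'")
      }
    }
  }
  list(rot = rot, trans = trans)
}

#' Expand a crystal to P1
#'
#' Applies every symmetry operator to every site, wraps the images into
#' [0, 1), and merges duplicates (same element within `merge_tol` Angstrom
#' by minimum-image distance, e.g. sites on special positions). Output site
#' order is operator-major: all images under the first operator first, in
#' input site order. Labels of images beyond the first operator gain a
#' `_k` suffix (k = operator index) to stay unique.
#'
#' @param x A [crystal()].
#' @param merge_tol Duplicate-image merge threshold in Angstrom.
#' @return A P1 [crystal()] with identity-only symmetry.
#' @export
to_p1 <- function(x, merge_tol = 0.01) {
  stopifnot(inherits(x, "crystal"))
  ops <- lapply(x$symmetry, parse_symop)
  frac <- crystal_frac(x)
  out <- list()
  for (k in seq_along(ops)) {
    img <- wrap_frac(frac %*% t(ops[[k]]$rot) + matrix(ops[[k]]$trans, nrow(frac), 3, byrow = TRUE))
    s <- x$sites
    s$fx <- img[, 1]; s$fy <- img[, 2]; s$fz <- img[, 3]
    if (k > 1) s$label <- paste0(s$label, "_", k)
    s$.base <- x$sites$label
    out[[k]] <- s
  }
  all_sites <- do.call(rbind, out)
  keep <- rep(TRUE, nrow(all_sites))
  frac_all <- as.matrix(all_sites[, c("fx", "fy", "fz")])
  if (nrow(all_sites) > 1) {
    d <- min_image_dist(frac_all, frac_all, x$cell)
    for (i in seq_len(nrow(all_sites))) {
      if (!keep[i]) next
      dup <- which(keep & seq_len(nrow(all_sites)) > i &
                     all_sites$element == all_sites$element[i] & d[i, ] < merge_tol)
      keep[dup] <- FALSE
    }
  }
  sites <- all_sites[keep, setdiff(names(all_sites), ".base")]
  crystal(x$cell, sites, symmetry = "x,y,z", z_value = x$z_value,
          z_prime = x$z_prime, name = x$name)
}

#' Build a supercell meeting a minimum perpendicular span
#'
#' Replicates a P1 crystal by the smallest integer triple `(na, nb, nc)`
#' such that every perpendicular width of the supercell (volume over
#' opposite-face area, the side-to-side distance) is at least `min_span`.
#' Simulation protocols commonly require this span to be twice the
#' non-bonded cut-off distance. An explicit replication can be supplied
#' instead to reproduce a fixed system size.
#'
#' @param x A P1 [crystal()].
#' @param min_span Required minimum perpendicular width in Angstrom.
#' @param replication Optional explicit integer triple overriding the
#'   minimal-satisfying computation.
#' @return List with `crystal` (the supercell, P1) and `replication`.
#' @export
build_supercell <- function(x, min_span = NULL, replication = NULL) {
  stopifnot(inherits(x, "crystal"))
  if (!is_p1(x)) stop("build_supercell expects a P1 crystal; call to_p1() first")
  if (cell_volume(x$cell) <= 0) stop("degenerate cell with zero volume")
  if (is.null(replication)) {
    if (is.null(min_span) || min_span <= 0) stop("min_span must be positive")
    widths <- cell_perp_widths(x$cell)
    replication <- as.integer(ceiling(min_span / widths - 1e-9))
    replication <- pmax(replication, 1L)
  } else {
    replication <- as.integer(replication)
    if (length(replication) != 3 || any(replication < 1)) {
      stop("replication must be 3 positive integers")
    }
  }
  na <- replication[1]; nb <- replication[2]; nc <- replication[3]
  cell <- unit_cell(x$cell[["a"]] * na, x$cell[["b"]] * nb, x$cell[["c"]] * nc,
                    x$cell[["alpha"]], x$cell[["beta"]], x$cell[["gamma"]])
  frac <- crystal_frac(x)
  blocks <- list()
  idx <- 1L
  for (ia in seq_len(na) - 1L) for (ib in seq_len(nb) - 1L) for (ic in seq_len(nc) - 1L) {
    s <- x$sites
    img <- sweep(frac, 2, c(ia, ib, ic), "+")
    img <- sweep(img, 2, c(na, nb, nc), "/")
    s$fx <- img[, 1]; s$fy <- img[, 2]; s$fz <- img[, 3]
    if (idx > 1L) s$label <- paste0(s$label, "+", ia, ib, ic)
    blocks[[idx]] <- s
    idx <- idx + 1L
  }
  z <- if (is.na(x$z_value)) NA_integer_ else x$z_value * na * nb * nc
  list(
    crystal = crystal(cell, do.call(rbind, blocks), z_value = z,
                      z_prime = x$z_prime, name = x$name),
    replication = replication
  )
}
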