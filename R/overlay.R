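#' Optimal rigid superposition of matched coordinate sets
#'
#' Finds the proper rotation and translation mapping `coords_b` onto
#' `coords_a` that minimize the root-mean-square displacement, via centroid
#' alignment and the closed-form SVD solution with a reflection guard (the
#' rotation determinant is forced to +1).
#'
#' @param coords_a,coords_b Nx3 Cartesian coordinate matrices, rows matched
#'   one-to-one.
#' @return An object of class `"overlay_result"`: list with `rmscd`
#'   (Angstrom), `rotation` (3x3, applied on the right to centred
#'   `coords_b`), `translation` and `n_atoms`. The transform maps b onto a:
#'   `sweep(coords_b %*% rotation, 2, translation, "+")`.
#' @export
superpose <- function(coords_a, coords_b) {
  a <- to_coord_matrix(coords_a)
  b <- to_coord_matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) == 0) stop("empty coordinate sets")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)          # minimise ||b0 R - a0||
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  resid <- b0 %*% rot - a0
  structure(list(
    rmscd = sqrt(mean(rowSums(resid^2))),
    rotation = rot,
    translation = as.numeric(ca - cb %*% rot),
    n_atoms = nrow(a)
  ), class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("<overlay> rmscd = %.4f Angstrom over %d atoms\n", x$rmscd, x$n_atoms))
  invisible(x)
}

# Strip the image/copy suffixes this package appends when expanding
# structures ("_k" from symmetry images, "+abc" from supercell blocks),
# recovering the asymmetric-unit label.
base_label <- function(label) {
  sub("\\+[0-9]+$", "", sub("_[0-9]+(\\+[0-9]+)?$", "\\1", label))
}

# Split a P1 crystal into molecules; returns a list of data.frames of
# sites (with base labels) ordered by base label, each molecule wrapped so
# its centroid lies in [0,1)^3.
molecule_blocks <- function(x, topo = NULL, tolerance = 0.40) {
  if (is.null(topo)) topo <- perceive_bonds(x, tolerance)
  frac <- crystal_frac(x)
  blocks <- list()
  for (mi in seq_along(topo$molecules)) {
    labs <- topo$molecules[[mi]]
    idx <- match(labs, x$sites$label)
    f <- frac[idx, , drop = FALSE]
    # make the molecule whole by walking its bond graph: each atom is
    # re-imaged next to an already-placed bonded neighbour, so molecules
    # longer than half a cell edge are handled correctly
    if (nrow(f) > 1) {
      placed <- c(TRUE, rep(FALSE, nrow(f) - 1))
      in_mol <- topo$bonds[, 1] %in% labs & topo$bonds[, 2] %in% labs
      bi <- match(topo$bonds[in_mol, 1], labs)
      bj <- match(topo$bonds[in_mol, 2], labs)
      repeat {
        moved <- FALSE
        for (r in seq_along(bi)) {
          i <- bi[r]; j <- bj[r]
          if (placed[i] && !placed[j]) {
            f[j, ] <- f[j, ] - round(f[j, ] - f[i, ])
            placed[j] <- TRUE; moved <- TRUE
          } else if (placed[j] && !placed[i]) {
            f[i, ] <- f[i, ] - round(f[i, ] - f[j, ])
            placed[i] <- TRUE; moved <- TRUE
          }
        }
        if (!moved) break
      }
      # isolated atoms (no bonds) fall back to first-atom re-imaging
      for (i in which(!placed)) f[i, ] <- f[i, ] - round(f[i, ] - f[1, ])
    }
    cen <- colMeans(f)
    f <- sweep(f, 2, floor(cen))
    s <- x$sites[idx, , drop = FALSE]
    s$fx <- f[, 1]; s$fy <- f[, 2]; s$fz <- f[, 3]
    s$base <- base_label(s$label)
    s <- s[order(s$base), , drop = FALSE]
    blocks[[mi]] <- s
  }
  blocks
}

block_cart <- function(block, cell, non_h = TRUE) {
  if (non_h) block <- block[block$element != "H", , drop = FALSE]
  frac_to_cart(as.matrix(block[, c("fx", "fy", "fz")]), cell)
}

#' RMSCD between two crystal structures
#'
#' Root-mean-square Cartesian displacement over matched non-hydrogen atoms
#' after optimal rigid overlay. In `"molecule"` mode a single molecule is
#' compared; in `"cell_cluster"` mode all molecules of one unit cell are
#' overlaid as a cluster, with the molecule-to-molecule assignment chosen
#' to minimize the RMSCD (exhaustive over permutations up to 8 molecules,
#' greedy by centroid proximity beyond). Atoms correspond by
#' asymmetric-unit label; molecules displaced by whole lattice vectors are
#' re-imaged, so pure periodic rearrangements give zero.
#'
#' @param a,b P1 [crystal()] objects (non-P1 inputs are expanded).
#' @param mode `"cell_cluster"` (default) or `"molecule"`.
#' @param label_map Optional named character vector translating a's
#'   asymmetric-unit labels to b's.
#' @param tolerance Bond-perception tolerance used to split molecules.
#' @return An `"overlay_result"` (see [superpose()]) with the mode recorded.
#' @export
rmscd_crystals <- function(a, b, mode = c("cell_cluster", "molecule"),
                           label_map = NULL, tolerance = 0.40) {
  mode <- match.arg(mode)
  if (!is_p1(a)) a <- to_p1(a)
  if (!is_p1(b)) b <- to_p1(b)
  blocks_a <- molecule_blocks(a, tolerance = tolerance)
  blocks_b <- molecule_blocks(b, tolerance = tolerance)
  if (!is.null(label_map)) {
    for (i in seq_along(blocks_a)) {
      mapped <- unname(label_map[blocks_a[[i]]$base])
      blocks_a[[i]]$base <- ifelse(is.na(mapped), blocks_a[[i]]$base, mapped)
      blocks_a[[i]] <- blocks_a[[i]][order(blocks_a[[i]]$base), , drop = FALSE]
    }
  }
  sig <- function(bl) paste(sort(bl$base[bl$element != "H"]), collapse = "|")
  sigs_a <- vapply(blocks_a, sig, "")
  sigs_b <- vapply(blocks_b, sig, "")
  if (length(intersect(sigs_a, sigs_b)) == 0) {
    stop("no molecules with common (mapped) labels between the two structures")
  }

  if (mode == "molecule") {
    ia <- 1L
    ib <- which(sigs_b == sigs_a[1])[1]
    if (is.na(ib)) stop("no molecule in b matches the labels of a's first molecule")
    res <- superpose(block_cart(blocks_a[[ia]], a$cell),
                     block_cart(blocks_b[[ib]], b$cell))
    res$mode <- "molecule"
    return(res)
  }

  if (length(blocks_a) != length(blocks_b)) {
    stop("cell_cluster mode needs equal molecule counts (",
         length(blocks_a), " vs ", length(blocks_b), ")")
  }
  nm <- length(blocks_a)
  # re-image each b molecule nearest (in fractional space) to each a molecule
  cen_a <- t(vapply(blocks_a, function(s) colMeans(as.matrix(s[, c("fx", "fy", "fz")])), numeric(3)))
  cen_b <- t(vapply(blocks_b, function(s) colMeans(as.matrix(s[, c("fx", "fy", "fz")])), numeric(3)))
  shifted_b <- function(j, i) {
    s <- blocks_b[[j]]
    shift <- round(cen_b[j, ] - cen_a[i, ])
    f <- sweep(as.matrix(s[, c("fx", "fy", "fz")]), 2, shift)
    s$fx <- f[, 1]; s$fy <- f[, 2]; s$fz <- f[, 3]
    s
  }
  cluster_rmscd <- function(perm) {
    ca <- do.call(rbind, lapply(seq_len(nm), function(i) block_cart(blocks_a[[i]], a$cell)))
    cb <- do.call(rbind, lapply(seq_len(nm), function(i) block_cart(shifted_b(perm[i], i), b$cell)))
    superpose(ca, cb)
  }
  compatible <- outer(seq_len(nm), seq_len(nm),
                      Vectorize(function(i, j) sigs_a[i] == sigs_b[j]))
  if (nm <= 8) {
    perms <- all_permutations(nm)
    best <- NULL
    for (p in perms) {
      if (!all(compatible[cbind(seq_len(nm), p)])) next
      r <- cluster_rmscd(p)
      if (is.null(best) || r$rmscd < best$rmscd) best <- r
    }
    if (is.null(best)) stop("no label-compatible molecule assignment found")
  } else {
    # greedy assignment by fractional centroid min-image proximity
    p <- integer(nm)
    taken <- rep(FALSE, nm)
    for (i in seq_len(nm)) {
      dd <- vapply(seq_len(nm), function(j) {
        if (taken[j] || !compatible[i, j]) return(Inf)
        df <- cen_b[j, ] - cen_a[i, ]
        sum((df - round(df))^2)
      }, 1)
      j <- which.min(dd)
      if (!is.finite(dd[j])) stop("no label-compatible molecule assignment found")
      p[i] <- j
      taken[j] <- TRUE
    }
    best <- cluster_rmscd(p)
  }
  best$mode <- "cell_cluster"
  best
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Average structure of a trajectory
#'
#' Coordinates are unwrapped frame-to-frame (each atom shifted by whole
#' lattice vectors to minimize its displacement from the previous frame)
#' before arithmetic averaging; averaging wrapped coordinates directly is
#' the classic failure mode for atoms crossing the cell boundary. Cell
#' parameters are averaged arithmetically. Frame 1 is the unwrapping
#' reference.
#'
#' @param traj A [trajectory()].
#' @return List of class `"average_structure"`: `crystal` (mean cell, mean
#'   unwrapped coordinates), `n_frames`, and `max_drift` (largest per-atom
#'   Cartesian displacement of the average from frame 1, Angstrom).
#' @export
average_structure <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  unwrapped <- traj$frac
  if (nf > 1) {
    for (i in 2:nf) {
      prev <- unwrapped[i - 1, , , drop = FALSE]
      cur <- unwrapped[i, , , drop = FALSE]
      unwrapped[i, , ] <- cur - round(cur - prev)
    }
  }
  mean_frac <- apply(unwrapped, c(2, 3), mean)
  mean_cell <- colMeans(traj$cells)
  sites <- data.frame(label = traj$labels, element = traj$elements,
                      fx = mean_frac[, 1], fy = mean_frac[, 2],
                      fz = mean_frac[, 3], stringsAsFactors = FALSE)
  avg <- crystal(mean_cell, sites, name = "average_structure")
  disp <- frac_to_cart(mean_frac - unwrapped[1, , ], mean_cell)
  structure(list(crystal = avg, n_frames = nf,
                 max_drift = if (nf > 0) max(sqrt(rowSums(disp^2))) else 0),
            class = "average_structure")
}

#' Flag an in-run phase transition
#'
#' A trajectory is flagged when its average structure departs from the
#' reference packing: either the cell-cluster RMSCD of the average against
#' the reference exceeds `rmscd_threshold`, or any averaged cell length
#' deviates from the reference by more than `cell_drift_threshold`
#' (relative). The default RMSCD threshold of 0.35 Angstrom sits midway
#' between typical stable (~0.14) and transitioned (~0.69) trajectory
#' averages for small-molecule organics.
#'
#' @param traj A [trajectory()] with the same topology as `reference`.
#' @param reference The starting [crystal()].
#' @param rmscd_threshold RMSCD threshold in Angstrom.
#' @param cell_drift_threshold Relative cell-length drift threshold.
#' @param mode Overlay mode passed to [rmscd_crystals()].
#' @return List with `flag` (logical), `rmscd`, `max_cell_drift` and the
#'   `average` structure used.
#' @export
flag_phase_transition <- function(traj, reference, rmscd_threshold = 0.35,
                                  cell_drift_threshold = 0.05,
                                  mode = "cell_cluster") {
  avg <- average_structure(traj)
  ov <- rmscd_crystals(avg$crystal, reference, mode = mode)
  ref_len <- as.numeric(reference$cell)[1:3]
  avg_len <- as.numeric(avg$crystal$cell)[1:3]
  drift <- max(abs(avg_len - ref_len) / ref_len)
  list(flag = ov$rmscd > rmscd_threshold || drift > cell_drift_threshold,
       rmscd = ov$rmscd, max_cell_drift = drift, average = avg)
}
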