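# Synthetic campaign generators: a toy molecular crystal, a declared
# forward model mapping structure to shieldings (13C conformation-dominated
# via torsion terms, 1H packing-sensitive via an inverse-cube
# intermolecular proximity term), rigid-perturbation CSP-like candidate
# sets, and jitter + methyl-rotor trajectories. These stand in for the
# electronic-structure and MD engines so every pipeline stage runs and is
# testable offline; they are statistical surrogates, not predictors.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched, making every generator a pure function of
# (inputs, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

unit_vec <- function(v) v / sqrt(sum(v^2))

cross3 <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                           u[3] * w[1] - u[1] * w[3],
                           u[1] * w[2] - u[2] * w[1])

# Rotation matrix for angle (radians) about unit axis (Rodrigues).
rotation_matrix <- function(axis, angle) {
  a <- unit_vec(axis)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

rotate_about_axis <- function(points, origin, axis, angle) {
  points <- to_coord_matrix(points)
  r <- rotation_matrix(axis, angle)
  sweep(sweep(points, 2, origin) %*% t(r), 2, origin, "+")
}

# Signed dihedral angle (radians, in (-pi, pi]) of four Cartesian points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Directions completing an approximately tetrahedral arrangement around a
# centre given the unit directions of existing neighbours.
complete_tetrahedron <- function(neighbour_dirs, n_new) {
  tet <- 109.4712206 * pi / 180
  k <- nrow(neighbour_dirs)
  if (k == 0) stop("need at least one existing neighbour direction")
  if (k == 1) {
    n1 <- neighbour_dirs[1, ]
    ref <- if (abs(n1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit_vec(cross3(n1, ref))
    dirs <- t(vapply(0:(n_new - 1), function(i) {
      d <- cos(tet) * n1 + sin(tet) * perp
      as.numeric(rotation_matrix(n1, i * 2 * pi / 3) %*% d)
    }, numeric(3)))
  } else if (k == 2) {
    u <- unit_vec(-(neighbour_dirs[1, ] + neighbour_dirs[2, ]))
    w <- unit_vec(cross3(neighbour_dirs[1, ], neighbour_dirs[2, ]))
    psi <- tet / 2
    dirs <- rbind(cos(psi) * u + sin(psi) * w,
                  cos(psi) * u - sin(psi) * w)[seq_len(n_new), , drop = FALSE]
  } else {
    dirs <- matrix(unit_vec(-colSums(neighbour_dirs)), 1, 3)
  }
  dirs
}

#' Toy molecule for synthetic campaigns
#'
#' A pentanol-like test molecule (5 carbons in a zigzag chain, a hydroxyl
#' on C3, methyls at both chain ends) with idealised tetrahedral geometry.
#' Small enough for fast pipelines yet exercising every structural feature
#' the scoring needs: two methyl rotors, distinguishable carbon sites, a
#' backbone torsion (C2-C3-C4-C5) that can flip, and hydroxyl/ methylene
#' protons whose shifts feel the packing.
#'
#' @return List with `labels`, `elements` and Cartesian `coords` (Angstrom,
#'   centred on the centroid).
#' @export
toy_molecule <- function() {
  ch <- 1.09; co <- 1.43; oh <- 0.96
  # zigzag chain with 1.54 A bonds and tetrahedral angles: advance p along
  # x, alternate q in y
  p <- 1.54 * sqrt(2 / 3); q <- 1.54 / sqrt(3)
  pos <- list(
    C1 = c(0, 0, 0), C2 = c(p, q, 0), C3 = c(2 * p, 0, 0),
    C4 = c(3 * p, q, 0), C5 = c(4 * p, 0, 0)
  )
  add_h <- function(centre, neighbours, labels, lens) {
    nd <- t(vapply(neighbours, function(nb) unit_vec(pos[[nb]] - pos[[centre]]), numeric(3)))
    dirs <- complete_tetrahedron(nd, length(labels))
    for (i in seq_along(labels)) {
      pos[[labels[i]]] <<- pos[[centre]] + lens[i] * dirs[i, ]
    }
  }
  add_h("C3", c("C2", "C4"), c("O6", "H31"), c(co, ch))
  add_h("C1", "C2", c("H11", "H12", "H13"), rep(ch, 3))
  add_h("C2", c("C1", "C3"), c("H21", "H22"), rep(ch, 2))
  add_h("C4", c("C3", "C5"), c("H41", "H42"), rep(ch, 2))
  add_h("C5", "C4", c("H51", "H52", "H53"), rep(ch, 3))
  add_h("O6", "C3", "H61", oh)
  labels <- names(pos)
  coords <- do.call(rbind, pos)
  coords <- sweep(coords, 2, colMeans(coords))
  list(labels = labels, elements = gsub("[0-9]", "", labels), coords = coords)
}

#' Toy molecular crystal (Z = 2)
#'
#' Packs two copies of [toy_molecule()] related by an exact 2_1 screw
#' along c — fractional operation (-x, -y, z + 1/2) — in a monoclinic
#' unique-c cell, expressed directly in P1. The two molecules are
#' therefore crystallographically equivalent (identical packing
#' environments), as symmetry-related molecules are in a real Z' = 1
#' structure. Copy-2 labels carry the `_2` suffix.
#'
#' @param name Structure name.
#' @return A P1 [crystal()] with Z = 2.
#' @export
toy_crystal <- function(name = "toy") {
  mol <- toy_molecule()
  cell <- unit_cell(10.5, 8.5, 7.5, 90, 90, 96)
  m <- cell_matrix(cell)
  f1 <- sweep(mol$coords %*% solve(m), 2, c(0.25, 0.25, 0.25), "+")
  # 2_1 screw along c: a genuine symmetry of the unique-c monoclinic
  # lattice, so both copies see identical environments
  f2 <- cbind(-f1[, 1], -f1[, 2], f1[, 3] + 0.5)
  sites <- data.frame(
    label = c(mol$labels, paste0(mol$labels, "_2")),
    element = c(mol$elements, mol$elements),
    fx = c(f1[, 1], f2[, 1]), fy = c(f1[, 2], f2[, 2]), fz = c(f1[, 3], f2[, 3]),
    stringsAsFactors = FALSE
  )
  crystal(cell, sites, z_value = 2L, z_prime = 1, name = name)
}

#' Forward shift model
#'
#' Declared statistical surrogate for an electronic-structure shielding
#' calculation. Per nucleus, the true shift is a base value for its site
#' class, plus (13C) torsion terms `coeff * |dihedral|` in ppm per radian
#' for designated backbone torsions — emulating conformation-dominated
#' carbon shifts — plus (1H) `packing_coeff` times the inverse-cube sum of
#' intermolecular distances within `cutoff` — emulating packing-sensitive
#' proton shifts. Shieldings are `sigma_ref_true - shift + noise`.
#'
#' @param base_shifts Named numeric vector of base shifts (ppm) per
#'   asymmetric-unit label; defaults cover [toy_molecule()].
#' @param torsions List of `list(atoms = 4 labels, target = carbon label,
#'   coeff = ppm/rad)` terms.
#' @param packing_coeff ppm.A^3 coefficient of the 1H proximity term.
#' @param cutoff Proximity cutoff in Angstrom.
#' @param noise_sd_H,noise_sd_C Gaussian method-error sd in ppm.
#' @return List of class `"forward_shift_model"`.
#' @export
forward_shift_model <- function(base_shifts = NULL, torsions = NULL,
                                packing_coeff = 12.0, cutoff = 5.5,
                                noise_sd_H = 0.3, noise_sd_C = 1.5) {
  if (is.null(base_shifts)) {
    base_shifts <- c(
      C1 = 14.2, C2 = 33.5, C3 = 71.0, C4 = 36.8, C5 = 18.9,
      H11 = 0.90, H12 = 0.90, H13 = 0.90, H21 = 1.45, H22 = 1.45,
      H31 = 3.60, H41 = 1.52, H42 = 1.52, H51 = 0.95, H52 = 0.95,
      H53 = 0.95, H61 = 2.80
    )
  }
  if (is.null(torsions)) {
    torsions <- list(list(atoms = c("C2", "C3", "C4", "C5"), target = "C5",
                          coeff = 9.0))
  }
  structure(list(base_shifts = base_shifts, torsions = torsions,
                 packing_coeff = packing_coeff, cutoff = cutoff,
                 noise_sd_H = noise_sd_H, noise_sd_C = noise_sd_C),
            class = "forward_shift_model")
}

# Inverse-cube intermolecular proximity sums for every atom: over all
# periodic images within `cutoff`, excluding the atom itself and — for
# same-molecule partners — the single nearest (intramolecular) image;
# farther images of the own molecule are genuine intermolecular contacts.
proximity_sums <- function(frac_all, cellm, mol_of, cutoff) {
  n <- nrow(frac_all)
  dx <- outer(frac_all[, 1], frac_all[, 1], "-")
  dy <- outer(frac_all[, 2], frac_all[, 2], "-")
  dz <- outer(frac_all[, 3], frac_all[, 3], "-")
  dx <- dx - round(dx); dy <- dy - round(dy); dz <- dz - round(dz)
  shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
  prox_pair <- matrix(0, n, n)
  dmin <- matrix(Inf, n, n)
  for (k in seq_len(nrow(shifts))) {
    fx <- dx + shifts[k, 1]; fy <- dy + shifts[k, 2]; fz <- dz + shifts[k, 3]
    cx <- fx * cellm[1, 1] + fy * cellm[2, 1] + fz * cellm[3, 1]
    cy <- fx * cellm[1, 2] + fy * cellm[2, 2] + fz * cellm[3, 2]
    cz <- fx * cellm[1, 3] + fy * cellm[2, 3] + fz * cellm[3, 3]
    r <- sqrt(cx^2 + cy^2 + cz^2)
    sel <- r > 1e-6 & r <= cutoff
    prox_pair <- prox_pair + ifelse(sel, 1 / r^3, 0)
    upd <- r < dmin & r > 1e-6
    dmin[upd] <- r[upd]
  }
  same <- outer(mol_of, mol_of, "==") & !diag(n)
  excl <- same & dmin <= cutoff
  prox_pair[excl] <- prox_pair[excl] - 1 / dmin[excl]^3
  colSums(prox_pair)
}

# Noise-free forward shifts for one P1 crystal; returns a shift table with
# one row per (molecule copy, nucleus), delta in ppm.
forward_shifts_true <- function(x, model, topo = NULL) {
  if (is.null(topo)) topo <- perceive_bonds(x)
  blocks <- molecule_blocks(x, topo)
  frac_all <- wrap_frac(crystal_frac(canonicalize(x)))
  cellm <- cell_matrix(x$cell)
  lab_all <- x$sites$label
  mol_of <- integer(length(lab_all))
  for (mi in seq_along(topo$molecules)) {
    mol_of[match(topo$molecules[[mi]], lab_all)] <- mi
  }
  prox_all <- proximity_sums(frac_all, cellm, mol_of, model$cutoff)
  rows <- list()
  for (mi in seq_along(blocks)) {
    blk <- blocks[[mi]]
    cart <- frac_to_cart(as.matrix(blk[, c("fx", "fy", "fz")]), x$cell)
    rownames(cart) <- blk$base
    delta <- unname(model$base_shifts[blk$base])
    if (any(is.na(delta) & blk$element %in% c("H", "C"))) {
      stop("forward model has no base shift for: ",
           paste(blk$base[is.na(delta) & blk$element %in% c("H", "C")], collapse = ", "))
    }
    for (tor in model$torsions) {
      if (!all(tor$atoms %in% blk$base) || !(tor$target %in% blk$base)) next
      ang <- dihedral(cart[tor$atoms[1], ], cart[tor$atoms[2], ],
                      cart[tor$atoms[3], ], cart[tor$atoms[4], ])
      delta[blk$base == tor$target] <- delta[blk$base == tor$target] +
        tor$coeff * abs(ang)
    }
    # intermolecular inverse-cube proximity term for hydrogens
    h_rows <- which(blk$element == "H")
    if (length(h_rows)) {
      i_all <- match(blk$label[h_rows], lab_all)
      delta[h_rows] <- delta[h_rows] + model$packing_coeff * prox_all[i_all]
    }
    keep <- blk$element %in% c("H", "C")
    rows[[mi]] <- data.frame(structure_id = x$name, frame = NA_integer_,
                             molecule = mi, label = blk$label[keep],
                             element = blk$element[keep],
                             delta = delta[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Forward-model shieldings for a structure
#'
#' Computes the model's true shifts and returns shieldings
#' `sigma = sigma_ref_true - delta_true + noise`, deterministic per seed.
#'
#' @param x A P1 [crystal()].
#' @param model A [forward_shift_model()].
#' @param sigma_ref_true Named per-element true reference shieldings (ppm).
#' @param seed Integer seed for the noise draw.
#' @param frame,topology Optional frame index to stamp and pre-computed
#'   topology.
#' @return A shielding table data.frame.
#' @export
forward_shieldings <- function(x, model, sigma_ref_true = c(H = 31.2, C = 170.5),
                               seed = 0, frame = NA_integer_, topology = NULL) {
  tab <- forward_shifts_true(x, model, topology)
  noise_sd <- ifelse(tab$element == "H", model$noise_sd_H, model$noise_sd_C)
  noise <- with_seed(seed, stats::rnorm(nrow(tab), 0, 1)) * noise_sd
  out <- shielding_table(tab$structure_id, tab$label, tab$element,
                         unname(sigma_ref_true[tab$element]) - tab$delta + noise,
                         frame = frame, molecule = tab$molecule)
  out
}

#' Generate a CSP-like candidate set
#'
#' Candidate 1 ("cand_00") is the unperturbed truth; decoys apply
#' molecule-rigid random rotations/translations and isotropic cell-length
#' perturbations, resampled until no intermolecular contact falls below
#' `min_contact` and bond perception still recovers the original molecule
#' partition.
#'
#' @param base A P1 molecular [crystal()].
#' @param n_decoys Number of perturbed packings to generate.
#' @param trans_sd Cartesian translation sd per molecule (Angstrom).
#' @param rot_sd_deg Rotation-angle sd per molecule (degrees).
#' @param cell_sd Relative cell-length perturbation sd.
#' @param min_contact Minimum allowed intermolecular distance (Angstrom).
#' @param seed Integer seed.
#' @return Named list of [crystal()] objects, truth first.
#' @export
generate_candidates <- function(base, n_decoys = 10, trans_sd = 0.5,
                                rot_sd_deg = 20, cell_sd = 0.02,
                                min_contact = 1.5, seed = 0) {
  stopifnot(inherits(base, "crystal"))
  topo0 <- perceive_bonds(base)
  mol_sizes <- sort(vapply(topo0$molecules, length, 1L))
  out <- list(cand_00 = stamp_name(base, "cand_00"))
  with_seed(seed, {
    for (d in seq_len(n_decoys)) {
      ok <- FALSE
      for (attempt in 1:100) {
        cand <- perturb_packing(base, topo0, trans_sd, rot_sd_deg, cell_sd)
        if (packing_valid(cand, mol_sizes, min_contact)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not generate a collision-free decoy after 100 attempts")
      nm <- sprintf("cand_%02d", d)
      out[[nm]] <- stamp_name(cand, nm)
    }
  })
  out
}

stamp_name <- function(x, name) { x$name <- name; x }

perturb_packing <- function(base, topo, trans_sd, rot_sd_deg, cell_sd) {
  cellpar <- as.numeric(base$cell)
  cellpar[1:3] <- cellpar[1:3] * (1 + stats::rnorm(3, 0, cell_sd))
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3],
                    cellpar[4], cellpar[5], cellpar[6])
  m <- cell_matrix(cell)
  frac <- crystal_frac(base)
  out <- frac
  for (labs in topo$molecules) {
    idx <- match(labs, base$sites$label)
    cart <- frac[idx, , drop = FALSE] %*% m
    cen <- colMeans(cart)
    axis <- stats::rnorm(3)
    angle <- stats::rnorm(1, 0, rot_sd_deg) * pi / 180
    cart <- rotate_about_axis(cart, cen, axis, angle)
    cart <- sweep(cart, 2, stats::rnorm(3, 0, trans_sd), "+")
    out[idx, ] <- cart %*% solve(m)
  }
  x <- set_frac(base, out)
  x$cell <- cell
  x
}

packing_valid <- function(x, mol_sizes, min_contact) {
  topo <- tryCatch(perceive_bonds(x), error = function(e) NULL)
  if (is.null(topo)) return(FALSE)
  if (!identical(sort(vapply(topo$molecules, length, 1L)), mol_sizes)) return(FALSE)
  min_intermolecular_distance(x, topo) >= min_contact
}

# Smallest intermolecular distance in a P1 crystal, counting periodic
# images of a molecule as neighbours of itself.
min_intermolecular_distance <- function(x, topo = NULL) {
  if (is.null(topo)) topo <- perceive_bonds(x)
  frac <- wrap_frac(crystal_frac(x))
  lab <- x$sites$label
  mol_of <- integer(length(lab))
  for (mi in seq_along(topo$molecules)) mol_of[match(topo$molecules[[mi]], lab)] <- mi
  m <- cell_matrix(x$cell)
  shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
  best <- Inf
  for (i in seq_along(lab)) {
    df <- sweep(frac, 2, frac[i, ])
    df <- df - round(df)
    same <- mol_of == mol_of[i]
    dmin_same <- rep(Inf, length(lab))
    rs <- matrix(NA_real_, length(lab), nrow(shifts))
    for (k in seq_len(nrow(shifts))) {
      dc <- sweep(df, 2, shifts[k, ], "+") %*% m
      rs[, k] <- sqrt(rowSums(dc^2))
    }
    dmin_same <- apply(rs, 1, min)
    for (k in seq_len(nrow(shifts))) {
      r <- rs[, k]
      inter <- r > 1e-6 & !(same & abs(r - dmin_same) < 1e-9)
      if (any(inter)) best <- min(best, min(r[inter]))
    }
  }
  best
}

#' Jitter model for synthetic trajectories
#'
#' @param amplitude Named per-element Gaussian sd of Cartesian displacement
#'   (Angstrom); unnamed scalar applies to all elements.
#' @param methyl_rotor_rate Poisson rate of 120-degree methyl hops per ps.
#' @param drift Optional phase-transition surrogate: `list(total =
#'   Angstrom, molecule = index, angle_deg_per_A = 30, shape =
#'   "equilibration")`. One molecule is coherently displaced by `total`
#'   and reoriented by `angle_deg_per_A * total` about its centroid —
#'   packing changes reorient molecules, and a pure translation is largely
#'   absorbed by the optimal overlay. Shape `"equilibration"` applies the
#'   full change from frame 1 (the transition happened before the
#'   production run, the common experimental phenomenology);
#'   `"linear"` ramps it over the run (slow drift).
#' @param n_frames,timestep_ps Trajectory length and spacing.
#' @param seed Integer seed.
#' @return List of class `"jitter_model"`.
#' @export
jitter_model <- function(amplitude = c(H = 0.10, C = 0.06, N = 0.06, O = 0.06),
                         methyl_rotor_rate = 0, drift = NULL,
                         n_frames = 24, timestep_ps = 4, seed = 0) {
  structure(list(amplitude = amplitude, methyl_rotor_rate = methyl_rotor_rate,
                 drift = drift, n_frames = as.integer(n_frames),
                 timestep_ps = timestep_ps, seed = seed),
            class = "jitter_model")
}

amplitude_for <- function(model, elements) {
  a <- model$amplitude
  if (is.null(names(a))) return(rep(a[1], length(elements)))
  out <- a[elements]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate a synthetic trajectory
#'
#' Frames are the base structure plus i.i.d. Gaussian Cartesian jitter;
#' methyl hydrogens additionally hop by 120 degrees about their C-heavy
#' axis as a Poisson process (fast-rotor surrogate, conserving C-H bond
#' lengths); an optional drift schedule displaces one molecule coherently
#' (phase-transition surrogate). With zero amplitude, rate and drift all
#' frames equal the input.
#'
#' @param x A P1 [crystal()].
#' @param model A [jitter_model()].
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(x, model) {
  stopifnot(inherits(x, "crystal"), inherits(model, "jitter_model"))
  topo <- perceive_bonds(x)
  if (model$methyl_rotor_rate > 0 && length(topo$methyl_groups) == 0) {
    stop("methyl rotor requested but the structure has no methyl groups")
  }
  nf <- model$n_frames
  lab <- x$sites$label
  base_cart <- crystal_cart(make_whole(x, topo))
  amp <- amplitude_for(model, x$sites$element)
  minv <- solve(cell_matrix(x$cell))
  frac <- array(NA_real_, c(nf, length(lab), 3))
  with_seed(model$seed, {
    rotor_angle <- rep(0, length(topo$methyl_groups))
    for (f in seq_len(nf)) {
      cart <- base_cart
      if (model$methyl_rotor_rate > 0 && f > 1) {
        hops <- stats::rpois(length(rotor_angle),
                             model$methyl_rotor_rate * model$timestep_ps)
        rotor_angle <- rotor_angle + hops * 2 * pi / 3
      }
      for (gi in seq_along(topo$methyl_groups)) {
        if (rotor_angle[gi] == 0) next
        me <- topo$methyl_groups[[gi]]
        ci <- match(me$carbon, lab)
        hv <- match(me$heavy_neighbour, lab)
        hs <- match(me$hydrogens, lab)
        axis <- base_cart[ci, ] - base_cart[hv, ]
        cart[hs, ] <- rotate_about_axis(base_cart[hs, , drop = FALSE],
                                        base_cart[ci, ], axis, rotor_angle[gi])
      }
      if (any(amp > 0)) {
        cart <- cart + matrix(stats::rnorm(length(cart)), ncol = 3) * amp
      }
      if (!is.null(model$drift) && model$drift$total > 0) {
        dr <- model$drift
        mi <- if (is.null(dr$molecule)) 1L else dr$molecule
        shape <- if (is.null(dr$shape)) "equilibration" else dr$shape
        ang_per_a <- if (is.null(dr$angle_deg_per_A)) 30 else dr$angle_deg_per_A
        idx <- match(topo$molecules[[mi]], lab)
        s <- switch(shape,
                    equilibration = 1,
                    linear = if (nf > 1) (f - 1) / (nf - 1) else 1,
                    stop("unknown drift shape: ", shape))
        cen <- colMeans(cart[idx, , drop = FALSE])
        cart[idx, ] <- rotate_about_axis(cart[idx, , drop = FALSE], cen, c(0, 0, 1),
                                         s * ang_per_a * dr$total * pi / 180)
        cart[idx, 1] <- cart[idx, 1] + dr$total * s
      }
      frac[f, , ] <- cart %*% minv
    }
  })
  cells <- matrix(rep(as.numeric(x$cell), nf), nf, 6, byrow = TRUE)
  trajectory(lab, x$sites$element, frac, cells, model$timestep_ps)
}

# Re-image every molecule whole and with centroid in [0,1); keeps site
# order.
make_whole <- function(x, topo = NULL) {
  blocks <- molecule_blocks(x, topo)
  all_sites <- do.call(rbind, blocks)
  idx <- match(x$sites$label, all_sites$label)
  set_frac(x, as.matrix(all_sites[idx, c("fx", "fy", "fz")]))
}
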