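# Synthetic campaign assembly: everything the scoring pipeline consumes,
# written to disk in the same formats real data would arrive in (CIF,
# extended-XYZ, TSV, YAML manifest), with a planted ground truth.

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

#' Campaign configuration
#'
#' Defaults define the reference study conditions of the synthetic
#' campaigns: 10 decoy packings plus the truth plus one backbone-flipped
#' conformer, per-nucleus forward noise of 1.5 ppm (13C) / 0.3 ppm (1H),
#' assignment noise sized so the truth candidate's expected RMSD equals
#' the benchmark-window mean, a Z = 2 frame plan (24 frames x 4 ps, 48
#' molecular spectra), two decoys with a planted 1 Angstrom drift
#' (phase-transition surrogate), and a 4.43 kJ/mol energy gap between the
#' two lowest candidates.
#'
#' @param n_decoys Number of rigid-perturbation decoys.
#' @param include_flip Add one conformer decoy with the backbone torsion
#'   rotated by 60 degrees (shifts its C5 by ~9 ppm, so the 3-sigma
#'   pre-filter removes it).
#' @param model A [forward_shift_model()].
#' @param sigma_ref_true Named per-element true reference shieldings.
#' @param assignment_noise Named per-element sd (ppm) of the noise added to
#'   the truth shifts when fabricating the experimental assignment.
#' @param min_h_separation Minimum RMS 1H forward-model separation
#'   (ppm) each decoy must have from the truth; decoys are resampled until
#'   they clear it.
#' @param windows List of [benchmark_window()]s keyed `C`, `H`.
#' @param approaches Which computational approaches to emulate
#'   (`"static"`, `"md"`).
#' @param rotor_rate Methyl hop rate (per ps) in MD frames.
#' @param jitter_amplitude Per-element Cartesian jitter sd (Angstrom).
#' @param n_transitions How many kept decoys get a planted phase
#'   transition.
#' @param drift_total Planted coherent drift in Angstrom.
#' @param energy_gap Lattice-energy gap (kJ/mol) between the truth and the
#'   second-lowest candidate.
#' @param energy_span Spread of the remaining candidates above the truth.
#' @param ff_energy_sd,ff_energy_offset Noise sd and constant offset of the
#'   surrogate force-field energies relative to the reference method.
#' @param trans_sd,rot_sd_deg,cell_sd Decoy perturbation scales (see
#'   [generate_candidates()]).
#' @return List of class `"campaign_config"`.
#' @export
campaign_config <- function(n_decoys = 10, include_flip = TRUE,
                            model = forward_shift_model(),
                            sigma_ref_true = c(H = 31.2, C = 170.5),
                            assignment_noise = c(H = 0.221, C = 1.166),
                            min_h_separation = 0.5,
                            windows = list(C = benchmark_window("C"),
                                           H = benchmark_window("H")),
                            approaches = c("static", "md"),
                            rotor_rate = 0.5,
                            jitter_amplitude = c(H = 0.10, C = 0.06, N = 0.06, O = 0.06),
                            n_transitions = 2, drift_total = 1.0,
                            energy_gap = 4.43, energy_span = 12,
                            ff_energy_sd = 1.5, ff_energy_offset = 60,
                            trans_sd = 0.5, rot_sd_deg = 20, cell_sd = 0.02) {
  structure(as.list(environment()), class = "campaign_config")
}

# Truth-model mean shifts per asymmetric-unit label: noise-free forward
# shifts, averaged over molecule copies, methyl protons averaged.
true_mean_shifts <- function(x, model, topo = NULL) {
  if (is.null(topo)) topo <- perceive_bonds(x)
  tab <- forward_shifts_true(x, model, topo)
  tab <- average_methyl_protons(tab, topo)
  agg <- stats::aggregate(tab$delta,
                          by = list(label = base_label(tab$label), element = tab$element),
                          FUN = mean)
  data.frame(label = agg$label, element = agg$element, delta = agg$x,
             stringsAsFactors = FALSE)
}

# RMS 1H separation between two candidates' noise-free mean shifts.
h_separation <- function(mean_a, mean_b) {
  m <- merge(mean_a[mean_a$element == "H", ], mean_b[mean_b$element == "H", ],
             by = "label")
  sqrt(mean((m$delta.x - m$delta.y)^2))
}

# Mean offset of b's 1H shifts from a's (positive = b denser packing).
h_mean_offset <- function(mean_a, mean_b) {
  m <- merge(mean_a[mean_a$element == "H", ], mean_b[mean_b$element == "H", ],
             by = "label")
  mean(m$delta.y - m$delta.x)
}

# Rescale the cell isotropically while keeping every molecule's internal
# geometry rigid (only centroids move with the lattice).
rescale_cell_rigid <- function(x, s, topo = NULL) {
  if (is.null(topo)) topo <- perceive_bonds(x)
  cellpar <- as.numeric(x$cell)
  new_cell <- unit_cell(cellpar[1] * s, cellpar[2] * s, cellpar[3] * s,
                        cellpar[4], cellpar[5], cellpar[6])
  old_m <- cell_matrix(x$cell)
  new_m <- cell_matrix(new_cell)
  whole <- make_whole(x, topo)
  frac <- crystal_frac(whole)
  out <- frac
  for (labs in topo$molecules) {
    idx <- match(labs, x$sites$label)
    cart <- frac[idx, , drop = FALSE] %*% old_m
    cen_frac <- colMeans(frac[idx, , drop = FALSE])
    cart_new <- sweep(sweep(cart, 2, colMeans(cart)), 2, cen_frac %*% new_m, "+")
    out[idx, ] <- cart_new %*% solve(new_m)
  }
  y <- set_frac(x, out)
  y$cell <- new_cell
  y
}

# Unrelaxed random packings systematically compress intermolecular
# contacts, inflating the convex inverse-cube proximity sums and hence
# biasing the pooled sigma_ref fit. Real CSP candidates are
# energy-minimized and sit at physical densities, so decoys are rescaled
# until their molecule-averaged 1H proximity shift matches the parent
# structure (secant iteration on the isotropic cell scale).
calibrate_decoy_density <- function(cand, truth_mean, model, tol = 0.02,
                                    max_iter = 8) {
  g <- function(x) h_mean_offset(truth_mean, true_mean_shifts(x, model))
  s0 <- 1; g0 <- g(cand)
  if (abs(g0) < tol) return(cand)
  s1 <- if (g0 > 0) 1.03 else 0.97
  x1 <- rescale_cell_rigid(cand, s1)
  g1 <- g(x1)
  for (i in seq_len(max_iter)) {
    if (abs(g1) < tol) return(x1)
    if (g1 == g0) break
    s2 <- s1 - g1 * (s1 - s0) / (g1 - g0)
    s2 <- min(max(s2, 0.85), 1.2)
    x1 <- rescale_cell_rigid(cand, s2)
    s0 <- s1; g0 <- g1; s1 <- s2; g1 <- g(x1)
  }
  x1
}

# Rotate the chain tail (target atoms) of every molecule about the
# axis_labels bond, changing the designated backbone torsion.
flip_torsion <- function(x, axis_labels = c("C3", "C4"),
                         moving = c("C5", "H51", "H52", "H53"),
                         angle_deg = 60) {
  topo <- perceive_bonds(x)
  blocks <- molecule_blocks(x, topo)
  frac <- crystal_frac(x)
  m <- cell_matrix(x$cell)
  for (blk in blocks) {
    if (!all(axis_labels %in% blk$base)) next
    cart <- frac_to_cart(as.matrix(blk[, c("fx", "fy", "fz")]), x$cell)
    rownames(cart) <- blk$base
    mv <- blk$label[blk$base %in% moving]
    cart_mv <- cart[blk$base %in% moving, , drop = FALSE]
    rot <- rotate_about_axis(cart_mv, cart[axis_labels[1], ],
                             cart[axis_labels[2], ] - cart[axis_labels[1], ],
                             angle_deg * pi / 180)
    idx <- match(mv, x$sites$label)
    frac[idx, ] <- rot %*% solve(m)
  }
  set_frac(x, frac)
}

#' Generate a complete synthetic campaign on disk
#'
#' Writes candidates (multi-block CIF), an experimental-style shift
#' assignment fabricated from the truth candidate, static shielding tables
#' for every candidate, MD-frame shielding tables and extended-XYZ
#' trajectories for every candidate surviving the static 3-sigma
#' pre-filter (48 molecular spectra each under the Z = 2 frame plan),
#' lattice energies for a reference method and a surrogate force field,
#' and a YAML manifest recording every derived seed and threshold. The
#' truth candidate is `cand_00`; a fixed seed reproduces the bundle
#' byte-for-byte.
#'
#' @param dir Target directory (must not exist unless `overwrite`).
#' @param config A [campaign_config()].
#' @param seed Integer master seed; all internal seeds derive from it.
#' @param overwrite Allow writing into an existing directory.
#' @return The manifest list, invisibly; files under `dir`.
#' @export
make_campaign <- function(dir, config = campaign_config(), seed = 0,
                          overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop("campaign directory exists (use overwrite = TRUE): ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trajectories"), showWarnings = FALSE)
  base <- toy_crystal("cand_00")
  topo <- perceive_bonds(base)
  truth_mean <- true_mean_shifts(base, config$model, topo)

  # --- candidates: truth + separation-enforced decoys + torsion flip ----
  cands <- list(cand_00 = base)
  seps <- numeric(0)
  for (d in seq_len(config$n_decoys)) {
    found <- FALSE
    for (attempt in 0:49) {
      sub_seed <- (seed * 977 + d * 131 + attempt * 7919) %% .Machine$integer.max
      cand <- generate_candidates(base, n_decoys = 1, trans_sd = config$trans_sd,
                                  rot_sd_deg = config$rot_sd_deg,
                                  cell_sd = config$cell_sd, seed = sub_seed)[[2]]
      cand <- calibrate_decoy_density(cand, truth_mean, config$model)
      if (min_intermolecular_distance(cand) < 1.5) next
      sep <- h_separation(truth_mean, true_mean_shifts(cand, config$model))
      if (sep >= config$min_h_separation) {
        nm <- sprintf("cand_%02d", d)
        cands[[nm]] <- stamp_name(cand, nm)
        seps <- c(seps, sep)
        found <- TRUE
        break
      }
    }
    if (!found) stop("decoy ", d, " never reached the required 1H separation")
  }
  if (config$include_flip) {
    nm <- sprintf("cand_%02d", config$n_decoys + 1)
    cands[[nm]] <- stamp_name(flip_torsion(base), nm)
  }
  write_cif(cands, file.path(dir, "candidates.cif"))
  ids <- names(cands)

  # --- experimental-style assignment from the truth candidate ----------
  asg <- truth_mean
  asg <- asg[order(asg$element, asg$label), ]
  groups <- value_groups(asg$label, topo)
  noise <- with_seed(seed * 977 + 7,
                     stats::rnorm(length(unique(groups))))[match(groups, unique(groups))]
  asg$delta_exp <- asg$delta + noise * unname(config$assignment_noise[asg$element])
  write_assignment_tsv(asg, file.path(dir, "assignment.tsv"))

  # --- static shieldings ----------------------------------------------
  static_tabs <- lapply(seq_along(ids), function(i) {
    forward_shieldings(cands[[i]], config$model, config$sigma_ref_true,
                       seed = (seed * 977 + 500 + i) %% .Machine$integer.max)
  })
  static_all <- do.call(rbind, static_tabs)
  write_shieldings_tsv(static_all, file.path(dir, "shieldings_static.tsv"))

  # --- static 13C scoring for the pre-filter ---------------------------
  refs <- list(compute_sigma_ref(static_all, asg, "H"),
               compute_sigma_ref(static_all, asg, "C"))
  static_rmsd_c <- vapply(seq_along(ids), function(i) {
    sh <- shieldings_to_shifts(static_tabs[[i]], refs)
    sh <- average_methyl_protons(sh, topo)
    rmsd_shifts(sh, asg, "C")$rmsd
  }, 1)
  pf <- prefilter(data.frame(structure_id = ids, rmsd = static_rmsd_c,
                             stringsAsFactors = FALSE), config$windows$C)
  kept <- pf$kept

  # --- MD stage: trajectories + per-frame shieldings for kept ----------
  manifest_md <- list()
  md_rows <- list()
  plan <- plan_frames(z_value = base$z_value)
  if ("md" %in% config$approaches) {
    transition_ids <- utils::tail(setdiff(kept, "cand_00"), config$n_transitions)
    for (id in kept) {
      traj_seed <- (seed * 977 + 900 + match(id, ids)) %% .Machine$integer.max
      drift <- if (id %in% transition_ids) {
        list(total = config$drift_total, molecule = 1L)
      } else NULL
      jm <- jitter_model(amplitude = config$jitter_amplitude,
                         methyl_rotor_rate = config$rotor_rate, drift = drift,
                         n_frames = plan$n_frames, timestep_ps = plan$interval_ps,
                         seed = traj_seed)
      traj <- generate_trajectory(cands[[id]], jm)
      write_xyz_trajectory(traj, file.path(dir, "trajectories", paste0(id, ".xyz")))
      # method error: one draw per asymmetric-unit nucleus per candidate,
      # constant across frames (frames differ by geometry only)
      cand_topo <- perceive_bonds(cands[[id]])
      asu <- unique(base_label(cands[[id]]$sites$label))
      eps_seed <- (seed * 977 + 1500 + match(id, ids)) %% .Machine$integer.max
      eps <- with_seed(eps_seed, stats::rnorm(length(asu)))
      names(eps) <- asu
      el_of <- cands[[id]]$sites$element[match(asu, base_label(cands[[id]]$sites$label))]
      sd_of <- ifelse(el_of == "H", config$model$noise_sd_H, config$model$noise_sd_C)
      eps <- eps * sd_of
      noiseless <- config$model
      noiseless$noise_sd_H <- 0; noiseless$noise_sd_C <- 0
      for (f in seq_len(n_frames(traj))) {
        fr <- traj_frame(traj, f, name = id)
        tab <- forward_shieldings(fr, noiseless, config$sigma_ref_true,
                                  seed = 0, frame = f, topology = cand_topo)
        tab$sigma <- tab$sigma + unname(eps[base_label(tab$label)])
        md_rows[[length(md_rows) + 1L]] <- tab
      }
      manifest_md[[id]] <- list(seed = traj_seed,
                                transition = id %in% transition_ids)
    }
    write_shieldings_tsv(do.call(rbind, md_rows),
                         file.path(dir, "shieldings_md.tsv"))
  }

  # --- lattice energies ------------------------------------------------
  e0 <- -102.4
  n <- length(ids)
  u <- with_seed(seed * 977 + 31, stats::runif(n - 2, 0, 1))
  # truth lowest, one candidate exactly `gap` above, the rest spread out
  others <- e0 + c(config$energy_gap,
                   config$energy_gap +
                     (config$energy_span - config$energy_gap) * sort(u))
  perm <- with_seed(seed * 977 + 37, sample.int(n - 1))
  energy <- c(e0, others[perm])
  dens <- vapply(cands, crystal_density, 1)
  ref_en <- data.frame(structure_id = ids, energy = energy,
                       density = unname(dens), method = "reference",
                       stringsAsFactors = FALSE)
  ff_noise <- with_seed(seed * 977 + 41, stats::rnorm(n, 0, config$ff_energy_sd))
  ff_en <- data.frame(structure_id = ids,
                      energy = energy + config$ff_energy_offset + ff_noise,
                      density = unname(dens), method = "ff",
                      stringsAsFactors = FALSE)
  utils::write.table(rbind(ref_en, ff_en), file.path(dir, "energies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "nmrcsp",
    seed = seed,
    candidates = ids,
    truth = "cand_00",
    kept = kept,
    excluded = pf$excluded,
    prefilter_threshold_ppm = pf$threshold,
    windows = list(
      C = unclass(config$windows$C)[c("mean", "sd", "k_select", "k_prefilter")],
      H = unclass(config$windows$H)[c("mean", "sd", "k_select", "k_prefilter")]
    ),
    sigma_ref_true = as.list(config$sigma_ref_true),
    noise_sd = list(H = config$model$noise_sd_H, C = config$model$noise_sd_C),
    assignment_noise = as.list(config$assignment_noise),
    min_h_separation_ppm = config$min_h_separation,
    decoy_h_separation_ppm = as.list(stats::setNames(round(seps, 4),
                                                     sprintf("cand_%02d", seq_along(seps)))),
    frame_plan = unclass(plan),
    approaches = config$approaches,
    md = manifest_md,
    files = list(candidates = "candidates.cif", assignment = "assignment.tsv",
                 static = "shieldings_static.tsv",
                 md = if ("md" %in% config$approaches) "shieldings_md.tsv" else NULL,
                 energies = "energies.tsv", trajectories = "trajectories")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

# One resolved value per NMR peak: methyl protons share one group.
value_groups <- function(labels, topo) {
  grp <- labels
  for (me in topo$methyl_groups) {
    grp[labels %in% base_label(me$hydrogens)] <- paste0("methyl_", base_label(me$carbon))
  }
  grp
}

crystal_density <- function(x) {
  mass <- sum(.atomic_masses[x$sites$element])
  if (any(is.na(mass))) stop("no atomic mass for an element in ", x$name)
  # g/cm^3: mass in u per cell over volume in A^3
  1.66053907 * mass / cell_volume(x$cell)
}
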