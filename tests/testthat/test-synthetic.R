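test_that("the toy crystal is a valid Z = 2 molecular packing", {
  x <- toy_crystal()
  expect_equal(x$z_value, 2)
  topo <- perceive_bonds(x)
  expect_length(topo$molecules, 2)
  expect_equal(sort(vapply(topo$molecules, length, 1L)), c(18L, 18L))
  expect_length(topo$methyl_groups, 4)
  expect_gt(nmrcsp:::min_intermolecular_distance(x, topo), 2.0)
  # the 2_1-screw copies see identical environments: copy shifts match
  tab <- nmrcsp:::forward_shifts_true(x, forward_shift_model(), topo)
  m1 <- tab$delta[tab$molecule == 1][order(tab$label[tab$molecule == 1])]
  m2 <- tab$delta[tab$molecule == 2][order(nmrcsp:::base_label(tab$label[tab$molecule == 2]))]
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("candidate generation is seeded, collision-free and truth-first", {
  base <- toy_crystal("cand_00")
  cands <- generate_candidates(base, n_decoys = 2, seed = 1)
  expect_length(cands, 3)
  expect_identical(names(cands)[1], "cand_00")
  expect_equal(crystal_frac(cands[[1]]), crystal_frac(base), tolerance = 1e-12)
  # zero perturbation returns copies of the base
  null <- generate_candidates(base, n_decoys = 2, trans_sd = 0, rot_sd_deg = 0,
                              cell_sd = 0, seed = 1)
  expect_equal(crystal_frac(null[[2]]), crystal_frac(base), tolerance = 1e-12)
  # different seeds give different packings
  c1 <- generate_candidates(base, 1, seed = 1)[[2]]
  c2 <- generate_candidates(base, 1, seed = 2)[[2]]
  expect_gt(rmscd_crystals(c1, c2)$rmscd, 1e-3)
  # perturbed packings keep molecular topology and respect the contact floor
  for (cand in cands[-1]) {
    topo <- perceive_bonds(cand)
    expect_length(topo$molecules, 2)
    expect_gte(nmrcsp:::min_intermolecular_distance(cand, topo), 1.5)
  }
  # reproducibility: same seed, same structures
  again <- generate_candidates(base, n_decoys = 2, seed = 1)
  expect_equal(crystal_frac(again[[3]]), crystal_frac(cands[[3]]), tolerance = 1e-15)
})

test_that("a CSP-scale candidate list (26 packings) generates cleanly", {
  base <- toy_crystal("cand_00")
  cands <- generate_candidates(base, n_decoys = 25, seed = 4)
  expect_length(cands, 26)
  expect_length(unique(names(cands)), 26)
})

test_that("forward shieldings honour the zero-noise identities", {
  x <- toy_crystal()
  # zero coefficients and zero noise: sigma is exactly ref minus base shift
  model0 <- forward_shift_model(packing_coeff = 0, noise_sd_H = 0, noise_sd_C = 0,
                                torsions = list())
  tab <- forward_shieldings(x, model0, c(H = 31, C = 170), seed = 5)
  base <- model0$base_shifts[nmrcsp:::base_label(tab$label)]
  ref <- ifelse(tab$element == "H", 31, 170)
  expect_equal(tab$sigma, unname(ref - base), tolerance = 1e-12)
  # same seed is bit-identical; different seed differs
  m <- forward_shift_model()
  expect_identical(forward_shieldings(x, m, seed = 7)$sigma,
                   forward_shieldings(x, m, seed = 7)$sigma)
  expect_false(identical(forward_shieldings(x, m, seed = 7)$sigma,
                         forward_shieldings(x, m, seed = 8)$sigma))
})

test_that("zero-noise pipeline round trip recovers the true reference exactly", {
  x <- toy_crystal()
  topo <- perceive_bonds(x)
  model <- forward_shift_model(noise_sd_H = 0, noise_sd_C = 0)
  truth <- c(H = 31.2, C = 170.5)
  tab <- forward_shieldings(x, model, truth, seed = 1)
  asg <- nmrcsp:::true_mean_shifts(x, model, topo)
  asg$delta_exp <- asg$delta
  for (el in c("H", "C")) {
    ref <- compute_sigma_ref(tab, asg, el)
    expect_equal(ref$sigma_ref, unname(truth[el]), tolerance = 1e-9)
  }
  sh <- average_methyl_protons(shieldings_to_shifts(tab, truth), topo)
  expect_equal(rmsd_shifts(sh, asg, "H")$rmsd, 0, tolerance = 1e-9)
  expect_equal(rmsd_shifts(sh, asg, "C")$rmsd, 0, tolerance = 1e-9)
})

test_that("generators are pure functions of (inputs, seed)", {
  x <- toy_crystal()
  set.seed(123)
  before <- .Random.seed
  invisible(forward_shieldings(x, forward_shift_model(), seed = 3))
  invisible(generate_trajectory(x, jitter_model(n_frames = 2, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("all-zero jitter gives a constant trajectory equal to the input", {
  x <- toy_crystal()
  traj <- generate_trajectory(x, jitter_model(amplitude = 0, n_frames = 5, seed = 1))
  cart0 <- crystal_cart(nmrcsp:::make_whole(x))
  for (f in 1:5) {
    cf <- frac_to_cart(traj$frac[f, , ], traj$cells[f, ])
    expect_equal(cf, cart0, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the methyl rotor permutes hydrogens while conserving geometry", {
  x <- toy_crystal()
  model <- jitter_model(amplitude = 0, methyl_rotor_rate = 1.5, n_frames = 10,
                        timestep_ps = 4, seed = 6)
  traj <- generate_trajectory(x, model)
  topo <- perceive_bonds(x)
  heavy <- which(x$sites$element != "H")
  base_cart <- crystal_cart(nmrcsp:::make_whole(x, topo))
  for (f in seq_len(n_frames(traj))) {
    cart <- frac_to_cart(traj$frac[f, , ], traj$cells[f, ])
    # heavy atoms identical in every frame
    expect_equal(cart[heavy, ], base_cart[heavy, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
    # C-H bond lengths conserved through the hops
    for (me in topo$methyl_groups) {
      ci <- match(me$carbon, traj$labels)
      for (h in match(me$hydrogens, traj$labels)) {
        expect_equal(sqrt(sum((cart[h, ] - cart[ci, ])^2)), 1.09,
                     tolerance = 1e-9)
      }
    }
  }
  # hops happened somewhere in the run
  moved <- any(abs(traj$frac[n_frames(traj), , ] - traj$frac[1, , ]) > 1e-6)
  expect_true(moved)
  expect_error(generate_trajectory(
    crystal(unit_cell(10, 10, 10),
            data.frame(label = "C1", element = "C", fx = 0.5, fy = 0.5, fz = 0.5)),
    jitter_model(methyl_rotor_rate = 1)), "no methyl")
})

test_that("rotor ensemble averaging drives methyl protons to a common value", {
  x <- toy_crystal()
  topo <- perceive_bonds(x)
  noiseless <- forward_shift_model(noise_sd_H = 0, noise_sd_C = 0)
  static <- nmrcsp:::forward_shifts_true(x, noiseless, topo)
  spread0 <- diff(range(static$delta[static$label %in% c("H11", "H12", "H13")]))
  traj <- generate_trajectory(x, jitter_model(
    amplitude = 0, methyl_rotor_rate = 2, n_frames = 36, timestep_ps = 4, seed = 2))
  tabs <- lapply(seq_len(n_frames(traj)), function(f) {
    forward_shieldings(traj_frame(traj, f, name = "s"), noiseless,
                       frame = f, topology = topo)
  })
  avg <- ensemble_average(do.call(rbind, tabs))
  spread <- diff(range(avg$sigma[avg$label %in% c("H11", "H12", "H13")]))
  expect_gt(spread0, 0.01)       # statically the three protons differ
  expect_lt(spread, spread0 / 3) # motional averaging shrinks the spread
})

test_that("a campaign bundle is complete, reproducible and prefilters the flip", {
  dir1 <- withr::local_tempdir()
  cfg <- small_campaign_config(approaches = "static")
  man <- make_campaign(file.path(dir1, "c"), cfg, seed = 5)
  expect_error(make_campaign(file.path(dir1, "c"), cfg, seed = 5), "exists")
  files <- c("candidates.cif", "assignment.tsv", "shieldings_static.tsv",
             "energies.tsv", "manifest.yaml")
  for (f in files) expect_true(file.exists(file.path(dir1, "c", f)))
  expect_length(man$candidates, cfg$n_decoys + 2)
  # the torsion-flipped conformer is caught by the static 3-sigma pre-filter
  flip_id <- sprintf("cand_%02d", cfg$n_decoys + 1)
  expect_true(flip_id %in% man$excluded)
  expect_true("cand_00" %in% man$kept)
  # decoys meet the declared 1H separation floor
  expect_true(all(unlist(man$decoy_h_separation_ppm) >= man$min_h_separation_ppm))
  # byte-identical bundle under the same seed
  man2 <- make_campaign(file.path(dir1, "c2"), cfg, seed = 5)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, "c2", f)),
                     readLines(file.path(dir1, "c", f)))
  }
  # the planted energy gap survives the landscape round trip
  en <- read.delim(file.path(dir1, "c", "energies.tsv"))
  ls <- energy_landscape(en[en$method == "reference", ])
  expect_identical(ls$structure_id[1], "cand_00")
  expect_equal(energy_gap(ls, 1, 2), 4.43, tolerance = 1e-9)
})
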