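test_that("slope-constrained referencing has the closed-form solution", {
  one <- shielding_table("s", "C1", "C", 100.0)
  asg <- data.frame(label = "C1", element = "C", delta_exp = 10.0)
  expect_equal(compute_sigma_ref(one, asg, "C")$sigma_ref, 110.0)
  tab <- shielding_table("s", c("C1", "C2", "C3"), "C", c(165, 170, 175))
  asg3 <- data.frame(label = c("C1", "C2", "C3"), element = "C",
                     delta_exp = c(5, 1, -4))
  ref <- compute_sigma_ref(tab, asg3, "C")
  expect_equal(ref$sigma_ref, 170.6667, tolerance = 1e-4)
  expect_equal(ref$sigma_ref, sigma_ref_oracle(c(165, 170, 175), c(5, 1, -4)),
               tolerance = 1e-9)
  expect_equal(ref$n_points, 3)
  expect_error(compute_sigma_ref(tab, asg3, "H"), "no matched")
})

test_that("referencing residuals always have exactly zero mean", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:30, 1)
    sigma <- runif(n, 20, 200)
    delta <- runif(n, -5, 100)
    labs <- paste0("C", seq_len(n))
    ref <- compute_sigma_ref(shielding_table("s", labs, "C", sigma),
                             data.frame(label = labs, element = "C",
                                        delta_exp = delta), "C")
    resid <- (ref$sigma_ref - sigma) - delta
    expect_equal(mean(resid), 0, tolerance = 1e-9)
  }
})

test_that("shieldings convert to shifts as sigma_ref minus sigma", {
  tab <- shielding_table("s", c("C1", "H1"), c("C", "H"), c(100, 25))
  sh <- shieldings_to_shifts(tab, c(C = 110, H = 31))
  expect_equal(sh$delta, c(10, 6))
  # sigma at the reference gives zero shift
  expect_equal(shieldings_to_shifts(shielding_table("s", "C1", "C", 167.9),
                                    c(C = 167.9))$delta, 0)
  # a motional-averaging reference shielding of 167.9 ppm sends 100 -> 67.9
  expect_equal(shieldings_to_shifts(shielding_table("s", "C1", "C", 100),
                                    c(C = 167.9))$delta, 67.9)
  expect_error(shieldings_to_shifts(tab, c(C = 110)), "H")
})

test_that("methyl averaging replaces each trio by its mean, nothing else", {
  x <- toy_crystal()
  topo <- perceive_bonds(x)
  labs <- x$sites$label[x$sites$element %in% c("H", "C")]
  els <- x$sites$element[x$sites$element %in% c("H", "C")]
  set.seed(4)
  tab <- shielding_table("s", labs, els, runif(length(labs), 1, 30),
                         molecule = ifelse(grepl("_2$", labs), 2L, 1L))
  avg <- average_methyl_protons(tab, topo)
  trio <- avg$sigma[avg$label %in% c("H11", "H12", "H13")]
  expect_equal(trio, rep(mean(tab$sigma[tab$label %in% c("H11", "H12", "H13")]), 3))
  # idempotence and locality
  expect_identical(average_methyl_protons(avg, topo), avg)
  untouched <- !(nmrcsp:::base_label(tab$label) %in%
                   c("H11", "H12", "H13", "H51", "H52", "H53"))
  expect_identical(avg$sigma[untouched], tab$sigma[untouched])
  # mean conservation per trio
  expect_equal(mean(trio), mean(tab$sigma[tab$label %in% c("H11", "H12", "H13")]))
  # missing methyl hydrogen is an explicit error naming labels
  expect_error(average_methyl_protons(tab[tab$label != "H12", ], topo), "H1")
})

test_that("methyl averaging commutes with shift conversion", {
  x <- toy_crystal()
  topo <- perceive_bonds(x)
  tab <- forward_shieldings(x, forward_shift_model(), seed = 9)
  refs <- c(H = 31.2, C = 170.5)
  a <- shieldings_to_shifts(average_methyl_protons(tab, topo), refs)
  b <- average_methyl_protons(shieldings_to_shifts(tab, refs), topo)
  expect_equal(a$delta, b$delta, tolerance = 1e-12)
})

test_that("frame plans deliver 48 molecular spectra for every cell size", {
  p2 <- plan_frames(2)
  expect_equal(p2$n_frames, 24)
  expect_equal(p2$interval_ps, 4.0)
  p4 <- plan_frames(4)
  expect_equal(p4$n_frames, 12)
  expect_equal(p4$interval_ps, 8.0)
  p1 <- plan_frames(1, replication = c(2, 2, 2))
  expect_equal(p1$n_frames, 6)
  expect_equal(p1$interval_ps, 16.0)
  for (p in list(p2, p4, p1)) {
    expect_equal(p$n_frames * p$molecules_per_frame, 48)
    expect_lte(p$n_frames * p$interval_ps, 100)
  }
  expect_error(plan_frames(5), "divide")
})

test_that("ensemble averaging pools frames and molecule copies", {
  mk <- function(frame, mol, val) {
    shielding_table("s", "C1", "C", val, frame = frame, molecule = mol)
  }
  tabs <- rbind(mk(1, 1, 100), mk(1, 2, 102), mk(2, 1, 101), mk(2, 2, 103))
  avg <- ensemble_average(tabs)
  expect_equal(avg$sigma, 101.5)
  expect_equal(avg$n_obs, 4L)
  # constant input is the identity
  const <- rbind(mk(1, 1, 7), mk(2, 1, 7))
  expect_equal(ensemble_average(const)$sigma, 7)
  # a missing copy is a hard error
  expect_error(ensemble_average(rbind(tabs, mk(3, 1, 104))), "ragged")
})

test_that("ensemble averaging maps copy labels to the asymmetric unit", {
  t1 <- shielding_table("s", c("C1", "C1_2"), "C", c(10, 20), frame = 1,
                        molecule = c(1, 2))
  t2 <- shielding_table("s", c("C1", "C1_2"), "C", c(12, 22), frame = 2,
                        molecule = c(1, 2))
  avg <- ensemble_average(rbind(t1, t2))
  expect_equal(nrow(avg), 1)
  expect_identical(avg$label, "C1")
  expect_equal(avg$sigma, 16)
  # an explicit map overrides the suffix convention
  avg2 <- ensemble_average(rbind(t1, t2), molecule_map = c(C1_2 = "C9", C1 = "C9"))
  expect_identical(avg2$label, "C9")
})

test_that("shift RMSD is the root mean square over matched nuclei", {
  calc <- data.frame(structure_id = "s", frame = NA, molecule = 1,
                     label = c("C1", "C2", "C3"), element = "C",
                     delta = c(10, 20, 30))
  asg <- data.frame(label = c("C1", "C2", "C3"), element = "C",
                    delta_exp = c(12, 19, 30))
  r <- rmsd_shifts(calc, asg, "C")
  expect_equal(r$rmsd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(r$n, 3)
  # exact match and uniform offset
  expect_equal(rmsd_shifts(transform(calc, delta = asg$delta_exp), asg, "C")$rmsd, 0)
  expect_equal(rmsd_shifts(transform(calc, delta = asg$delta_exp + 1), asg, "C")$rmsd, 1)
  # permutation invariance and unmatched extras
  shuf <- calc[c(3, 1, 2), ]
  expect_equal(rmsd_shifts(shuf, asg, "C")$rmsd, r$rmsd)
  extra <- rbind(asg, data.frame(label = "C99", element = "C", delta_exp = 5))
  expect_equal(rmsd_shifts(calc, extra, "C")$rmsd, r$rmsd)
  expect_error(rmsd_shifts(calc, asg, "H"), "no matched")
})

test_that("magres files parse to isotropic shieldings (trace/3)", {
  lines <- c(
    "#$magres-abinitio-v1.0",
    "[atoms]",
    "units lattice Angstrom",
    "atom C C 1 0.0 0.0 0.0",
    "atom H H 1 1.0 0.0 0.0",
    "[/atoms]",
    "[magres]",
    "units ms ppm",
    "ms C 1 150.0 1.0 2.0 1.0 160.0 3.0 2.0 3.0 170.0",
    "ms H 1 30.0 0.0 0.0 0.0 31.0 0.0 0.0 0.0 32.0",
    "[/magres]"
  )
  path <- withr::local_tempfile(fileext = ".magres")
  writeLines(lines, path)
  tab <- read_magres(path, structure_id = "m")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sigma[tab$label == "C1"], 160)
  expect_equal(tab$sigma[tab$label == "H1"], 31)
  expect_identical(tab$element, c("C", "H"))
})

test_that("shielding and assignment TSVs round-trip", {
  tab <- forward_shieldings(toy_crystal(), forward_shift_model(), seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_shieldings_tsv(tab, p)
  back <- read_shieldings_tsv(p)
  expect_equal(back$sigma, tab$sigma, tolerance = 1e-9)
  expect_identical(back$label, tab$label)
  asg <- data.frame(label = c("H11", "C1"), element = c("H", "C"),
                    delta_exp = c(1.234, 17.8))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_assignment_tsv(asg, p2)
  expect_equal(read_assignment_tsv(p2), asg, tolerance = 1e-9)
})
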