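#' Run the candidate-selection pipeline on a campaign directory
#'
#' Orchestrates the full analysis over a campaign laid out as
#' [make_campaign()] writes it (and as real data can be arranged): reads
#' the manifest, candidates, assignment, shielding tables, trajectories
#' and energies; computes per-approach reference shieldings
#' (slope-constrained pooled fit), converts to shifts, averages methyl
#' protons and MD ensembles, scores per-candidate 1H/13C RMSDs, applies
#' the static 13C 3-sigma pre-filter and the one-sigma benchmark-window
#' shortlists, flags phase transitions from trajectory averages, ranks by
#' consensus, and summarises the lattice-energy landscape.
#'
#' @param campaign_dir Directory holding `manifest.yaml` and the campaign
#'   files.
#' @param out_dir Where to write the report tables (TSV + JSON); `NULL`
#'   skips writing.
#' @param phase_rmscd_threshold,phase_cell_threshold Phase-transition
#'   thresholds passed to [flag_phase_transition()].
#' @return List of class `"nmrcsp_report"`: `sigma_ref` (per approach and
#'   element), `scores` (candidate x approach x element), `prefilter`,
#'   `consensus`, `phase`, `energy` and the manifest.
#' @export
run_pipeline <- function(campaign_dir, out_dir = file.path(campaign_dir, "report"),
                         phase_rmscd_threshold = 0.35,
                         phase_cell_threshold = 0.05) {
  manifest_path <- file.path(campaign_dir, "manifest.yaml")
  if (!file.exists(manifest_path)) stop("no manifest.yaml in ", campaign_dir)
  manifest <- yaml::read_yaml(manifest_path)
  cands <- read_cif(file.path(campaign_dir, manifest$files$candidates))
  for (x in cands) {
    if (any(x$sites$occ < 1)) {
      stop("candidate '", x$name, "' is disordered (partial occupancy); ",
           "the pipeline scores ordered structures only")
    }
  }
  asg <- read_assignment_tsv(file.path(campaign_dir, manifest$files$assignment))
  windows <- list(
    C = benchmark_window("C", mean = manifest$windows$C$mean, sd = manifest$windows$C$sd,
                         k_select = manifest$windows$C$k_select,
                         k_prefilter = manifest$windows$C$k_prefilter),
    H = benchmark_window("H", mean = manifest$windows$H$mean, sd = manifest$windows$H$sd,
                         k_select = manifest$windows$H$k_select,
                         k_prefilter = manifest$windows$H$k_prefilter)
  )
  ids <- names(cands)
  topos <- lapply(cands, perceive_bonds)

  score_approach <- function(tables_by_id, approach) {
    refs <- list(compute_sigma_ref(tables_by_id, asg, "H"),
                 compute_sigma_ref(tables_by_id, asg, "C"))
    sigma_ref <- data.frame(
      approach = approach,
      element = c("H", "C"),
      sigma_ref = vapply(refs, `[[`, 1, "sigma_ref"),
      n_points = vapply(refs, `[[`, 1, "n_points"),
      residual_rms = vapply(refs, `[[`, 1, "residual_rms"),
      stringsAsFactors = FALSE
    )
    rows <- list()
    for (id in names(tables_by_id)) {
      sh <- shieldings_to_shifts(tables_by_id[[id]], refs)
      sh <- average_methyl_protons(sh, topos[[id]])
      for (el in c("H", "C")) {
        r <- rmsd_shifts(sh, asg, el)
        rows[[length(rows) + 1L]] <- data.frame(
          structure_id = id, approach = approach, element = el,
          rmsd = r$rmsd, n = r$n, stringsAsFactors = FALSE)
      }
    }
    list(sigma_ref = sigma_ref, scores = do.call(rbind, rows))
  }

  # ---- static approach ------------------------------------------------
  static_all <- read_shieldings_tsv(file.path(campaign_dir, manifest$files$static))
  static_by_id <- split(static_all, static_all$structure_id)[ids]
  static <- score_approach(static_by_id, "static")

  pf_scores <- static$scores[static$scores$element == "C",
                             c("structure_id", "rmsd")]
  pf <- prefilter(pf_scores, windows$C)

  # ---- MD-averaged approach ------------------------------------------
  sigma_ref <- static$sigma_ref
  scores <- static$scores
  phase <- NULL
  if (!is.null(manifest$files$md) &&
      file.exists(file.path(campaign_dir, manifest$files$md))) {
    md_all <- read_shieldings_tsv(file.path(campaign_dir, manifest$files$md))
    md_by_id <- split(md_all, md_all$structure_id)
    md_avg <- lapply(md_by_id, ensemble_average)
    md <- score_approach(md_avg, "md")
    sigma_ref <- rbind(sigma_ref, md$sigma_ref)
    scores <- rbind(scores, md$scores)

    traj_dir <- file.path(campaign_dir, manifest$files$trajectories)
    phase_rows <- list()
    for (id in names(md_by_id)) {
      tp <- file.path(traj_dir, paste0(id, ".xyz"))
      if (!file.exists(tp)) next
      traj <- read_xyz_trajectory(tp)
      fl <- flag_phase_transition(traj, cands[[id]],
                                  rmscd_threshold = phase_rmscd_threshold,
                                  cell_drift_threshold = phase_cell_threshold)
      phase_rows[[id]] <- data.frame(structure_id = id, flag = fl$flag,
                                     rmscd = fl$rmscd,
                                     max_cell_drift = fl$max_cell_drift,
                                     stringsAsFactors = FALSE)
    }
    phase <- do.call(rbind, phase_rows)
    if (!is.null(phase)) rownames(phase) <- NULL
  }

  # prefiltered candidates carry no MD-averaged scores
  scores <- scores[!(scores$approach != "static" &
                       scores$structure_id %in% pf$excluded), , drop = FALSE]
  scores$prefiltered <- scores$structure_id %in% pf$excluded
  scores$phase_transition <- if (is.null(phase)) FALSE else
    scores$structure_id %in% phase$structure_id[phase$flag]

  # ---- shortlists + consensus ----------------------------------------
  out_scores <- list()
  for (el in c("H", "C")) {
    sub <- scores[scores$element == el, , drop = FALSE]
    out_scores[[el]] <- shortlist(sub, windows[[el]])
  }
  scores <- do.call(rbind, out_scores)
  rownames(scores) <- NULL
  consensus <- consensus_rank(scores)

  # ---- energies -------------------------------------------------------
  energy <- NULL
  if (!is.null(manifest$files$energies) &&
      file.exists(file.path(campaign_dir, manifest$files$energies))) {
    en <- utils::read.delim(file.path(campaign_dir, manifest$files$energies),
                            stringsAsFactors = FALSE)
    methods <- unique(en$method)
    landscapes <- lapply(methods, function(m) {
      energy_landscape(en[en$method == m, , drop = FALSE])
    })
    names(landscapes) <- methods
    cmp <- NULL
    if (length(methods) >= 2) {
      cmp <- energy_rmsd_vs_reference(en[en$method == methods[2], ],
                                      en[en$method == methods[1], ])
    }
    energy <- list(landscapes = landscapes, ff_vs_reference = cmp)
  }

  report <- structure(list(
    sigma_ref = sigma_ref, scores = scores, prefilter = pf,
    consensus = consensus, phase = phase, energy = energy,
    windows = windows, manifest = manifest,
    thresholds = list(phase_rmscd = phase_rmscd_threshold,
                      phase_cell = phase_cell_threshold)
  ), class = "nmrcsp_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.nmrcsp_report <- function(x, ...) {
  cat(sprintf("<nmrcsp_report> %d candidates, approaches: %s\n",
              length(unique(x$scores$structure_id)),
              paste(unique(x$scores$approach), collapse = ", ")))
  cat(sprintf("  consensus rank 1: %s\n", x$consensus$structure_id[1]))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(report$sigma_ref, "sigma_ref.tsv")
  wt(report$scores, "scores.tsv")
  wt(report$consensus, "consensus.tsv")
  if (!is.null(report$phase)) wt(report$phase, "phase_transitions.tsv")
  if (!is.null(report$energy)) {
    for (m in names(report$energy$landscapes)) {
      wt(report$energy$landscapes[[m]], paste0("energy_landscape_", m, ".tsv"))
    }
  }
  json <- list(
    sigma_ref = report$sigma_ref,
    consensus = report$consensus,
    prefilter = list(kept = report$prefilter$kept,
                     excluded = report$prefilter$excluded,
                     threshold_ppm = report$prefilter$threshold),
    phase_transitions = report$phase,
    thresholds = report$thresholds,
    windows = lapply(report$windows, function(w)
      unclass(w)[c("element", "mean", "sd", "k_select", "k_prefilter")]),
    energy_ff_vs_reference = report$energy$ff_vs_reference
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Compare two computational approaches
#'
#' Tabulates per-element reference-shielding differences and per-candidate
#' RMSD differences between two approaches, either across two reports or
#' between two approach tags of one report. Deltas are `a - b`
#' (antisymmetric).
#'
#' @param a,b [run_pipeline()] reports; `b` may be omitted when `a`
#'   contains both approaches.
#' @param approach_a,approach_b Approach tags to compare (defaults: the
#'   first tag of `a` and the first of `b`, or the first two tags of `a`).
#' @return List with `sigma_ref_delta` (per element, ppm) and `rmsd_delta`
#'   (per candidate and element, ppm over the shared candidates).
#' @export
compare_approaches <- function(a, b = NULL, approach_a = NULL, approach_b = NULL) {
  if (is.null(b)) b <- a
  tags_a <- unique(a$sigma_ref$approach)
  tags_b <- unique(b$sigma_ref$approach)
  if (is.null(approach_a)) approach_a <- tags_a[1]
  if (is.null(approach_b)) {
    approach_b <- if (identical(a, b) && length(tags_b) > 1 &&
                      tags_b[1] == approach_a) tags_b[2] else tags_b[1]
  }
  sr_a <- a$sigma_ref[a$sigma_ref$approach == approach_a, ]
  sr_b <- b$sigma_ref[b$sigma_ref$approach == approach_b, ]
  if (nrow(sr_a) == 0 || nrow(sr_b) == 0) stop("approach tag not found in report")
  sm <- merge(sr_a[, c("element", "sigma_ref")], sr_b[, c("element", "sigma_ref")],
              by = "element", suffixes = c("_a", "_b"))
  sigma_ref_delta <- data.frame(element = sm$element,
                                delta = sm$sigma_ref_a - sm$sigma_ref_b,
                                stringsAsFactors = FALSE)
  sc_a <- a$scores[a$scores$approach == approach_a, c("structure_id", "element", "rmsd")]
  sc_b <- b$scores[b$scores$approach == approach_b, c("structure_id", "element", "rmsd")]
  shared <- intersect(sc_a$structure_id, sc_b$structure_id)
  if (length(shared) == 0) stop("the two reports share no candidates")
  mm <- merge(sc_a, sc_b, by = c("structure_id", "element"),
              suffixes = c("_a", "_b"))
  rmsd_delta <- data.frame(structure_id = mm$structure_id, element = mm$element,
                           delta = mm$rmsd_a - mm$rmsd_b,
                           stringsAsFactors = FALSE)
  list(approaches = c(approach_a, approach_b),
       sigma_ref_delta = sigma_ref_delta, rmsd_delta = rmsd_delta)
}
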