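#' Benchmark window for shift RMSDs
#'
#' Literature expectation for the RMSD between calculated and experimental
#' shifts of a *correct* structure: mean +/- sd, with a selection
#' multiplier (shortlist within `k_select` sd of the mean) and a
#' pre-filter multiplier (exclude beyond `mean + k_prefilter * sd`).
#' Defaults are the established static-DFT benchmarks: 1.9 +/- 0.4 ppm for
#' 13C and 0.33 +/- 0.16 ppm for 1H. No MD-averaged benchmark exists yet,
#' so the values are deliberately configurable.
#'
#' @param element `"H"` or `"C"`.
#' @param mean,sd Window centre and width in ppm.
#' @param k_select,k_prefilter Multipliers for shortlisting / exclusion.
#' @return List of class `"benchmark_window"`.
#' @export
benchmark_window <- function(element = c("C", "H"), mean = NULL, sd = NULL,
                             k_select = 1, k_prefilter = 3) {
  element <- match.arg(element)
  if (is.null(mean)) mean <- if (element == "C") 1.9 else 0.33
  if (is.null(sd)) sd <- if (element == "C") 0.4 else 0.16
  stopifnot(sd > 0)
  structure(list(element = element, mean = mean, sd = sd,
                 k_select = k_select, k_prefilter = k_prefilter),
            class = "benchmark_window")
}

#' @rdname benchmark_window
#' @param window A benchmark window.
#' @export
prefilter_threshold <- function(window) window$mean + window$k_prefilter * window$sd

#' @rdname benchmark_window
#' @export
select_bounds <- function(window) {
  c(lower = window$mean - window$k_select * window$sd,
    upper = window$mean + window$k_select * window$sd)
}

#' Pre-filter candidates on static 13C RMSD
#'
#' Candidates whose static RMSD is strictly larger than
#' `mean + k_prefilter * sd` of the benchmark window are excluded from the
#' expensive MD stage ("larger than": boundary equality keeps the
#' candidate).
#'
#' @param scores data.frame with columns `structure_id` and `rmsd` (static
#'   RMSD of the window's element, ppm).
#' @param window A [benchmark_window()] (13C by default).
#' @return List with `kept` and `excluded` structure-id vectors, the
#'   `threshold` used, and the input `scores` with a `prefiltered` flag.
#' @export
prefilter <- function(scores, window = benchmark_window("C")) {
  if (any(is.na(scores$rmsd))) {
    stop("missing static RMSD for: ",
         paste(scores$structure_id[is.na(scores$rmsd)], collapse = ", "))
  }
  thr <- prefilter_threshold(window)
  excluded <- scores$rmsd > thr
  scores$prefiltered <- excluded
  list(kept = scores$structure_id[!excluded],
       excluded = scores$structure_id[excluded],
       threshold = thr, scores = scores)
}

#' Shortlist candidates inside a benchmark window
#'
#' A candidate is shortlisted when its RMSD lies within `k_select` sd of
#' the window mean, i.e. in `[mean - k sd, mean + k sd]` (inclusive).
#'
#' @param scores data.frame with `structure_id` and `rmsd` (ppm; NA rows
#'   are never shortlisted).
#' @param window A [benchmark_window()].
#' @return The scores with a logical `shortlisted` column.
#' @export
shortlist <- function(scores, window) {
  b <- select_bounds(window)
  scores$shortlisted <- !is.na(scores$rmsd) &
    scores$rmsd >= b[["lower"]] & scores$rmsd <= b[["upper"]]
  scores
}

#' Consensus ranking across approaches and elements
#'
#' Orders candidates by how often they fall inside the benchmark windows
#' across all requested (approach, element) combinations, breaking ties by
#' mean 1H RMSD, then mean 13C RMSD, then structure id. The ordering is
#' total and deterministic under row shuffling.
#'
#' @param scores data.frame with columns `structure_id`, `approach`,
#'   `element`, `rmsd`, `shortlisted` (one row per candidate x approach x
#'   element; see [shortlist()]).
#' @return data.frame with one row per candidate: membership count, mean
#'   RMSDs and `rank`.
#' @export
consensus_rank <- function(scores) {
  stopifnot(all(c("structure_id", "element", "rmsd", "shortlisted") %in% names(scores)))
  ids <- sort(unique(scores$structure_id))
  agg <- do.call(rbind, lapply(ids, function(id) {
    s <- scores[scores$structure_id == id, , drop = FALSE]
    data.frame(
      structure_id = id,
      n_shortlisted = sum(s$shortlisted, na.rm = TRUE),
      mean_rmsd_1H = mean(s$rmsd[s$element == "H"], na.rm = TRUE),
      mean_rmsd_13C = mean(s$rmsd[s$element == "C"], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  key_h <- ifelse(is.finite(agg$mean_rmsd_1H), agg$mean_rmsd_1H, Inf)
  key_c <- ifelse(is.finite(agg$mean_rmsd_13C), agg$mean_rmsd_13C, Inf)
  ord <- order(-agg$n_shortlisted, key_h, key_c, agg$structure_id)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Lattice-energy landscape summary
#'
#' Relative energies are calibrated so the lowest-energy candidate sits at
#' zero; candidates are ranked by ascending energy.
#'
#' @param records data.frame with `structure_id`, `energy` (kJ/mol per
#'   molecule) and optionally `density` (g/cm^3).
#' @return The records with `energy_rel` and `rank` columns, ordered by
#'   rank.
#' @export
energy_landscape <- function(records) {
  stopifnot(nrow(records) >= 1, all(c("structure_id", "energy") %in% names(records)))
  records$energy_rel <- records$energy - min(records$energy)
  records <- records[order(records$energy, records$structure_id), , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' @rdname energy_landscape
#' @param landscape An [energy_landscape()] result.
#' @param i,j Structure ids (or ranks if numeric) to take the gap between.
#' @return Energy gap in kJ/mol.
#' @export
energy_gap <- function(landscape, i = 1, j = 2) {
  pick <- function(k) {
    if (is.numeric(k)) landscape$energy[landscape$rank == k]
    else landscape$energy[landscape$structure_id == k]
  }
  abs(pick(j) - pick(i))
}

#' Energy RMSD between a force field and a reference method
#'
#' Lattice-energy zeros differ between methods, so both sets are
#' mean-centred (the optimal constant offset is removed) before the RMSD
#' is taken; the raw-difference RMSD is reported alongside for
#' transparency.
#'
#' @param ff,ref data.frames with `structure_id` and `energy` over the same
#'   candidate set.
#' @return List with `rmsd` (offset-corrected, kJ/mol), `rmsd_raw`, and
#'   `n`.
#' @export
energy_rmsd_vs_reference <- function(ff, ref) {
  if (!setequal(ff$structure_id, ref$structure_id)) {
    stop("energy record sets cover different candidates")
  }
  m <- merge(ff, ref, by = "structure_id", suffixes = c("_ff", "_ref"))
  d <- m$energy_ff - m$energy_ref
  list(rmsd = sqrt(mean((d - mean(d))^2)),
       rmsd_raw = sqrt(mean(d^2)),
       n = nrow(m))
}

#' @rdname energy_rmsd_vs_reference
#' @param rmsd_a,rmsd_b Two energy RMSD values to compare.
#' @return Ratio of the larger to the smaller RMSD.
#' @export
energy_rmsd_ratio <- function(rmsd_a, rmsd_b) {
  max(rmsd_a, rmsd_b) / min(rmsd_a, rmsd_b)
}
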