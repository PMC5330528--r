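# Shielding tables are plain data.frames with columns
#   structure_id, frame (NA for static), molecule (copy index), label,
#   element, sigma (ppm)
# and shift tables replace `sigma` by `delta`. Experimental assignments
# carry label, element, delta_exp (ppm).

#' Construct a shielding table
#'
#' @param structure_id Structure identifier.
#' @param label,element,sigma Per-nucleus label, element symbol and
#'   isotropic shielding in ppm.
#' @param frame Frame index (NA for a static structure).
#' @param molecule Molecule copy index within the frame.
#' @return data.frame with the shielding-table columns.
#' @export
shielding_table <- function(structure_id, label, element, sigma,
                            frame = NA_integer_, molecule = 1L) {
  if (length(element) == 1) element <- rep(element, length(label))
  stopifnot(length(label) == length(element), length(label) == length(sigma))
  data.frame(structure_id = structure_id, frame = frame, molecule = molecule,
             label = as.character(label), element = as.character(element),
             sigma = as.numeric(sigma), stringsAsFactors = FALSE)
}

#' Read/write shielding tables as TSV
#'
#' Columns: `structure_id, frame, molecule, label, element, sigma_ppm`.
#' Empty `frame` means a static calculation.
#'
#' @param path File path.
#' @return data.frame in the package's shielding-table layout.
#' @export
read_shieldings_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("structure_id", "frame", "molecule", "label", "element", "sigma_ppm")
  if (!all(req %in% names(d))) {
    stop("shielding TSV must have columns: ", paste(req, collapse = ", "))
  }
  shielding_table(d$structure_id, d$label, d$element, d$sigma_ppm,
                  frame = suppressWarnings(as.integer(d$frame)),
                  molecule = as.integer(d$molecule))
}

#' @rdname read_shieldings_tsv
#' @param table Shielding table to write.
#' @export
write_shieldings_tsv <- function(table, path) {
  out <- data.frame(structure_id = table$structure_id, frame = table$frame,
                    molecule = table$molecule, label = table$label,
                    element = table$element, sigma_ppm = table$sigma)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-nucleus isotropic shieldings from a magres file
#'
#' Parses the `[atoms]` block for labels/elements and the `ms` lines of the
#' `[magres]` block; the isotropic shielding is the trace/3 of each
#' 3x3 shielding tensor. Atom identity is `label` + index, e.g. `C1`.
#'
#' @param path Path to a magres (v1) file.
#' @param structure_id Identifier to stamp on the table.
#' @return A shielding table data.frame.
#' @export
read_magres <- function(path, structure_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  block <- ""
  atoms <- list()
  ms <- list()
  for (line in lines) {
    t <- trimws(line)
    if (grepl("^\\[/", t)) { block <- ""; next }
    if (grepl("^\\[", t)) { block <- gsub("\\[|\\]", "", t); next }
    toks <- strsplit(t, "[[:space:]]+")[[1]]
    if (block == "atoms" && length(toks) >= 7 && toks[1] == "atom") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        element = toks[2], label = paste0(toks[3], toks[4]),
        stringsAsFactors = FALSE)
    }
    if (block == "magres" && length(toks) >= 12 && toks[1] == "ms") {
      tens <- as.numeric(toks[4:12])
      ms[[length(ms) + 1L]] <- data.frame(
        label = paste0(toks[2], toks[3]),
        sigma = (tens[1] + tens[5] + tens[9]) / 3, stringsAsFactors = FALSE)
    }
  }
  if (length(ms) == 0) stop("no ms entries found in magres file: ", path)
  atoms <- do.call(rbind, atoms)
  ms <- do.call(rbind, ms)
  m <- merge(atoms, ms, by = "label", sort = FALSE)
  shielding_table(structure_id, m$label, m$element, m$sigma)
}

#' Read an experimental shift assignment from TSV
#'
#' Columns: `label, element, delta_exp_ppm`.
#'
#' @param path File path.
#' @return data.frame with columns `label, element, delta_exp`.
#' @export
read_assignment_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("label", "element", "delta_exp_ppm")
  if (!all(req %in% names(d))) {
    stop("assignment TSV must have columns: ", paste(req, collapse = ", "))
  }
  data.frame(label = as.character(d$label), element = as.character(d$element),
             delta_exp = as.numeric(d$delta_exp_ppm), stringsAsFactors = FALSE)
}

#' @rdname read_assignment_tsv
#' @param assignment Assignment data.frame to write.
#' @export
write_assignment_tsv <- function(assignment, path) {
  out <- data.frame(label = assignment$label, element = assignment$element,
                    delta_exp_ppm = assignment$delta_exp)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference shielding by slope-constrained regression
#'
#' Fits delta = sigma_ref - sigma with the slope constrained to unity,
#' pooling every matched nucleus of one element across the supplied
#' tables (typically all candidates scored under one computational
#' approach). The least-squares solution with the slope fixed is the
#' closed form `sigma_ref = mean(sigma_calc + delta_exp)`, which leaves
#' residuals with exactly zero mean.
#'
#' @param shieldings A shielding table (or list of tables, pooled).
#' @param assignment Assignment data.frame (`label, element, delta_exp`).
#' @param element Element to fit, `"H"` or `"C"`.
#' @return List of class `"reference_shielding"`: `sigma_ref` (ppm),
#'   `element`, `n_points` and `residual_rms` (ppm).
#' @export
compute_sigma_ref <- function(shieldings, assignment, element) {
  if (is.data.frame(shieldings)) shieldings <- list(shieldings)
  pool <- do.call(rbind, shieldings)
  pool <- pool[pool$element == element, , drop = FALSE]
  asg <- assignment[assignment$element == element, , drop = FALSE]
  pool$.base <- base_label(pool$label)
  m <- merge(pool, asg[, c("label", "delta_exp")], by.x = ".base", by.y = "label")
  if (nrow(m) == 0) stop("no matched ", element, " nuclei between shieldings and assignment")
  sigma_ref <- mean(m$sigma + m$delta_exp)
  resid <- (sigma_ref - m$sigma) - m$delta_exp
  structure(list(sigma_ref = sigma_ref, element = element,
                 n_points = nrow(m), residual_rms = sqrt(mean(resid^2))),
            class = "reference_shielding")
}

#' @export
print.reference_shielding <- function(x, ...) {
  cat(sprintf("<sigma_ref> %s: %.4f ppm (n = %d, residual rms = %.4f ppm)\n",
              x$element, x$sigma_ref, x$n_points, x$residual_rms))
  invisible(x)
}

#' Convert shieldings to chemical shifts
#'
#' Applies `delta_calc = sigma_ref - sigma_calc` element-wise.
#'
#' @param table Shielding table.
#' @param refs A single [compute_sigma_ref()] result, a list of them, or a
#'   named numeric vector of per-element reference shieldings in ppm.
#' @return The table with a `delta` column replacing `sigma`.
#' @export
shieldings_to_shifts <- function(table, refs) {
  ref_vec <- as_ref_vector(refs)
  missing_el <- setdiff(unique(table$element[table$element %in% c("H", "C")]),
                        names(ref_vec))
  if (length(missing_el)) {
    stop("no reference shielding for element(s): ", paste(missing_el, collapse = ", "))
  }
  out <- table
  out$delta <- unname(ref_vec[out$element]) - out$sigma
  out$sigma <- NULL
  out
}

as_ref_vector <- function(refs) {
  if (inherits(refs, "reference_shielding")) refs <- list(refs)
  if (is.list(refs)) {
    v <- vapply(refs, function(r) r$sigma_ref, 1)
    names(v) <- vapply(refs, function(r) r$element, "")
    return(v)
  }
  if (is.numeric(refs) && !is.null(names(refs))) return(refs)
  stop("refs must be reference_shielding object(s) or a named numeric vector")
}

#' Average methyl-proton values
#'
#' Methyl protons exchange fast on the NMR timescale, so each methyl
#' group's three hydrogen values are replaced by their arithmetic mean
#' (idempotent, mean-conserving). Works on shielding (`sigma`) or shift
#' (`delta`) tables; all other records are untouched. Labels are matched
#' per molecule copy via the table's `molecule` column against the
#' topology's asymmetric-unit labels.
#'
#' @param table Shielding or shift table.
#' @param topology A [perceive_bonds()] result for the structure.
#' @return The table with methyl hydrogens averaged.
#' @export
average_methyl_protons <- function(table, topology) {
  col <- if ("delta" %in% names(table)) "delta" else "sigma"
  out <- table
  key <- paste(out$structure_id, out$frame, out$molecule)
  for (grp in unique(key)) {
    rows <- which(key == grp)
    for (me in topology$methyl_groups) {
      hb <- base_label(me$hydrogens)
      sel <- rows[base_label(out$label[rows]) %in% hb & out$element[rows] == "H"]
      if (length(sel) == 0) next
      if (length(sel) != 3) {
        stop("methyl group on ", me$carbon, " is incomplete in the table; found ",
             length(sel), " of 3 hydrogens (", paste(hb, collapse = ", "), ")")
      }
      out[[col]][sel] <- mean(out[[col]][sel])
    }
  }
  out
}

#' Frame-selection plan for motional averaging
#'
#' Given Z (molecules per cell) and the small-cell replication, selects how
#' many trajectory frames to average so that every candidate contributes
#' the same number of molecular spectra (48): `n_frames = 48 / molecules
#' per frame`, evenly spread over a 96 ps window of the 100 ps production
#' run (`interval = 96 / n_frames` ps). This reproduces the canonical
#' ladder 24 frames x 4 ps (Z = 2), 12 x 8 ps (Z = 4) and 6 x 16 ps for a
#' Z = 1 cell replicated 2x2x2.
#'
#' @param z_value Molecules per unit cell of the candidate.
#' @param replication Small-cell replication triple (default no
#'   replication).
#' @param n_spectra Total molecular spectra per candidate (default 48).
#' @param production_ps Production-run length bounding the plan.
#' @return List of class `"frame_plan"`: `z_value`, `replication`,
#'   `n_frames`, `interval_ps`, `molecules_per_frame`, `n_spectra`.
#' @export
plan_frames <- function(z_value, replication = c(1, 1, 1), n_spectra = 48,
                        production_ps = 100) {
  z_value <- as.integer(z_value)
  replication <- as.integer(replication)
  n_spectra <- as.integer(n_spectra)
  stopifnot(z_value >= 1, length(replication) == 3, all(replication >= 1))
  mpf <- as.integer(z_value * prod(replication))
  if (n_spectra %% mpf != 0) {
    stop("molecules per frame (", mpf, ") does not divide ", n_spectra, " spectra")
  }
  n_frames <- n_spectra %/% mpf
  interval <- (n_spectra * 2) / n_frames  # 96 ps window for the default 48
  if (n_frames * interval > production_ps) {
    stop("frame plan exceeds the ", production_ps, " ps production run")
  }
  structure(list(z_value = z_value, replication = replication,
                 n_frames = n_frames, interval_ps = interval,
                 molecules_per_frame = mpf, n_spectra = n_spectra),
            class = "frame_plan")
}

#' @export
print.frame_plan <- function(x, ...) {
  cat(sprintf("<frame_plan> Z = %d, replication %s: %d frames x %d molecules every %g ps (%d spectra)\n",
              x$z_value, paste(x$replication, collapse = "x"), x$n_frames,
              x$molecules_per_frame, x$interval_ps, x$n_spectra))
  invisible(x)
}

#' Ensemble (motional) average of per-frame shieldings
#'
#' Averages sigma over all frames and symmetry-equivalent molecule copies,
#' mapping each copy's nuclei onto asymmetric-unit labels. By default the
#' copy suffix convention of this package is stripped
#' ([base_label] semantics); an explicit `molecule_map` (named vector
#' copy-label -> asymmetric-unit label) overrides.
#'
#' @param tables Shielding table (rows for every frame and molecule copy)
#'   or list of such tables.
#' @param molecule_map Optional named character vector mapping table labels
#'   to asymmetric-unit labels.
#' @return A static shielding table (one row per asymmetric-unit nucleus)
#'   with an `n_obs` column; every nucleus must be observed frames x
#'   copies times, else an error identifies the gap.
#' @export
ensemble_average <- function(tables, molecule_map = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  pool <- do.call(rbind, tables)
  asu <- if (is.null(molecule_map)) base_label(pool$label) else {
    mapped <- unname(molecule_map[pool$label])
    ifelse(is.na(mapped), pool$label, mapped)
  }
  expected <- length(unique(pool$frame)) * length(unique(pool$molecule))
  agg <- stats::aggregate(pool$sigma, by = list(label = asu, element = pool$element),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  n_obs <- agg$x[, "n"]
  if (any(n_obs != expected)) {
    bad <- agg$label[n_obs != expected]
    stop("ragged ensemble: nucleus ", paste(bad, collapse = ", "),
         " observed ", paste(unique(n_obs[n_obs != expected]), collapse = "/"),
         " times, expected ", expected, " (frames x molecule copies)")
  }
  out <- shielding_table(pool$structure_id[1], agg$label, agg$element,
                         agg$x[, "mean"])
  out$n_obs <- as.integer(n_obs)
  # keep the original asymmetric-unit ordering where possible
  ord <- match(out$label, unique(asu))
  out[order(ord), , drop = FALSE]
}

#' RMSD between calculated and experimental shifts
#'
#' @param calc Shift table (with `delta`).
#' @param assignment Assignment data.frame (`label, element, delta_exp`).
#' @param element `"H"` or `"C"`.
#' @return List with `rmsd` (ppm) and `n` (matched nuclei).
#' @export
rmsd_shifts <- function(calc, assignment, element) {
  cc <- calc[calc$element == element, , drop = FALSE]
  aa <- assignment[assignment$element == element, , drop = FALSE]
  cc$.base <- base_label(cc$label)
  m <- merge(cc, aa[, c("label", "delta_exp")], by.x = ".base", by.y = "label")
  if (nrow(m) == 0) stop("no matched ", element, " nuclei for RMSD")
  list(rmsd = sqrt(mean((m$delta - m$delta_exp)^2)), n = nrow(m))
}
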