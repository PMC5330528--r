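# Minimal CIF reader/writer covering the structural subset this package
# exchanges: cell parameters, an optional symmetry-operator loop, and the
# atom_site loop (label, type_symbol, fractional coordinates, occupancy).
# Multi-block files are supported; values may be quoted with ' or ".

#' Read crystal structures from a CIF document
#'
#' @param path Path to a CIF file, or a character vector of lines via
#'   `text`.
#' @param text Optional character scalar/vector holding the document
#'   directly.
#' @return A list of [crystal()] objects, one per `data_` block, named by
#'   block name. Symmetry operators are taken from the
#'   `_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz` loop
#'   when present, else identity.
#' @export
read_cif <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply path or text")
    text <- readLines(path, warn = FALSE)
  }
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  starts <- grep("^data_", lines)
  if (length(starts) == 0) stop("no data_ block found in CIF input")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    name <- sub("^data_", "", lines[starts[b]])
    block <- lines[seq(starts[b] + 1L, ends[b])]
    out[[name]] <- parse_cif_block(block, name)
  }
  out
}

cif_tokens <- function(line) {
  # split on whitespace, honouring '...' and "..." quoting
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)
  toks <- regmatches(line, m)[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_cif_block <- function(block, name) {
  kv <- list()
  loops <- list()
  i <- 1L
  n <- length(block)
  while (i <= n) {
    line <- block[i]
    if (!nzchar(line)) { i <- i + 1L; next }
    if (identical(tolower(line), "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", block[i])) {
        tags <- c(tags, tolower(cif_tokens(block[i])[1]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && nzchar(block[i]) && !grepl("^(_|loop_|data_)", block[i],
                                                  ignore.case = TRUE)) {
        toks <- cif_tokens(block[i])
        if (length(toks) == length(tags)) rows[[length(rows) + 1L]] <- toks
        i <- i + 1L
      }
      if (length(rows)) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- tags
        loops[[length(loops) + 1L]] <- tab
      }
    } else if (grepl("^_", line)) {
      toks <- cif_tokens(line)
      if (length(toks) >= 2) kv[[tolower(toks[1])]] <- toks[2]
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }

  num <- function(tag) {
    v <- kv[[tag]]
    if (is.null(v)) return(NA_real_)
    as.numeric(sub("\\(.*\\)", "", v))  # strip su parentheses
  }
  cellpar <- c(num("_cell_length_a"), num("_cell_length_b"), num("_cell_length_c"),
               num("_cell_angle_alpha"), num("_cell_angle_beta"), num("_cell_angle_gamma"))
  if (any(is.na(cellpar))) {
    stop("CIF block '", name, "' is missing cell parameters")
  }

  atom_loop <- NULL
  sym_loop <- NULL
  for (tab in loops) {
    if (any(grepl("^_atom_site_fract_x$", names(tab)))) atom_loop <- tab
    if (any(names(tab) %in% c("_symmetry_equiv_pos_as_xyz",
                              "_space_group_symop_operation_xyz"))) sym_loop <- tab
  }
  if (is.null(atom_loop)) stop("CIF block '", name, "' has no atom_site loop")

  getcol <- function(tab, tag) if (tag %in% names(tab)) tab[[tag]] else NULL
  label <- getcol(atom_loop, "_atom_site_label")
  element <- getcol(atom_loop, "_atom_site_type_symbol")
  if (is.null(element) && !is.null(label)) element <- gsub("[^A-Za-z].*$", "", label)
  if (is.null(label)) label <- make.unique(element, sep = "")
  occ <- getcol(atom_loop, "_atom_site_occupancy")
  strip <- function(v) as.numeric(sub("\\(.*\\)", "", v))
  sites <- data.frame(
    label = label,
    element = element,
    fx = strip(atom_loop[["_atom_site_fract_x"]]),
    fy = strip(atom_loop[["_atom_site_fract_y"]]),
    fz = strip(atom_loop[["_atom_site_fract_z"]]),
    occ = if (is.null(occ)) 1 else strip(occ),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites$label)) {
    stop("CIF block '", name, "' has duplicate atom labels")
  }
  symmetry <- "x,y,z"
  if (!is.null(sym_loop)) {
    col <- intersect(c("_symmetry_equiv_pos_as_xyz",
                       "_space_group_symop_operation_xyz"), names(sym_loop))[1]
    symmetry <- sym_loop[[col]]
  }
  zv <- num("_cell_formula_units_z")
  crystal(cellpar, sites, symmetry = symmetry,
          z_value = if (is.na(zv)) NA_integer_ else as.integer(zv), name = name)
}

#' Write crystals to a CIF document
#'
#' @param crystals A [crystal()] or list of them; each becomes one
#'   `data_` block named after the structure.
#' @param path Output file; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return The character vector of CIF lines, invisibly.
#' @export
write_cif <- function(crystals, path = NULL) {
  if (inherits(crystals, "crystal")) crystals <- list(crystals)
  lines <- character()
  for (x in crystals) {
    stopifnot(inherits(x, "crystal"))
    lines <- c(lines,
      paste0("data_", gsub("[[:space:]]", "_", x$name)),
      sprintf("_cell_length_a    %.6f", x$cell[["a"]]),
      sprintf("_cell_length_b    %.6f", x$cell[["b"]]),
      sprintf("_cell_length_c    %.6f", x$cell[["c"]]),
      sprintf("_cell_angle_alpha %.6f", x$cell[["alpha"]]),
      sprintf("_cell_angle_beta  %.6f", x$cell[["beta"]]),
      sprintf("_cell_angle_gamma %.6f", x$cell[["gamma"]])
    )
    if (!is.na(x$z_value)) {
      lines <- c(lines, sprintf("_cell_formula_units_Z %d", x$z_value))
    }
    lines <- c(lines, "loop_", "_symmetry_equiv_pos_as_xyz",
               paste0("'", x$symmetry, "'"))
    lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "_atom_site_occupancy",
               sprintf("%s %s %.8f %.8f %.8f %.4f", x$sites$label,
                       x$sites$element, x$sites$fx, x$sites$fy, x$sites$fz,
                       x$sites$occ),
               "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
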