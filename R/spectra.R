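#' Backbone amide assignment table
#'
#' An assignment table holds the reference (apo) amide \eqn{^1}H and
#' \eqn{^{15}}N chemical shifts for every observable backbone NH of the
#' protein -- the HSQC "fingerprint". Prolines and unassigned residues are
#' simply absent. Side-chain NH resonances that are analysed alongside the
#' backbone (for example a glutamine NE2 proton) are carried as additional
#' rows with their own synthetic residue index and an explicit label such
#' as `"Q69sc"`.
#'
#' @param residue integer vector of residue indices (unique, increasing).
#' @param code one-letter amino-acid codes, same length as `residue`.
#' @param w_H,w_N apo \eqn{^1}H and \eqn{^{15}}N chemical shifts (ppm).
#' @param label peak labels; defaults to `paste0(code, residue)`.
#' @param name text identifier for the table.
#' @return An `assignment_table`: a data frame with columns `residue`,
#'   `code`, `label`, `w_H`, `w_N` and attribute `name`.
#' @export
assignment_table <- function(residue, code, w_H, w_N,
                             label = paste0(code, residue),
                             name = "assignments") {
  residue <- as.integer(residue)
  if (anyNA(residue) || any(residue <= 0L)) {
    stop("residue indices must be positive integers", call. = FALSE)
  }
  if (is.unsorted(residue, strictly = TRUE)) {
    stop("residue indices must be unique and strictly increasing", call. = FALSE)
  }
  stopifnot(length(code) == length(residue),
            length(w_H) == length(residue),
            length(w_N) == length(residue),
            length(label) == length(residue))
  if (anyDuplicated(label)) {
    stop("assignment labels must be unique", call. = FALSE)
  }
  out <- data.frame(residue = residue, code = as.character(code),
                    label = as.character(label),
                    w_H = as.numeric(w_H), w_N = as.numeric(w_N),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' @export
print.assignment_table <- function(x, ...) {
  cat(sprintf("<assignment_table '%s'> %d NH resonances\n",
              attr(x, "name"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Discrete peak list for one HSQC sample
#'
#' @param peaks data frame with columns `label` (character, `NA` allowed),
#'   `w_H`, `w_N` (ppm) and `height` (arbitrary intensity units).
#' @param sample_id non-empty sample identifier.
#' @param conditions named numeric vector of additive total concentrations
#'   in mM (ligands, probes); may be empty.
#' @param protein_conc total protein concentration in uM.
#' @return A `peak_list` object.
#' @export
peak_list <- function(peaks, sample_id, conditions = numeric(0),
                      protein_conc = NA_real_) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(label = character(0), w_H = numeric(0),
                        w_N = numeric(0), height = numeric(0),
                        stringsAsFactors = FALSE)
  }
  need <- c("label", "w_H", "w_N", "height")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns label, w_H, w_N, height", call. = FALSE)
  }
  peaks <- as.data.frame(peaks)[need]
  peaks$label <- as.character(peaks$label)
  if (!all(is.finite(peaks$height))) {
    stop("peak heights must be finite", call. = FALSE)
  }
  lab <- peaks$label[!is.na(peaks$label)]
  if (anyDuplicated(lab)) stop("duplicate peak labels", call. = FALSE)
  if (length(conditions) && (is.null(names(conditions)) || any(conditions < 0))) {
    stop("conditions must be a named vector of non-negative mM totals",
         call. = FALSE)
  }
  structure(list(peaks = peaks, sample_id = sample_id,
                 conditions = conditions, protein_conc = protein_conc),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cond <- if (length(x$conditions)) {
    paste(sprintf("%s=%g mM", names(x$conditions), x$conditions),
          collapse = ", ")
  } else "none"
  cat(sprintf("<peak_list '%s'> %d peaks | protein %g uM | additives: %s\n",
              x$sample_id, nrow(x$peaks), x$protein_conc, cond))
  invisible(x)
}

#' Read a Sparky-style peak list
#'
#' Parses whitespace-delimited records `label w1 w2 [height]` where `w1` is
#' the \eqn{^{15}}N shift and `w2` the \eqn{^1}H shift (the usual column
#' order of amide-fingerprint exports). A header line mentioning
#' "Assignment" or "w1" is skipped. Labels of the form `I53N-H` are reduced
#' to the residue part (`I53`); the placeholder `?` denotes an unassigned
#' peak.
#'
#' @param path file to read.
#' @param sample_id sample identifier for the returned list; defaults to
#'   the file name without extension.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lab <- character(0); wN <- numeric(0); wH <- numeric(0); ht <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (grepl("Assignment|\\bw1\\b", ln, ignore.case = TRUE)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3L || length(tok) > 4L) {
      stop(sprintf("malformed peak-list line %d: '%s'", i, ln), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("malformed peak-list line %d: non-numeric field", i),
           call. = FALSE)
    }
    lab <- c(lab, tok[[1L]])
    wN <- c(wN, vals[[1L]])
    wH <- c(wH, vals[[2L]])
    ht <- c(ht, if (length(vals) >= 3L) vals[[3L]] else 1)
  }
  label <- sub("N-HN?$", "", lab)
  label[label %in% c("?", "?-?", "")] <- NA_character_
  if (anyDuplicated(label[!is.na(label)])) {
    stop("duplicate labels in peak list: ", path, call. = FALSE)
  }
  peak_list(data.frame(label = label, w_H = wH, w_N = wN, height = ht,
                       stringsAsFactors = FALSE),
            sample_id = sample_id)
}

#' Write a Sparky-style peak list
#'
#' Inverse of [read_peak_list()]: columns `Assignment w1(15N) w2(1H)
#' Height`, shifts printed to 4 decimals. Unlabeled peaks are written with
#' the `?` placeholder.
#'
#' @param pl a [peak_list()].
#' @param path destination file.
#' @return `invisible(path)`.
#' @export
write_peak_list <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  p <- pl$peaks
  lab <- ifelse(is.na(p$label), "?", paste0(p$label, "N-H"))
  body <- sprintf("%15s %10.4f %10.4f %15.6e", lab, p$w_N, p$w_H, p$height)
  out <- c(sprintf("%15s %10s %10s %15s", "Assignment", "w1", "w2", "Height"),
           body)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write peak list to ", path, call. = FALSE)
  invisible(path)
}

axis_spec <- function(ax) {
  ax <- as.numeric(ax)
  if (length(ax) != 3L || !all(is.finite(ax)) || ax[[1L]] >= ax[[2L]] ||
      ax[[3L]] < 2) {
    stop("axis spec must be c(min, max, n) with min < max and n >= 2",
         call. = FALSE)
  }
  ax[[3L]] <- as.integer(round(ax[[3L]]))
  ax
}

axis_points <- function(ax) seq(ax[[1L]], ax[[2L]], length.out = ax[[3L]])

#' Gridded 2D spectrum
#'
#' @param grid numeric matrix of intensities with `axis_N[3]` rows
#'   (ascending \eqn{^{15}}N ppm) and `axis_H[3]` columns (ascending
#'   \eqn{^1}H ppm).
#' @param axis_H,axis_N axis specs `c(min_ppm, max_ppm, n_points)`.
#' @param sample_id sample identifier.
#' @param conditions named numeric vector as in [peak_list()].
#' @return A `spectrum2d` object.
#' @export
spectrum2d <- function(grid, axis_H, axis_N, sample_id,
                       conditions = numeric(0)) {
  axis_H <- axis_spec(axis_H); axis_N <- axis_spec(axis_N)
  grid <- as.matrix(grid)
  if (nrow(grid) != axis_N[[3L]] || ncol(grid) != axis_H[[3L]]) {
    stop("grid dimensions must match axis point counts", call. = FALSE)
  }
  structure(list(grid = grid, axis_H = axis_H, axis_N = axis_N,
                 sample_id = sample_id, conditions = conditions),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf(
    "<spectrum2d '%s'> 1H %g-%g ppm x %d | 15N %g-%g ppm x %d | max %0.3g\n",
    x$sample_id, x$axis_H[1], x$axis_H[2], x$axis_H[3],
    x$axis_N[1], x$axis_N[2], x$axis_N[3],
    if (length(x$grid)) max(abs(x$grid)) else 0))
  invisible(x)
}

#' Render a peak list onto a 2D grid
#'
#' Each peak contributes a separable 2D Gaussian centred at its position
#' and scaled by its height; contributions from all peaks sum. `linewidth`
#' parameters are the Gaussian standard deviations per axis, so a peak
#' sitting exactly on a grid node attains its nominal height there. Peaks
#' outside the window contribute whatever tail reaches the grid.
#'
#' @param pl a [peak_list()].
#' @param axis_H,axis_N axis specs `c(min, max, n)`; defaults cover the
#'   amide region.
#' @param linewidth_H,linewidth_N Gaussian widths (ppm), > 0.
#' @return A [spectrum2d()].
#' @export
render_spectrum <- function(pl, axis_H = c(6, 11, 512),
                            axis_N = c(100, 135, 256),
                            linewidth_H = 0.02, linewidth_N = 0.15) {
  stopifnot(inherits(pl, "peak_list"))
  if (!is.finite(linewidth_H) || !is.finite(linewidth_N) ||
      linewidth_H <= 0 || linewidth_N <= 0) {
    stop("linewidths must be positive", call. = FALSE)
  }
  axis_H <- axis_spec(axis_H); axis_N <- axis_spec(axis_N)
  xH <- axis_points(axis_H); xN <- axis_points(axis_N)
  grid <- matrix(0, nrow = axis_N[[3L]], ncol = axis_H[[3L]])
  p <- pl$peaks
  if (nrow(p)) {
    # evaluate each Gaussian only inside +/- 6 sigma to keep rendering cheap
    for (i in seq_len(nrow(p))) {
      jH <- which(abs(xH - p$w_H[[i]]) <= 6 * linewidth_H)
      jN <- which(abs(xN - p$w_N[[i]]) <= 6 * linewidth_N)
      if (!length(jH) || !length(jN)) next
      gH <- exp(-0.5 * ((xH[jH] - p$w_H[[i]]) / linewidth_H)^2)
      gN <- exp(-0.5 * ((xN[jN] - p$w_N[[i]]) / linewidth_N)^2)
      grid[jN, jH] <- grid[jN, jH] + p$height[[i]] * (gN %o% gH)
    }
  }
  spectrum2d(grid, axis_H, axis_N, sample_id = pl$sample_id,
             conditions = pl$conditions)
}

#' Difference of two spectra on identical grids
#'
#' Elementwise `a - b`. Axes must match exactly; no resampling is
#' attempted.
#'
#' @param a,b [spectrum2d()] objects on the same axes.
#' @return A [spectrum2d()] whose `sample_id` records both parents.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "spectrum2d"), inherits(b, "spectrum2d"))
  if (!isTRUE(all.equal(a$axis_H, b$axis_H)) ||
      !isTRUE(all.equal(a$axis_N, b$axis_N))) {
    stop("incompatible axes: difference spectra require identical grids",
         call. = FALSE)
  }
  out <- spectrum2d(a$grid - b$grid, a$axis_H, a$axis_N,
                    sample_id = paste0(a$sample_id, " - ", b$sample_id),
                    conditions = a$conditions)
  attr(out, "minuend") <- a$sample_id
  attr(out, "subtrahend") <- b$sample_id
  out
}

#' Write / read a gridded spectrum as a text file pair
#'
#' A `spectrum2d` is stored as `<basename>.json` (axes, sample id,
#' conditions) plus `<basename>.csv` holding the dense intensity matrix,
#' rows = ascending \eqn{^{15}}N points, columns = ascending \eqn{^1}H
#' points, no header.
#'
#' @param spec a [spectrum2d()].
#' @param basename path without extension; both files are derived from it.
#' @return `write_spectrum2d` returns `invisible(basename)`;
#'   `read_spectrum2d` returns the [spectrum2d()].
#' @export
write_spectrum2d <- function(spec, basename) {
  stopifnot(inherits(spec, "spectrum2d"))
  header <- list(sample_id = spec$sample_id,
                 axis_H = spec$axis_H, axis_N = spec$axis_N,
                 conditions = as.list(spec$conditions))
  jsonlite::write_json(header, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(spec$grid, paste0(basename, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(basename)
}

#' @rdname write_spectrum2d
#' @export
read_spectrum2d <- function(basename) {
  header <- jsonlite::read_json(paste0(basename, ".json"),
                                simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(basename, ".csv"), sep = ",",
                                      header = FALSE))
  dimnames(grid) <- NULL
  cond <- unlist(header$conditions)
  if (is.null(cond)) cond <- numeric(0)
  spectrum2d(grid, header$axis_H, header$axis_N,
             sample_id = header$sample_id, conditions = cond)
}
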