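## Primary-screen triage: difference intensity analysis (DIA), PCA
## embedding of spectra, k-means clustering, hit flagging and iterative
## deconvolution planning.

#' Difference intensity analysis statistic
#'
#' Sum of `|intensity|` over all grid nodes whose magnitude exceeds the
#' noise floor -- a scalar summary of how much a sample's spectrum
#' deviates from the reference.
#'
#' @param diff a difference [spectrum2d()].
#' @param noise_floor non-negative intensity cutoff; nodes at or below it
#'   are ignored.
#' @return Non-negative scalar.
#' @export
dia_statistic <- function(diff, noise_floor = 0) {
  stopifnot(inherits(diff, "spectrum2d"))
  if (!is.finite(noise_floor) || noise_floor < 0) {
    stop("noise_floor must be >= 0", call. = FALSE)
  }
  a <- abs(diff$grid)
  sum(a[a > noise_floor])
}

#' Estimate an intensity noise floor from a signal-free region
#'
#' Returns `c_mult` times the standard deviation of the intensities inside
#' the given sub-window. The region must be free of peaks (a corner of the
#' spectrum by convention); a region overlapping signal inflates the
#' estimate.
#'
#' @param spec a [spectrum2d()].
#' @param region list with `H = c(min, max)` and `N = c(min, max)` in ppm;
#'   must lie inside the axes and contain at least 100 grid nodes.
#' @param c_mult multiplier applied to the region standard deviation.
#' @return Intensity threshold.
#' @export
estimate_noise_floor <- function(spec, region, c_mult = 5) {
  stopifnot(inherits(spec, "spectrum2d"))
  xH <- axis_points(spec$axis_H); xN <- axis_points(spec$axis_N)
  if (region$H[[1L]] < spec$axis_H[[1L]] - 1e-9 ||
      region$H[[2L]] > spec$axis_H[[2L]] + 1e-9 ||
      region$N[[1L]] < spec$axis_N[[1L]] - 1e-9 ||
      region$N[[2L]] > spec$axis_N[[2L]] + 1e-9) {
    stop("noise region lies outside the spectrum axes", call. = FALSE)
  }
  jH <- which(xH >= region$H[[1L]] & xH <= region$H[[2L]])
  jN <- which(xN >= region$N[[1L]] & xN <= region$N[[2L]])
  if (length(jH) * length(jN) < 100L) {
    stop("noise region must contain at least 100 grid nodes", call. = FALSE)
  }
  c_mult * stats::sd(as.vector(spec$grid[jN, jH]))
}

#' PCA embedding of a set of spectra
#'
#' Grids are flattened to vectors, mean-centred across samples and
#' projected onto the top right singular vectors. The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' coordinates are reproducible.
#'
#' @param spectra list of [spectrum2d()] on identical axes (>= 2).
#' @param n_components number of components to keep.
#' @return List with `scores` (samples x components matrix, rownames =
#'   sample ids) and `explained_variance` (fraction per component).
#' @export
pca_embed <- function(spectra, n_components = 2L) {
  if (length(spectra) < 2L) stop("need at least 2 spectra", call. = FALSE)
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!isTRUE(all.equal(s$axis_H, ref$axis_H)) ||
        !isTRUE(all.equal(s$axis_N, ref$axis_N))) {
      stop("incompatible axes across spectra", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(spectra, function(s) as.vector(s$grid)))
  X <- sweep(X, 2L, colMeans(X))
  k <- min(n_components, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[[which.max(abs(v))]] < 0) scores[, j] <- -scores[, j]
  }
  tot <- sum(X^2)
  ev <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  rownames(scores) <- vapply(spectra, `[[`, "", "sample_id")
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained_variance = ev)
}

#' K-means clustering of embedded samples
#'
#' Standard k-means (Hartigan-Wong, k-means++-like behaviour through many
#' random restarts with the best inertia kept) under a fixed seed. Labels
#' are renumbered so that cluster 1 contains the reference sample.
#'
#' @param coords numeric matrix of sample coordinates (rows = samples).
#' @param k number of clusters, `1 <= k <= nrow(coords)`.
#' @param seed integer seed.
#' @param reference_index row of the reference sample (defines cluster 1).
#' @param nstart random restarts.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
kmeans_cluster <- function(coords, k = 3L, seed = 1L, reference_index = 1L,
                           nstart = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1L || k > n) stop("k must be between 1 and the sample count",
                            call. = FALSE)
  if (k == 1L) return(rep(1L, n))
  cl <- with_seed(seed, stats::kmeans(coords, centers = k, nstart = nstart,
                                      iter.max = 100L))$cluster
  # renumber: reference cluster first, remaining clusters by first occurrence
  ref_cl <- cl[[reference_index]]
  others <- unique(cl[cl != ref_cl])
  map <- integer(k)
  map[[ref_cl]] <- 1L
  map[others] <- seq_along(others) + 1L
  map[cl]
}

#' Flag screening hits
#'
#' A sample is flagged when it falls outside the reference sample's
#' cluster *and* its DIA value exceeds `dia_mult` times the median DIA of
#' the reference cluster. Both conditions are advisory triage signals, not
#' proof of binding.
#'
#' @param results a `triage_result` data frame (columns `sample_id`,
#'   `dia`, `cluster`, ...).
#' @param reference_id sample id of the reference (DMSO-only) spectrum.
#' @param dia_mult multiplier on the reference-cluster median DIA.
#' @return The data frame with `is_hit` filled in.
#' @export
flag_hits <- function(results, reference_id, dia_mult = 3) {
  i_ref <- match(reference_id, results$sample_id)
  if (is.na(i_ref)) stop("reference sample not present", call. = FALSE)
  ref_cluster <- results$cluster[[i_ref]]
  thr <- dia_mult * stats::median(results$dia[results$cluster == ref_cluster])
  results$is_hit <- results$cluster != ref_cluster & results$dia > thr
  results$is_hit[[i_ref]] <- FALSE
  attr(results, "dia_threshold") <- thr
  results
}

#' Plan the next deconvolution round
#'
#' Every fragment belonging to a flagged plex is carried forward and
#' regrouped into pools of at most `next_size`, filled in manifest order;
#' fragments of unflagged plexes are dropped.
#'
#' @param hit_plexes character vector of flagged plex ids.
#' @param design the current round's [plex_design()].
#' @param next_size pool size of the next round (< current).
#' @param round_label tag for the new round.
#' @return A [plex_design()] for the next round (empty if no hits).
#' @export
deconvolution_plan <- function(hit_plexes, design, next_size,
                               round_label = NULL) {
  stopifnot(inherits(design, "plex_design"))
  if (next_size >= design$plex_size) {
    stop("next_size must be smaller than the current plex size",
         call. = FALSE)
  }
  if (is.null(round_label)) {
    round_label <- if (next_size == 1L) "single" else
      sprintf("%dplex", next_size)
  }
  missing_plex <- setdiff(hit_plexes, names(design$assignments))
  if (length(missing_plex)) {
    stop("unknown plex ids: ", paste(missing_plex, collapse = ", "),
         call. = FALSE)
  }
  keep <- names(design$assignments) %in% hit_plexes
  frags <- unlist(design$assignments[keep], use.names = FALSE)
  out <- plex_design(frags, plex_size = next_size,
                     round_label = round_label)
  # deconvolution lineage: which current-round plex each fragment came from
  out$parent_of_fragment <- stats::setNames(
    rep(names(design$assignments)[keep],
        lengths(design$assignments[keep])), frags)
  out
}
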