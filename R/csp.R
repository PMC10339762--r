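## Chemical shift perturbation analysis: peak tracking across conditions,
## combined 1H/15N CSP, significance thresholds, hotspot listing and
## sub-site classification.

#' Combined 1H/15N chemical shift perturbation
#'
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 +
#'   (w \cdot \Delta\delta_N)^2}}
#' with the community-standard nitrogen weight `w = 0.2` that compensates
#' for the larger \eqn{^{15}}N ppm range.
#'
#' @param d_H,d_N shift changes (ppm); vectorised.
#' @param weight nitrogen scaling factor, > 0.
#' @return Combined CSP magnitude (ppm).
#' @export
combined_csp <- function(d_H, d_N, weight = 0.2) {
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0",
                                              call. = FALSE)
  sqrt(d_H^2 + (weight * d_N)^2)
}

#' Match peaks between two conditions
#'
#' Greedy globally-nearest matching in the scaled shift space
#' \eqn{d = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}}: candidate
#' pairs are accepted in ascending distance until the cutoff `max_jump`
#' is reached, each peak used at most once. Reference peaks left unmatched
#' are reported as lost rather than force-matched.
#'
#' @param reference fully labelled [peak_list()] (the known positions).
#' @param perturbed [peak_list()] to match against (labels ignored).
#' @param max_jump largest scaled displacement accepted (ppm).
#' @param weight nitrogen weight of the scaled space.
#' @return List with `pairs` (data frame: `label`, `ref_idx`, `pert_idx`,
#'   `w_H`, `w_N` of the matched perturbed peak, `d_H`, `d_N`, `dist`)
#'   and `lost` (labels of unmatched reference peaks).
#' @export
track_peaks <- function(reference, perturbed, max_jump = 0.25,
                        weight = 0.2) {
  stopifnot(inherits(reference, "peak_list"), inherits(perturbed, "peak_list"))
  rp <- reference$peaks
  if (anyNA(rp$label)) stop("reference peaks must all be labelled",
                            call. = FALSE)
  if (anyDuplicated(rp$label)) stop("duplicate reference labels",
                                    call. = FALSE)
  pp <- perturbed$peaks
  nr <- nrow(rp); np <- nrow(pp)
  if (nr == 0L || np == 0L) {
    return(list(pairs = data.frame(label = character(0), ref_idx = integer(0),
                                   pert_idx = integer(0), w_H = numeric(0),
                                   w_N = numeric(0), d_H = numeric(0),
                                   d_N = numeric(0), dist = numeric(0)),
                lost = rp$label))
  }
  dH <- outer(rp$w_H, pp$w_H, `-`)
  dN <- outer(rp$w_N, pp$w_N, `-`)
  D <- sqrt(dH^2 + (weight * dN)^2)
  ord <- order(D)
  used_r <- logical(nr); used_p <- logical(np)
  ri <- integer(0); pi <- integer(0)
  for (k in ord) {
    if (D[[k]] > max_jump) break
    i <- (k - 1L) %% nr + 1L
    j <- (k - 1L) %/% nr + 1L
    if (used_r[[i]] || used_p[[j]]) next
    used_r[[i]] <- TRUE; used_p[[j]] <- TRUE
    ri <- c(ri, i); pi <- c(pi, j)
    if (all(used_r) || all(used_p)) break
  }
  o <- order(ri)
  ri <- ri[o]; pi <- pi[o]
  pairs <- data.frame(label = rp$label[ri], ref_idx = ri, pert_idx = pi,
                      w_H = pp$w_H[pi], w_N = pp$w_N[pi],
                      d_H = pp$w_H[pi] - rp$w_H[ri],
                      d_N = pp$w_N[pi] - rp$w_N[ri],
                      dist = D[cbind(ri, pi)],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, lost = rp$label[!used_r])
}

# Follow every labelled peak through a series of peak lists in
# concentration order; returns a list of data frames (label, w_H, w_N),
# one per point, restricted to peaks tracked at every step so far.
chain_track <- function(points, start = NULL, max_jump = 0.25,
                        weight = 0.2) {
  if (is.null(start)) {
    start <- points[[1L]]$peaks[c("label", "w_H", "w_N")]
    from <- 2L
    out <- list(start)
  } else {
    from <- 1L
    out <- list()
  }
  cur <- start
  idx_range <- if (from > length(points)) integer(0) else
    seq(from, length(points))
  for (i in idx_range) {
    ref <- peak_list(data.frame(label = cur$label, w_H = cur$w_H,
                                w_N = cur$w_N, height = 1),
                     sample_id = "chain")
    tr <- track_peaks(ref, points[[i]], max_jump = max_jump,
                      weight = weight)
    cur <- tr$pairs[c("label", "w_H", "w_N")]
    out <- c(out, list(cur))
  }
  # restrict every frame to the labels that survived to the end
  keep <- out[[length(out)]]$label
  lapply(out, function(df) df[match(keep, df$label), , drop = FALSE])
}

new_csp_profile <- function(ligand_id, per_residue, threshold_n_sd = 2) {
  mean_csp <- mean(per_residue$csp)
  sd_csp <- stats::sd(per_residue$csp)
  structure(list(ligand_id = ligand_id, per_residue = per_residue,
                 mean_csp = mean_csp, sd_csp = sd_csp,
                 threshold = mean_csp + threshold_n_sd * sd_csp),
            class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf(
    "<csp_profile '%s'> %d residues | mean %0.4f, sd %0.4f, threshold %0.4f ppm\n",
    x$ligand_id, nrow(x$per_residue), x$mean_csp, x$sd_csp, x$threshold))
  invisible(x)
}

#' Per-residue CSP profile of a titration series
#'
#' Peaks are tracked point-to-point through the series in concentration
#' order; the profile reports each tracked residue's shift change between
#' the apo point and the chosen endpoint, its combined CSP, and the
#' mean + 2 SD significance threshold computed over all tracked residues.
#' Residues lost during tracking are absent, not zero-filled.
#'
#' @param series a `titration_series`.
#' @param endpoint_index index of the endpoint (default: last point).
#' @param max_jump,weight tracking parameters, see [track_peaks()].
#' @return A `csp_profile`: `per_residue` data frame (`label`, `residue`,
#'   `d_H`, `d_N`, `csp`), `mean_csp`, `sd_csp`, `threshold`.
#' @export
csp_profile <- function(series, endpoint_index = NULL, max_jump = 0.25,
                        weight = 0.2) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(endpoint_index)) endpoint_index <- length(series$points)
  if (endpoint_index < 2L || endpoint_index > length(series$points)) {
    stop("endpoint_index must address a non-apo series point", call. = FALSE)
  }
  frames <- chain_track(series$points[seq_len(endpoint_index)],
                        max_jump = max_jump, weight = weight)
  apo <- frames[[1L]]; end <- frames[[length(frames)]]
  if (nrow(end) < 5L) {
    stop("fewer than 5 residues tracked across the series; ",
         "significance threshold would be meaningless", call. = FALSE)
  }
  d_H <- end$w_H - apo$w_H
  d_N <- end$w_N - apo$w_N
  per <- data.frame(label = end$label,
                    residue = suppressWarnings(
                      as.integer(sub("^[A-Za-z]+", "",
                                     sub("sc$", "", end$label)))),
                    d_H = d_H, d_N = d_N,
                    csp = combined_csp(d_H, d_N, weight),
                    stringsAsFactors = FALSE)
  new_csp_profile(series$ligand_id, per)
}

#' Residues with significant CSP
#'
#' @param profile a [csp_profile()].
#' @param n_sd number of standard deviations above the mean (default 2).
#' @return Character vector of residue labels with
#'   `csp > mean + n_sd * sd`.
#' @export
significant_residues <- function(profile, n_sd = 2) {
  if (!is.finite(n_sd) || n_sd < 0) stop("n_sd must be >= 0", call. = FALSE)
  thr <- profile$mean_csp + n_sd * profile$sd_csp
  profile$per_residue$label[profile$per_residue$csp > thr]
}

#' Residues above an absolute CSP cutoff
#'
#' The hotspot rule used for strong probes: every residue whose combined
#' CSP exceeds the absolute cutoff (e.g. 0.6 ppm for the sulfotyrosine
#' titration endpoint).
#'
#' @param profile a [csp_profile()].
#' @param cutoff absolute combined-CSP cutoff (ppm), >= 0.
#' @return Character vector of residue labels.
#' @export
hotspot_by_absolute_threshold <- function(profile, cutoff = 0.6) {
  if (!is.finite(cutoff) || cutoff < 0) stop("cutoff must be >= 0",
                                             call. = FALSE)
  profile$per_residue$label[profile$per_residue$csp > cutoff]
}

#' Cosine similarity of two CSP profiles
#'
#' Computed over the residues present in both profiles (at least 3
#' required); scale-invariant, so ligands with proportional perturbation
#' patterns score 1 regardless of potency.
#'
#' @param a,b [csp_profile()] objects.
#' @return Value in `[-1, 1]`.
#' @export
profile_similarity <- function(a, b) {
  shared <- intersect(a$per_residue$label, b$per_residue$label)
  if (length(shared) < 3L) {
    stop("profiles share fewer than 3 residues; similarity undefined",
         call. = FALSE)
  }
  va <- a$per_residue$csp[match(shared, a$per_residue$label)]
  vb <- b$per_residue$csp[match(shared, b$per_residue$label)]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Assign a fragment to a binding sub-site
#'
#' Membership of the significant residues in the (disjoint) site
#' definitions decides the call: `"both"` when each site holds at least
#' two significant residues, otherwise the site with the majority of
#' significant residues, `"unassigned"` when no significant residue falls
#' in any site.
#'
#' @param profile a [csp_profile()].
#' @param site_definitions named list of disjoint residue-label sets (see
#'   [ccl28_site_definitions()]).
#' @param n_sd significance level passed to [significant_residues()].
#' @return List with `fragment_id`, `site`, `evidence` (significant
#'   residues) and `counts` per site.
#' @export
assign_site <- function(profile, site_definitions = ccl28_site_definitions(),
                        n_sd = 2) {
  if (length(site_definitions) >= 2L) {
    for (i in seq_along(site_definitions)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(site_definitions[[i]], site_definitions[[j]]))) {
          stop("site definitions must be disjoint", call. = FALSE)
        }
      }
    }
  }
  sig <- significant_residues(profile, n_sd)
  counts <- vapply(site_definitions,
                   function(s) length(intersect(sig, s)), 0L)
  site <- if (all(counts == 0L)) {
    "unassigned"
  } else if (sum(counts >= 2L) >= 2L) {
    "both"
  } else {
    names(counts)[[which.max(counts)]]
  }
  list(fragment_id = profile$ligand_id, site = site, evidence = sig,
       counts = counts)
}
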