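## Synthetic screening data: fast-exchange peak movement under single-site
## binding with ligand depletion, pooled samples, titrations, dual-ligand
## schedules, and positional measurement noise.

# Run code with a private, restored RNG state so generators are pure
# functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Fraction of protein bound under single-site binding with ligand depletion
#'
#' Exact solution of the 1:1 binding mass balance
#' \eqn{P + L \rightleftharpoons PL} at total protein `P_T` and total
#' ligand `L_T`:
#' \deqn{f = \frac{b - \sqrt{b^2 - 4 P_T L_T}}{2 P_T}, \quad
#'       b = P_T + L_T + K_d}
#' evaluated in the numerically stable form \eqn{f = 2 L_T / (b +
#' \sqrt{b^2 - 4 P_T L_T})}. The depletion quadratic is exact at any
#' concentration ratio and reduces to \eqn{L_T/(L_T+K_d)} in the dilute
#' protein limit.
#'
#' @param P_T total protein concentration (uM), > 0.
#' @param L_T total ligand concentration (mM), >= 0; vectorised.
#' @param kd dissociation constant (mM), > 0.
#' @return Fraction of protein bound, in `[0, 1]`.
#' @export
fraction_bound <- function(P_T, L_T, kd) {
  if (!all(is.finite(P_T), is.finite(L_T), is.finite(kd))) {
    stop("fraction_bound requires finite inputs", call. = FALSE)
  }
  if (P_T <= 0) stop("P_T must be > 0", call. = FALSE)
  if (any(L_T < 0)) stop("L_T must be >= 0", call. = FALSE)
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  P <- P_T / 1000  # uM -> mM
  b <- P + L_T + kd
  disc <- b^2 - 4 * P * L_T
  2 * L_T / (b + sqrt(pmax(disc, 0)))
}

#' Two-ligand binding equilibria
#'
#' Solves the coupled mass balances for one protein and two ligands by a
#' damped Newton iteration on the free ligand concentrations (relative
#' tolerance `tol`).
#'
#' In `independent_sites` mode the protein carries two non-interacting
#' sites (species P, PA, PB and the ternary PAB with no cooperativity), so
#' the occupancy of each site is \eqn{f_X = [X]_{free}/(K_X +
#' [X]_{free})}. In `competitive` mode both ligands contend for a single
#' shared site (species P, PA, PB only) and \eqn{f_A = ([A]/K_A) / (1 +
#' [A]/K_A + [B]/K_B)}.
#'
#' @param P_T protein (uM); `A_T`, `B_T` ligand totals (mM); `kd_A`,
#'   `kd_B` dissociation constants (mM).
#' @param mode `"independent_sites"` or `"competitive"`.
#' @param tol relative convergence tolerance on the mass balances.
#' @return List with site/state occupancies `f_A`, `f_B`, free ligand
#'   concentrations `A_free`, `B_free` (mM) and the iteration count.
#' @export
solve_dual_occupancy <- function(P_T, A_T, B_T, kd_A, kd_B,
                                 mode = c("independent_sites", "competitive"),
                                 tol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(is.finite(P_T), P_T > 0, is.finite(A_T), A_T >= 0,
            is.finite(B_T), B_T >= 0, kd_A > 0, kd_B > 0)
  P <- P_T / 1000
  occ <- function(a, b) {
    if (mode == "independent_sites") {
      c(a / (kd_A + a), b / (kd_B + b))
    } else {
      d <- 1 + a / kd_A + b / kd_B
      c((a / kd_A) / d, (b / kd_B) / d)
    }
  }
  resid <- function(a, b) {
    f <- occ(a, b)
    c(a + P * f[[1L]] - A_T, b + P * f[[2L]] - B_T)
  }
  a <- A_T; b <- B_T
  scale <- pmax(c(A_T, B_T), kd_A + kd_B)
  it <- 0L
  repeat {
    it <- it + 1L
    r <- resid(a, b)
    if (all(abs(r) <= tol * scale)) break
    if (it > 200L) {
      stop(sprintf(paste0("dual equilibrium solver failed to converge ",
                          "(mode=%s, residual=%.3g/%.3g after %d steps)"),
                   mode, r[[1L]], r[[2L]], it), call. = FALSE)
    }
    h <- 1e-7
    ja <- (resid(a + h * max(a, 1e-6), b) - r) / (h * max(a, 1e-6))
    jb <- (resid(a, b + h * max(b, 1e-6)) - r) / (h * max(b, 1e-6))
    J <- cbind(ja, jb)
    step <- tryCatch(solve(J, r), error = function(e) r / diag(J))
    lam <- 1
    repeat {
      a2 <- a - lam * step[[1L]]; b2 <- b - lam * step[[2L]]
      if (a2 >= 0 && b2 >= 0) break
      lam <- lam / 2
      if (lam < 1e-8) { a2 <- max(a - step[[1L]], 0); b2 <- max(b - step[[2L]], 0); break }
    }
    a <- a2; b <- b2
  }
  f <- occ(a, b)
  list(f_A = f[[1L]], f_B = f[[2L]], A_free = a, B_free = b, iterations = it)
}

frag_field <- function(frag, what) {
  if (is.null(frag[[what]])) stop("fragment record lacks field ", what,
                                  call. = FALSE)
  frag[[what]]
}

#' Create a fragment record
#'
#' A fragment record carries the ground truth used by the simulator: which
#' sub-site the fragment engages, its dissociation constant, and the
#' per-residue maximal fast-exchange shifts `dmax` it would induce at full
#' occupancy.
#'
#' @param fragment_id,library_name identifiers.
#' @param site_label one of `"site1_Nloop_helix"`, `"site2_sY_cleft"`,
#'   `"both"`, `"none"`.
#' @param kd dissociation constant (mM); `NA` for inert fragments.
#' @param dmax `NULL` for inert fragments, otherwise a data frame with
#'   columns `residue`, `d_H`, `d_N` (ppm at full occupancy).
#' @return A `fragment_record` list.
#' @export
fragment_record <- function(fragment_id, library_name = "lib",
                            site_label = "none", kd = NA_real_,
                            dmax = NULL) {
  site_label <- match.arg(site_label,
                          c("site1_Nloop_helix", "site2_sY_cleft",
                            "both", "none"))
  active <- !is.null(dmax) && nrow(dmax) > 0L
  if (site_label != "none" && !active) {
    stop("site-specific fragments need a non-empty dmax table", call. = FALSE)
  }
  if (active) {
    # non-specific perturbers keep site_label "none" but still carry dmax
    if (!is.finite(kd) || kd <= 0) {
      stop("perturbing fragments need kd > 0", call. = FALSE)
    }
    stopifnot(all(c("residue", "d_H", "d_N") %in% names(dmax)))
  }
  structure(list(fragment_id = fragment_id, library_name = library_name,
                 site_label = site_label, kd = kd, dmax = dmax),
            class = "fragment_record")
}

#' Simulate one HSQC sample
#'
#' Under fast exchange every residue's peak sits at the population-weighted
#' average position: apo position plus, for each fragment present, its
#' bound fraction times that fragment's per-residue maximal shift.
#' Fragments engaging distinct sites contribute independently and
#' additively. Gaussian positional noise (per-axis standard deviations
#' `noise_sd`) models peak-picking precision.
#'
#' @param assign an [assignment_table()].
#' @param fragments list of [fragment_record()]s present in the sample.
#' @param conc numeric vector of total concentrations (mM), one per
#'   fragment.
#' @param protein_conc total protein (uM).
#' @param noise_sd length-2 vector `c(H, N)` of positional noise standard
#'   deviations (ppm); `c(0, 0)` for noiseless data.
#' @param seed integer seed; the result is a pure function of the inputs
#'   and this seed.
#' @param sample_id identifier for the returned [peak_list()].
#' @return A [peak_list()] with one peak per assignment entry, labels
#'   preserved.
#' @export
simulate_sample <- function(assign, fragments = list(), conc = numeric(0),
                            protein_conc = 50,
                            noise_sd = c(0.004, 0.02), seed = 1L,
                            sample_id = "sample") {
  stopifnot(inherits(assign, "assignment_table"),
            length(fragments) == length(conc))
  if (any(conc < 0)) stop("fragment concentrations must be >= 0", call. = FALSE)
  noise_sd <- rep_len(as.numeric(noise_sd), 2L)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  wH <- assign$w_H; wN <- assign$w_N
  conditions <- numeric(0)
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    conditions[frag_field(fr, "fragment_id")] <- conc[[i]]
    if (is.null(fr$dmax) || nrow(fr$dmax) == 0L || conc[[i]] == 0) next
    f <- fraction_bound(protein_conc, conc[[i]], fr$kd)
    idx <- match(fr$dmax$residue, assign$residue)
    keep <- !is.na(idx)
    wH[idx[keep]] <- wH[idx[keep]] + f * fr$dmax$d_H[keep]
    wN[idx[keep]] <- wN[idx[keep]] + f * fr$dmax$d_N[keep]
  }
  if (any(noise_sd > 0)) {
    n <- length(wH)
    noise <- with_seed(seed, list(h = stats::rnorm(n, 0, noise_sd[[1L]]),
                                  n = stats::rnorm(n, 0, noise_sd[[2L]])))
    wH <- wH + noise$h
    wN <- wN + noise$n
  }
  peak_list(data.frame(label = assign$label, w_H = wH, w_N = wN,
                       height = rep(1, length(wH)), stringsAsFactors = FALSE),
            sample_id = sample_id, conditions = conditions,
            protein_conc = protein_conc)
}

new_titration_series <- function(protein_conc, ligand_id, ligand_totals,
                                 points, seed) {
  structure(list(protein_conc = protein_conc, ligand_id = ligand_id,
                 ligand_totals = ligand_totals, points = points,
                 seed = seed),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series '%s'> protein %g uM | %d points: %s mM\n",
              x$ligand_id, x$protein_conc, length(x$ligand_totals),
              paste(x$ligand_totals, collapse = ", ")))
  invisible(x)
}

check_ladder <- function(ligand_totals) {
  if (length(ligand_totals) < 2L) {
    stop("a titration needs at least an apo point and one ligand point",
         call. = FALSE)
  }
  if (ligand_totals[[1L]] != 0) {
    stop("the first titration point must be the apo reference (0 mM)",
         call. = FALSE)
  }
  if (is.unsorted(ligand_totals, strictly = TRUE)) {
    stop("ligand totals must be strictly increasing", call. = FALSE)
  }
}

#' Simulate an HSQC titration series
#'
#' One [simulate_sample()] per ladder point with a fresh noise draw each,
#' first point apo.
#'
#' @inheritParams simulate_sample
#' @param fragment the titrated [fragment_record()].
#' @param ligand_totals strictly increasing mM ladder starting at 0.
#' @return A `titration_series` (points are [peak_list()]s).
#' @export
simulate_titration <- function(assign, fragment, ligand_totals,
                               protein_conc = 50,
                               noise_sd = c(0.004, 0.02), seed = 1L) {
  check_ladder(ligand_totals)
  id <- frag_field(fragment, "fragment_id")
  points <- lapply(seq_along(ligand_totals), function(i) {
    simulate_sample(assign, list(fragment), ligand_totals[[i]],
                    protein_conc = protein_conc, noise_sd = noise_sd,
                    seed = seed + 1000L * i,
                    sample_id = sprintf("%s_%02d", id, i))
  })
  new_titration_series(protein_conc, id, ligand_totals, points, seed)
}

#' Dual-ligand titration schedule
#'
#' @param fixed_id,fixed_conc identity and constant concentration (mM) of
#'   the background ligand; 0 degenerates to a plain single-ligand
#'   titration of the varied fragment.
#' @param varied_id identity of the titrated ligand.
#' @param varied_totals mM ladder for the titrated ligand, starting at 0.
#' @param mode `"independent_sites"` (ternary complex allowed, no
#'   cooperativity) or `"competitive"` (one shared site).
#' @return A `dual_schedule` list.
#' @export
dual_schedule <- function(fixed_id, fixed_conc, varied_id, varied_totals,
                          mode = c("independent_sites", "competitive")) {
  mode <- match.arg(mode)
  check_ladder(varied_totals)
  if (!is.finite(fixed_conc) || fixed_conc < 0) {
    stop("fixed ligand concentration must be >= 0", call. = FALSE)
  }
  structure(list(fixed_id = fixed_id, fixed_conc = fixed_conc,
                 varied_id = varied_id, varied_totals = varied_totals,
                 mode = mode),
            class = "dual_schedule")
}

#' Simulate a dual-fragment titration
#'
#' The varied fragment is titrated into a sample already containing the
#' fixed fragment. At every point the coupled two-ligand equilibria are
#' solved with [solve_dual_occupancy()] in the schedule's mode, and each
#' residue's fast-exchange shift is the occupancy-weighted sum of the two
#' fragments' maximal shifts.
#'
#' @inheritParams simulate_sample
#' @param varied,fixed [fragment_record()]s (must be distinct); `varied`
#'   is titrated, `fixed` is present at `schedule$fixed_conc` throughout.
#' @param schedule a [dual_schedule()].
#' @return A `titration_series` over the varied ligand's ladder; every
#'   point's `conditions` also record the fixed ligand.
#' @export
simulate_dual <- function(assign, varied, fixed, schedule,
                          protein_conc = 50, noise_sd = c(0.004, 0.02),
                          seed = 1L) {
  stopifnot(inherits(schedule, "dual_schedule"))
  vid <- frag_field(varied, "fragment_id")
  fid <- frag_field(fixed, "fragment_id")
  if (identical(vid, fid)) stop("dual titration needs two distinct fragments",
                                call. = FALSE)
  totals <- schedule$varied_totals
  points <- lapply(seq_along(totals), function(i) {
    sol <- solve_dual_occupancy(protein_conc, totals[[i]],
                                schedule$fixed_conc,
                                frag_field(varied, "kd"),
                                frag_field(fixed, "kd"),
                                mode = schedule$mode)
    wH <- assign$w_H; wN <- assign$w_N
    for (fr in list(list(rec = varied, f = sol$f_A),
                    list(rec = fixed, f = sol$f_B))) {
      idx <- match(fr$rec$dmax$residue, assign$residue)
      keep <- !is.na(idx)
      wH[idx[keep]] <- wH[idx[keep]] + fr$f * fr$rec$dmax$d_H[keep]
      wN[idx[keep]] <- wN[idx[keep]] + fr$f * fr$rec$dmax$d_N[keep]
    }
    noise_sd2 <- rep_len(as.numeric(noise_sd), 2L)
    if (any(noise_sd2 > 0)) {
      n <- length(wH)
      noise <- with_seed(seed + 1000L * i,
                         list(h = stats::rnorm(n, 0, noise_sd2[[1L]]),
                              n = stats::rnorm(n, 0, noise_sd2[[2L]])))
      wH <- wH + noise$h
      wN <- wN + noise$n
    }
    cond <- c(totals[[i]], schedule$fixed_conc)
    names(cond) <- c(vid, fid)
    peak_list(data.frame(label = assign$label, w_H = wH, w_N = wN,
                         height = rep(1, length(wH)),
                         stringsAsFactors = FALSE),
              sample_id = sprintf("%s_into_%s_%02d", vid, fid, i),
              conditions = cond, protein_conc = protein_conc)
  })
  out <- new_titration_series(protein_conc, vid, totals, points, seed)
  out$fixed_id <- fid
  out$fixed_conc <- schedule$fixed_conc
  out$mode <- schedule$mode
  out
}
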