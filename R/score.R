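#' Crossbridge scoring parameters
#'
#' The five Gaussian (mu, sigma) pairs over the fiducial distances, the
#' sigma multiplication factor `m` (encoding fascin plasticity) and the
#' minimum binding probability `tau`.
#'
#' @param mu numeric length-5 means of the five fiducial distances, nm.
#' @param sigma numeric length-5 standard deviations, nm (all > 0).
#' @param m sigma multiplication factor (>= 1, default 4).
#' @param tau minimum binding probability threshold (0 < tau < 1,
#'   default 0.4).
#' @param set optional label recording the provenance of the table
#'   (e.g. `"idealized"`).
#' @return an object of class `score_params`.
#' @export
score_params <- function(mu, sigma, m = 4, tau = 0.4, set = "custom") {
  stopifnot(length(mu) == 5L, length(sigma) == 5L)
  if (any(sigma <= 0)) stop("all sigma must be > 0")
  if (m < 1) stop("m must be >= 1")
  if (tau <= 0 || tau >= 1) stop("tau must satisfy 0 < tau < 1")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 m = m, tau = tau, set = set),
            class = "score_params")
}

#' @export
print.score_params <- function(x, ...) {
  cat(sprintf("Crossbridge score parameters [%s]: m = %g, tau = %g\n",
              x$set, x$m, x$tau))
  tab <- data.frame(distance = paste0("d", 1:5), mu = x$mu, sigma = x$sigma)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Single-distance Gaussian binding probability
#'
#' `exp(-((d - mu) / (m * sigma))^2 / 2)`: 1 exactly at `d = mu` and
#' strictly decreasing in `|d - mu|`. `m` widens the tolerated distance
#' range, modelling crossbridge structural plasticity.
#'
#' @param d observed distance, nm (vectorized).
#' @param mu,sigma Gaussian centre and width, nm (`sigma > 0`).
#' @param m sigma multiplication factor (>= 1).
#' @return probability in `(0, 1]`.
#' @export
component_probability <- function(d, mu, sigma, m = 4) {
  stopifnot(sigma > 0, m >= 1)
  exp(-0.5 * ((d - mu) / (m * sigma))^2)
}

#' Composite crossbridge probability
#'
#' Product of the five component probabilities evaluated at the five
#' fiducial distances of a candidate bond.
#'
#' @param d numeric length-5 vector of fiducial distances, nm (see
#'   [candidate_distances()]).
#' @param params a [score_params()].
#' @return probability `P` in `[0, 1]`.
#' @export
bond_probability <- function(d, params) {
  stopifnot(length(d) == 5L)
  prod(component_probability(d, params$mu, params$sigma, params$m))
}

#' Normalized crossbridge energy
#'
#' The negative inverse of the bond probability for a formed bond
#' (`Ec = -1/P <= -1`), and exactly 0 when no bond forms.
#'
#' @param P composite bond probability.
#' @param bonded logical: did a bond form?
#' @return `Ec`.
#' @export
crossbridge_energy <- function(P, bonded = TRUE) {
  if (!bonded) return(0)
  if (any(P <= 0)) stop("bonded crossbridge requires P > 0")
  -1 / P
}

# Normal vector (in xy) of the plane containing both filament axes.
.interaxis_normal <- function(posA, posB) {
  u <- posB - posA
  len <- sqrt(sum(u^2))
  if (len < 1e-9) stop("coincident filament axes: inter-axis plane undefined")
  c(-u[2], u[1]) / len
}

#' Fiducial distances of a candidate fascin bond
#'
#' For a candidate "up"-pose bond with ABS1 engaging protomers `i`, `i+2`
#' of `filA` and ABS2 engaging protomers `j+1`, `j+3` of `filB`, computes
#' the five scored distances:
#' `d1 = |R95_i - R95_(j+1)|`, `d2 = |R95_i - S350_(j+3)|`,
#' `d3 = |D24_(i+2) - S350_(j+3)|`, `d4 = |D24_(i+2) - R95_(j+1)|`, and
#' `d5` = distance from the centroid of those four sites to the plane
#' containing the two filament axes (which penalizes out-of-plane
#' distortion of the crossbridge).
#'
#' @param filA,filB [filament()] objects with distinct, parallel axes.
#' @param i base protomer index on the ABS1-side filament
#'   (`i + 2 < n_protomers` of `filA`).
#' @param j base protomer index on the ABS2-side filament
#'   (`j + 3 < n_protomers` of `filB`).
#' @param helix a [helical_params()].
#' @param fid a [fiducial_geometry()].
#' @return numeric length-5 vector `c(d1, d2, d3, d4, d5)` in nm.
#' @export
candidate_distances <- function(filA, i, filB, j, helix = helical_params(),
                                fid = fiducial_geometry()) {
  if (i < 0 || i + 2 >= filA$n_protomers)
    stop("ABS1 index i out of range: need 0 <= i and i+2 < n_protomers")
  if (j < 0 || j + 3 >= filB$n_protomers)
    stop("ABS2 index j out of range: need 0 <= j and j+3 < n_protomers")
  nrm <- .interaxis_normal(filA$position, filB$position)
  sA1 <- protomer_site(filA, i, "R95", helix, fid)
  sA2 <- protomer_site(filA, i + 2, "D24", helix, fid)
  sB1 <- protomer_site(filB, j + 1, "R95", helix, fid)
  sB2 <- protomer_site(filB, j + 3, "S350", helix, fid)
  cen <- (sA1 + sA2 + sB1 + sB2) / 4
  d5 <- abs(sum((cen[1:2] - filA$position) * nrm))
  c(sqrt(sum((sA1 - sB1)^2)), sqrt(sum((sA1 - sB2)^2)),
    sqrt(sum((sA2 - sB2)^2)), sqrt(sum((sA2 - sB1)^2)), d5)
}

# ---------------------------------------------------------------------------
# Vectorized rotation-sweep kernel.
#
# Every scored distance between a site on a rotating filament and a fixed
# point is a sinusoid in the rotation angle: d(theta)^2 = C + R cos(theta
# + delta); the plane distance is |K + G cos(theta + H)|. Candidates are
# therefore precomputed as constants (.pair_candidates) and evaluated on
# the whole angle grid in a handful of vector operations
# (.sweep_candidates), with axial/lateral pruning of candidates whose
# distances can never come near the Gaussian centres.
# ---------------------------------------------------------------------------

# Site constants on the *rotating* filament: phase offset (deg, to which
# theta is added), radius, z.
.rot_site <- function(k, res, helix, fid, axial_offset) {
  f <- fid[[res]]
  list(phase = k * helix$twist + f[["azimuth"]], r = f[["radius"]],
       z = k * helix$rise + axial_offset + f[["axial"]])
}

# Constants of d(theta) between a fixed 3D site s and a rotating site v
# on a filament centred at cen: d^2 = C + R cos(theta_rad + delta).
.dist_const <- function(s, v, cen) {
  ux <- cen[1] - s[1]; uy <- cen[2] - s[2]
  dz <- v$z - s[3]
  list(C = ux^2 + uy^2 + v$r^2 + dz^2,
       R = 2 * v$r * sqrt(ux^2 + uy^2),
       delta = deg2rad(v$phase) - atan2(uy, ux))
}

# Enumerate candidate (i, j) bonds between a fixed filament and a new
# filament at `center` whose rotation is to be swept. `new_is_abs2`
# selects which side the rotating filament plays: TRUE -> candidates have
# ABS1 on the fixed filament (indices i on fixed, j on new), FALSE ->
# ABS1 on the new filament (i on new, j on fixed).
#
# Returns a list of candidate records with sinusoid constants, or an
# empty list after pruning.
.pair_candidates <- function(fixed, center, n_new, axial_new, new_is_abs2,
                             helix, fid, params) {
  width <- 6.5 * params$m * params$sigma  # beyond this, P_n < 1e-9
  lo <- params$mu - width
  hi <- params$mu + width
  nrm <- .interaxis_normal(
    if (new_is_abs2) fixed$position else center,
    if (new_is_abs2) center else fixed$position)
  axisA <- if (new_is_abs2) fixed$position else center
  chi <- atan2(nrm[2], nrm[1])
  # site tables computed once per pair
  fix_site <- function(res) {
    ks <- seq_len(fixed$n_protomers) - 1L
    t(vapply(ks, function(k) protomer_site(fixed, k, res, helix, fid),
             numeric(3)))
  }
  rot_site <- function(res) {
    ks <- seq_len(n_new) - 1L
    lapply(ks, function(k) .rot_site(k, res, helix, fid, axial_new))
  }
  if (new_is_abs2) {
    fixR95 <- fix_site("R95"); fixD24 <- fix_site("D24")
    rotR95 <- rot_site("R95"); rotS350 <- rot_site("S350")
    i_rng <- seq_len(fixed$n_protomers - 2) - 1L   # i on fixed (ABS1)
    j_rng <- seq_len(n_new - 3) - 1L               # j on new (ABS2)
  } else {
    fixR95 <- fix_site("R95"); fixS350 <- fix_site("S350")
    rotR95 <- rot_site("R95"); rotD24 <- rot_site("D24")
    i_rng <- seq_len(n_new - 2) - 1L               # i on new (ABS1)
    j_rng <- seq_len(fixed$n_protomers - 3) - 1L   # j on fixed (ABS2)
  }
  out <- list()
  for (i in i_rng) for (j in j_rng) {
    if (new_is_abs2) {
      fixed_sites <- list(fixR95[i + 1L, ], fixD24[i + 3L, ])
      rot <- list(rotR95[[j + 2L]], rotS350[[j + 4L]])
      # d1..d4 as (fixed site index, rotating site index)
      pairs <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 1L))
    } else {
      fixed_sites <- list(fixR95[j + 2L, ], fixS350[j + 4L, ])
      rot <- list(rotR95[[i + 1L]], rotD24[[i + 3L]])
      pairs <- list(c(1L, 1L), c(2L, 1L), c(2L, 2L), c(1L, 2L))
    }
    ok <- TRUE
    cst <- vector("list", 4L)
    for (n in 1:4) {
      s <- fixed_sites[[pairs[[n]][1]]]
      v <- rot[[pairs[[n]][2]]]
      cc <- .dist_const(s, v, center)
      dmin <- sqrt(max(cc$C - cc$R, 0))
      dmax <- sqrt(cc$C + cc$R)
      if (dmin > hi[n] || dmax < lo[n]) { ok <- FALSE; break }
      cst[[n]] <- cc
    }
    if (!ok) next
    # plane distance d5 = |K + G cos(theta + H)| via summed sinusoids
    sfix <- (fixed_sites[[1]][1:2] + fixed_sites[[2]][1:2] + 2 * center) / 4
    K <- sum((sfix - axisA) * nrm)
    a1 <- rot[[1]]$r / 4; p1 <- deg2rad(rot[[1]]$phase) - chi
    a2 <- rot[[2]]$r / 4; p2 <- deg2rad(rot[[2]]$phase) - chi
    gx <- a1 * cos(p1) + a2 * cos(p2)
    gy <- a1 * sin(p1) + a2 * sin(p2)
    G <- sqrt(gx^2 + gy^2)
    H <- atan2(gy, gx)
    if (max(0, abs(K) - G) > hi[5] || abs(K) + G < lo[5]) next
    out[[length(out) + 1L]] <- list(
      i = i, j = j, abs1_on_new = !new_is_abs2,
      C = vapply(cst, `[[`, 0, "C"), R = vapply(cst, `[[`, 0, "R"),
      delta = vapply(cst, `[[`, 0, "delta"), K = K, G = G, H = H)
  }
  out
}

# Sweep all candidates of one fixed/new filament pair over an angle grid
# via the compiled kernel. theta_deg: grid of rotations of the new
# filament (degrees). Returns list(best_P, best_cand (index into cands,
# 0 = none), and a hit table of (cand, theta_idx, P) for P >= tau).
.sweep_candidates <- function(cands, theta_deg, params, tau = params$tau) {
  Tn <- length(theta_deg)
  if (!length(cands)) {
    return(list(best_P = numeric(Tn), best_cand = integer(Tn),
                hits = data.frame(cand = integer(0),
                                  theta_idx = integer(0), P = numeric(0))))
  }
  res <- .sweep_kernel(
    vapply(cands, `[[`, numeric(4), "C"),
    vapply(cands, `[[`, numeric(4), "R"),
    vapply(cands, `[[`, numeric(4), "delta"),
    vapply(cands, `[[`, 0, "K"),
    vapply(cands, `[[`, 0, "G"),
    vapply(cands, `[[`, 0, "H"),
    params$mu, params$m * params$sigma,
    deg2rad(theta_deg), if (is.finite(tau)) tau else 2)
  list(best_P = res$best_P, best_cand = res$best_cand,
       hits = data.frame(cand = res$hit_cand, theta_idx = res$hit_theta,
                         P = res$hit_P))
}

# Deterministic candidate ordering used for tie-breaking: pose "up"
# (ABS1 on the first-named filament) before "down", then smallest i,
# then smallest j.
.order_candidates <- function(cands, up_first_on_new = FALSE) {
  if (!length(cands)) return(cands)
  up <- vapply(cands, `[[`, TRUE, "abs1_on_new")
  if (!up_first_on_new) up <- !up
  ii <- vapply(cands, `[[`, 0, "i")
  jj <- vapply(cands, `[[`, 0, "j")
  cands[order(!up, ii, jj)]
}

#' Best fascin bond between two filaments
#'
#' Enumerates every valid candidate bond between `filA` and `filB` in
#' both poses -- "up" (ABS1 engaging `filA`) and "down" (ABS1 engaging
#' `filB`, i.e. the up pose of the swapped ordered pair) -- and returns
#' the candidate with the largest composite probability `P` provided
#' `P >= tau`, otherwise `NULL`. Ties are broken deterministically:
#' up pose before down, then smallest `i`, then smallest `j`.
#'
#' @param filA,filB [filament()] objects (parallel axes, distinct
#'   positions).
#' @param params a [score_params()].
#' @param helix a [helical_params()].
#' @param fid a [fiducial_geometry()].
#' @return a one-row data.frame (class `crossbridge`) with columns
#'   `filament_a`, `filament_b`, `i`, `j`, `pose`, `P`, `Ec`, where `i`
#'   is the base protomer index on the ABS1-side filament and `j` on the
#'   ABS2-side filament (`pose == "up"`: ABS1 side is `filA`; `"down"`:
#'   ABS1 side is `filB`); or `NULL` if no candidate reaches `tau`.
#' @export
best_bond <- function(filA, filB, params, helix = helical_params(),
                      fid = fiducial_geometry()) {
  best <- NULL
  for (pose in c("up", "down")) {
    a <- if (pose == "up") filA else filB
    b <- if (pose == "up") filB else filA
    for (i in seq_len(a$n_protomers - 2) - 1L) {
      for (j in seq_len(b$n_protomers - 3) - 1L) {
        P <- bond_probability(candidate_distances(a, i, b, j, helix, fid),
                              params)
        if (is.null(best) || P > best$P + 1e-15) {
          best <- list(pose = pose, i = i, j = j, P = P)
        }
      }
    }
  }
  if (is.null(best) || best$P < params$tau) return(NULL)
  out <- data.frame(filament_a = filA$id, filament_b = filB$id,
                    i = best$i, j = best$j, pose = best$pose,
                    P = best$P, Ec = -1 / best$P,
                    stringsAsFactors = FALSE)
  class(out) <- c("crossbridge", "data.frame")
  out
}
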