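# Axial centre of a crossbridge in subunit units: the mean protomer index
# of its four anchor sites (i, i+2 on the ABS1 side; j+1, j+3 on the
# ABS2 side). Half-integer values arise when the two sides are offset.
.bridge_center <- function(cb) (cb$i + cb$j + 3) / 2

# Pose of a bridge relative to an ordered (left, right) filament pair:
# "up" when ABS1 engages the left filament.
.pose_lr <- function(cb, left_id) {
  abs1 <- ifelse(cb$pose == "up", cb$filament_a, cb$filament_b)
  ifelse(abs1 == left_id, "up", "down")
}

# ABS1-side / ABS2-side filament ids of canonical bridge rows.
.abs1_id <- function(cb) ifelse(cb$pose == "up", cb$filament_a, cb$filament_b)
.abs2_id <- function(cb) ifelse(cb$pose == "up", cb$filament_b, cb$filament_a)

# Identify the central filament of a bundle element: the one bridgeable
# to every other filament.
.central_filament <- function(bundle) {
  pos <- t(vapply(bundle$filaments, `[[`, numeric(2), "position"))
  sp <- bundle$cfg$lattice$spacing
  for (k in seq_len(nrow(pos))) {
    d <- sqrt(rowSums((pos - matrix(pos[k, ], nrow(pos), 2, byrow = TRUE))^2))
    if (all(abs(d[-k] - sp) <= bundle$cfg$tol)) return(k)
  }
  stop("no filament is bridgeable to all others: not a bundle element")
}

#' Averaged crossbridge contact map of bundle elements
#'
#' Accumulates fascin anchor positions over a set of seven-filament
#' bundle elements aligned on their central filament. Rows are filament
#' labels (peripheral filaments 1-6 numbered counterclockwise from +x
#' around the centre; the central filament is 7); columns are the 16
#' protomers A-P from the barbed end. Each crossbridge is tallied at its
#' base protomer on each filament it touches: `i` on the ABS1 side,
#' `j + 1` on the ABS2 side.
#'
#' @param bundles list of seven-filament `fascin_bundle` objects whose
#'   filaments all carry 16 protomers.
#' @param align_on index of the central filament within each bundle, or
#'   `NULL` to detect it geometrically.
#' @return a 7 x 16 integer matrix of class `contact_map`.
#' @export
contact_map <- function(bundles, align_on = NULL) {
  M <- matrix(0L, 7, 16,
              dimnames = list(filament = c(as.character(1:6), "7"),
                              protomer = LETTERS[1:16]))
  class(M) <- c("contact_map", class(M))
  for (bundle in bundles) {
    if (length(bundle$filaments) != 7L)
      stop("contact_map expects seven-filament bundle elements")
    if (any(vapply(bundle$filaments, `[[`, 0L, "n_protomers") != 16L))
      stop("contact_map expects filaments of exactly 16 protomers")
    central <- if (is.null(align_on)) .central_filament(bundle) else align_on
    pos <- t(vapply(bundle$filaments, `[[`, numeric(2), "position"))
    ang <- wrap_360(atan2(pos[, 2] - pos[central, 2],
                          pos[, 1] - pos[central, 1]) * 180 / pi)
    periph <- setdiff(seq_len(7L), central)
    lab <- integer(7L)
    lab[central] <- 7L
    lab[periph[order(ang[periph])]] <- 1:6
    cb <- bundle$crossbridges
    if (!nrow(cb)) next
    a1 <- .abs1_id(cb); a2 <- .abs2_id(cb)
    for (r in seq_len(nrow(cb))) {
      M[lab[a1[r]], cb$i[r] + 1L] <- M[lab[a1[r]], cb$i[r] + 1L] + 1L
      M[lab[a2[r]], cb$j[r] + 2L] <- M[lab[a2[r]], cb$j[r] + 2L] + 1L
    }
  }
  M
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Crossbridge contact map (filament x protomer), total counts =",
      sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

# Phase-shift bin: "zero" when |s| < 12.5 deg, "minus"/"plus" when s is
# within 12.5 deg of -/+ 26.7 (the one-subunit-equivalent rotation),
# "other" beyond.
.shift_bin <- function(s) {
  ifelse(abs(s) < 12.5, "zero",
         ifelse(abs(s + 26.7) <= 12.5, "minus",
                ifelse(abs(s - 26.7) <= 12.5, "plus", "other")))
}

#' Classify the crossband morphology of an actin plane
#'
#' Given an ordered, co-planar run of filaments, bins the consecutive
#' rotational phase shifts (about 0, about -25, about +25 degrees, using
#' half-way boundaries around the one-subunit-equivalent rotation) and
#' labels the crossband: all about-zero shifts give `"linear"`, a run of
#' same-sign about-25 shifts gives `"slanted"`, a block of -25s followed
#' by a block of +25s gives `"chevron"`, anything else `"other"`. The
#' plane is first put in canonical orientation (reversed if its first
#' non-zero-binned shift is positive), so mirrored views classify
#' identically.
#'
#' @param x a `fascin_bundle`, or a numeric vector of consecutive
#'   phase shifts in degrees.
#' @param ids when `x` is a bundle: filament ids in plane order
#'   (>= 3 filaments).
#' @return a list of class `crossband_class` with `label`, the binned
#'   `shifts`, and `flagged` (`TRUE` when fewer than two crossbridges
#'   support the plane, making the classification undefined).
#' @export
classify_crossband <- function(x, ids = NULL) {
  flagged <- FALSE
  if (inherits(x, "fascin_bundle")) {
    stopifnot(length(ids) >= 3L)
    fils <- x$filaments[ids]
    shifts <- vapply(seq_len(length(fils) - 1L), function(k)
      rotational_phase_shift(fils[[k]], fils[[k + 1L]]), 0)
    cb <- x$crossbridges
    support <- sum(vapply(seq_len(length(ids) - 1L), function(k)
      sum((cb$filament_a == min(ids[k], ids[k + 1]) &
             cb$filament_b == max(ids[k], ids[k + 1]))), 0L))
    flagged <- support < 2L
  } else {
    shifts <- as.numeric(x)
    if (length(shifts) < 2L)
      stop("need at least two consecutive phase shifts (>= 3 filaments)")
  }
  bins <- .shift_bin(shifts)
  nz <- bins[bins != "zero"]
  if (length(nz) && nz[1] == "plus") {   # canonical orientation
    shifts <- rev(-shifts)
    bins <- .shift_bin(shifts)
    nz <- bins[bins != "zero"]
  }
  label <- if (any(bins == "other")) "other"
  else if (!length(nz)) "linear"
  else if (all(nz == "minus")) "slanted"
  else {
    # one sign reversal, pointing either way (a reversed chevron is
    # its own mirror image, so canonicalization cannot reorder it)
    r <- rle(nz)$values
    if (identical(r, c("minus", "plus")) ||
        identical(r, c("plus", "minus"))) "chevron" else "other"
  }
  structure(list(label = label, shifts = shifts, bins = bins,
                 flagged = flagged), class = "crossband_class")
}

#' @export
print.crossband_class <- function(x, ...) {
  cat(sprintf("Crossband: %s%s  (shifts: %s)\n", x$label,
              if (x$flagged) " [flagged: < 2 crossbridges]" else "",
              paste(round(x$shifts, 1), collapse = ", ")))
  invisible(x)
}

# Find co-linear triples of consecutive bridgeable lattice neighbours.
.colinear_triples <- function(bundle) {
  pos <- t(vapply(bundle$filaments, `[[`, numeric(2), "position"))
  sp <- bundle$cfg$lattice$spacing
  tol <- bundle$cfg$tol
  n <- nrow(pos)
  out <- list()
  pairs <- bridgeable_pairs(pos, sp, tol)
  adj <- lapply(seq_len(n), function(k)
    sort(c(pairs[pairs[, 1] == k, 2], pairs[pairs[, 2] == k, 1])))
  for (mid in seq_len(n)) {
    nb <- adj[[mid]]
    if (length(nb) < 2) next
    for (a in nb) for (b in nb) {
      if (a >= b) next
      v1 <- pos[mid, ] - pos[a, ]
      v2 <- pos[b, ] - pos[mid, ]
      if (sum(abs(v1 - v2)) < tol)   # same step: co-linear
        out[[length(out) + 1L]] <- c(a, mid, b)
    }
  }
  out
}

#' Extract three-filament crossbridge configurations
#'
#' Finds every co-linear run of three consecutive lattice neighbours
#' carrying a fascin on each of its two interfaces within half a
#' crossover of each other, and reports the quantities that govern the
#' emergent crossband rules: the cumulative rotational phase shift from
#' the first to the third filament, the axial offset between the two
#' fascins, and whether the two poses match. Triplets are canonicalized
#' (reversed when the first non-negligible phase shift is positive) so
#' mirrored views yield identical records.
#'
#' The axial offset is reported in fascin repeat units: 1.0 is the
#' axial spacing between equivalent same-pose binding positions (two
#' protomer rises, 5.5 nm -- one subunit step along a long-pitch
#' strand). Half units (one protomer rise) occur together with a pose
#' flip, since the bond anchor pattern shifts by a single protomer only
#' when the crossbridge orientation inverts. Under cumulative shifts of
#' about 0, -27 and -53 degrees this reproduces the observed rule
#' table: offset 0 with matched poses, 0.5 with opposite poses, and 1
#' with matched poses.
#'
#' @param bundle a `fascin_bundle` assembled on a hexagonal lattice.
#' @return data.frame of class `triplet_table`: one row per triplet with
#'   `f1`, `f2`, `f3`, `cumulative_shift` (deg, in (-180, 180]),
#'   `axial_offset` (subunits, >= 0), `pose_first`, `pose_second`,
#'   `pose_match` (`"same"`/`"opposite"`).
#' @export
extract_triplets <- function(bundle) {
  cb <- bundle$crossbridges
  half_cross <- crossover_length(bundle$cfg$helix) /
    (2 * bundle$cfg$helix$rise)          # in subunits
  rows <- list()
  for (tri in .colinear_triples(bundle)) {
    ids <- vapply(bundle$filaments[tri], `[[`, 0L, "id")
    b12 <- cb[(cb$filament_a == min(ids[1:2]) &
                 cb$filament_b == max(ids[1:2])), , drop = FALSE]
    b23 <- cb[(cb$filament_a == min(ids[2:3]) &
                 cb$filament_b == max(ids[2:3])), , drop = FALSE]
    if (!nrow(b12) || !nrow(b23)) next
    for (r1 in seq_len(nrow(b12))) for (r2 in seq_len(nrow(b23))) {
      z1 <- .bridge_center(b12[r1, ])
      z2 <- .bridge_center(b23[r2, ])
      if (abs(z2 - z1) > half_cross) next
      s12 <- rotational_phase_shift(bundle$filaments[[tri[1]]],
                                    bundle$filaments[[tri[2]]])
      s23 <- rotational_phase_shift(bundle$filaments[[tri[2]]],
                                    bundle$filaments[[tri[3]]])
      # canonical orientation: first non-negligible shift negative;
      # reversing the triple negates and swaps the pairwise shifts and
      # exchanges the two bridges
      first_nz <- if (abs(s12) > 0.01) s12 else
        if (abs(s23) > 0.01) s23 else 0
      if (first_nz > 0) {
        ids <- rev(ids)
        bA <- b23[r2, ]; bB <- b12[r1, ]
        tmp <- s12; s12 <- -s23; s23 <- -tmp
      } else {
        bA <- b12[r1, ]; bB <- b23[r2, ]
      }
      cum <- wrap_180(s12 + s23)
      zA <- .bridge_center(bA); zB <- .bridge_center(bB)
      poseA <- .pose_lr(bA, ids[1])
      poseB <- .pose_lr(bB, ids[2])
      rows[[length(rows) + 1L]] <- data.frame(
        f1 = ids[1], f2 = ids[2], f3 = ids[3],
        cumulative_shift = cum,
        axial_offset = round(abs(zB - zA)) / 2,
        pose_first = poseA, pose_second = poseB,
        pose_match = if (poseA == poseB) "same" else "opposite",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(f1 = integer(0), f2 = integer(0), f3 = integer(0),
               cumulative_shift = numeric(0), axial_offset = numeric(0),
               pose_first = character(0), pose_second = character(0),
               pose_match = character(0), stringsAsFactors = FALSE)
  class(out) <- c("triplet_table", "data.frame")
  out
}

#' Aggregate triplet configurations over simulated bundles
#'
#' Runs [extract_triplets()] over a list of bundles and stacks the
#' results -- the simulated counterpart of the cumulative-phase-shift
#' versus axial-offset scatter used to read out the emergent binding
#' rules.
#'
#' @param bundles list of `fascin_bundle` objects.
#' @return a `triplet_table` data.frame with an extra `bundle` column.
#' @export
triplet_scatter <- function(bundles) {
  rows <- lapply(seq_along(bundles), function(k) {
    tt <- extract_triplets(bundles[[k]])
    if (nrow(tt)) cbind(bundle = k, tt) else NULL
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(bundle = integer(0), extract_triplets.empty())
  class(out) <- c("triplet_table", "data.frame")
  out
}

extract_triplets.empty <- function() {
  data.frame(f1 = integer(0), f2 = integer(0), f3 = integer(0),
             cumulative_shift = numeric(0), axial_offset = numeric(0),
             pose_first = character(0), pose_second = character(0),
             pose_match = character(0), stringsAsFactors = FALSE)
}
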