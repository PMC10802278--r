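#' Helical symmetry parameters of F-actin
#'
#' F-actin is represented as a single genetic helix: one protomer per
#' axial rise step, successive protomers related by a left-handed twist.
#' The defaults are the canonical values used for bundle modelling
#' (-166.7 degrees per subunit, 2.75 nm rise).
#'
#' @param twist_per_subunit rotation between successive protomers, degrees.
#'   Must satisfy 90 < |twist| < 180.
#' @param rise_per_subunit axial translation between successive protomers, nm.
#' @return an object of class `helical_params`.
#' @export
helical_params <- function(twist_per_subunit = -166.7, rise_per_subunit = 2.75) {
  stopifnot(is.numeric(twist_per_subunit), length(twist_per_subunit) == 1L,
            is.numeric(rise_per_subunit), length(rise_per_subunit) == 1L)
  if (rise_per_subunit <= 0)
    stop("rise_per_subunit must be > 0")
  if (abs(twist_per_subunit) <= 90 || abs(twist_per_subunit) >= 180)
    stop("|twist_per_subunit| must lie strictly between 90 and 180 degrees")
  structure(list(twist = twist_per_subunit, rise = rise_per_subunit),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("Helical parameters: twist %.4g deg/subunit, rise %.4g nm\n",
              x$twist, x$rise))
  invisible(x)
}

#' Fiducial site geometry on the actin protomer
#'
#' Cylindrical offsets of the three fiducial residues (D24, R95, S350)
#' used to score fascin crossbridges, expressed relative to the protomer
#' frame: `radius` from the filament axis (nm), `azimuth` relative to the
#' protomer phase (degrees), `axial` relative to the protomer z (nm).
#'
#' The packaged default is a synthetic stand-in table with plausible
#' actin-surface coordinates (see
#' `inst/extdata/fiducial_geometry_synthetic.csv`); all downstream
#' scoring is self-consistent with whatever table is supplied here.
#'
#' @param table a data.frame with columns `residue`, `radius`, `azimuth`,
#'   `axial` containing exactly the rows D24, R95, S350, or `NULL` to
#'   load the packaged default.
#' @return an object of class `fiducial_geometry`: a named list of
#'   `c(radius, azimuth, axial)` per residue.
#' @export
fiducial_geometry <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "fiducial_geometry_synthetic.csv",
                        package = "fascinet", mustWork = TRUE)
    table <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  }
  needed <- c("residue", "radius", "azimuth", "axial")
  if (!all(needed %in% names(table)))
    stop("fiducial table must have columns: ", paste(needed, collapse = ", "))
  labels <- sort(table$residue)
  if (!identical(labels, c("D24", "R95", "S350")))
    stop("fiducial table must contain exactly the residues D24, R95, S350")
  if (any(table$radius < 0)) stop("fiducial radius must be >= 0")
  out <- lapply(seq_len(nrow(table)), function(r)
    c(radius = table$radius[r], azimuth = table$azimuth[r],
      axial = table$axial[r]))
  names(out) <- table$residue
  structure(out, class = "fiducial_geometry")
}

#' A single actin filament in a bundle
#'
#' @param id integer filament identifier.
#' @param position numeric length-2 lattice position (x, y) in nm; the
#'   filament axis runs along +z through this point, barbed end toward +z,
#'   protomer `k = 0` at the barbed end.
#' @param rotation absolute rotation angle of protomer 0, degrees
#'   (normalized to `[0, 360)`).
#' @param n_protomers number of protomers (>= 4; a fascin bond engages
#'   indices up to `i + 3`).
#' @param axial_offset axial shift of protomer 0, nm.
#' @return an object of class `filament`.
#' @export
filament <- function(id, position, rotation = 0, n_protomers = 16,
                     axial_offset = 0) {
  stopifnot(length(position) == 2L, is.numeric(position))
  if (n_protomers < 4)
    stop("n_protomers must be >= 4")
  structure(list(id = as.integer(id), position = as.numeric(position),
                 rotation = wrap_360(rotation),
                 n_protomers = as.integer(n_protomers),
                 axial_offset = as.numeric(axial_offset)),
            class = "filament")
}

#' Cartesian position of a fiducial site
#'
#' Places residue `residue` of protomer `k` on a filament: the azimuth is
#' `rotation + k * twist + azimuth offset` (mod 360) and the height is
#' `k * rise + filament axial offset + residue axial offset`.
#'
#' @param fil a [filament()].
#' @param k protomer index, `0 <= k < n_protomers`.
#' @param residue one of `"D24"`, `"R95"`, `"S350"` (or any label present
#'   in `fid`).
#' @param helix a [helical_params()].
#' @param fid a [fiducial_geometry()].
#' @return numeric length-3 point `(x, y, z)` in nm.
#' @export
protomer_site <- function(fil, k, residue, helix = helical_params(),
                          fid = fiducial_geometry()) {
  if (any(k < 0) || any(k >= fil$n_protomers))
    stop("protomer index out of range")
  f <- fid[[residue]]
  if (is.null(f))
    stop("unknown fiducial residue label: ", residue)
  az <- deg2rad(wrap_360(fil$rotation + k * helix$twist + f[["azimuth"]]))
  c(fil$position[1] + f[["radius"]] * cos(az),
    fil$position[2] + f[["radius"]] * sin(az),
    k * helix$rise + fil$axial_offset + f[["axial"]])
}

#' Crossover length of the actin helix
#'
#' The axial distance over which the protomer azimuth advances by 180
#' degrees, i.e. the period of the filament's apparent two-start
#' crossover pattern: `rise * 180 / (180 - |twist|)`. At the default
#' helical parameters this is ~37 nm, the longitudinal period of fascin
#' decoration in bundles.
#'
#' @param helix a [helical_params()].
#' @return length in nm.
#' @export
crossover_length <- function(helix = helical_params()) {
  gap <- 180 - abs(helix$twist)
  if (gap == 0) stop("|twist| = 180: no crossover")
  helix$rise * 180 / gap
}

#' Net rotation equivalent to an n-subunit axial translation
#'
#' Because of helical symmetry, translating a filament by `n` subunits is
#' equivalent to rotating it by `n * twist`; this returns that rotation
#' reduced to `(-180, 180]`. For the default twist, `n = 2` gives +26.6
#' degrees (often quoted rounded as 26.7), the rotation that exchanges a
#' one-strand-subunit shift for a pure spin.
#'
#' @param helix a [helical_params()].
#' @param n_subunits integer number of subunits translated.
#' @return degrees in `(-180, 180]`.
#' @export
equivalent_rotation <- function(helix = helical_params(), n_subunits = 1) {
  wrap_180(n_subunits * helix$twist)
}

#' Hexagonal bundle lattices
#'
#' `hex_lattice(rings)` builds a centred hexagon: a central site plus
#' `rings` full rings, `3k^2 + 3k + 1` sites in total, at the given
#' nearest-neighbour spacing. `row_lattice(rows)` builds hexagonally
#' offset horizontal rows (e.g. `c(7, 8, 7)` gives the 22-filament
#' three-layer bundle).
#'
#' @param rings number of rings around the centre (>= 0).
#' @param rows integer vector of row lengths, all >= 1.
#' @param spacing nearest-neighbour axis-to-axis distance, nm
#'   (default 12.15).
#' @return an object of class `lattice_spec`: a list with `spacing` and a
#'   two-column `positions` matrix (nm), one row per lattice site.
#' @export
hex_lattice <- function(rings = 1, spacing = 12.15) {
  stopifnot(rings >= 0, spacing > 0)
  pts <- matrix(c(0, 0), ncol = 2)
  if (rings >= 1) {
    # axial coordinates of a hex grid, rings 1..k
    for (k in seq_len(rings)) {
      corner <- t(sapply(0:5, function(c6) {
        a <- deg2rad(60 * c6)
        k * spacing * c(cos(a), sin(a))
      }))
      for (c6 in 0:5) {
        a <- corner[c6 + 1, ]
        b <- corner[(c6 + 1) %% 6 + 1, ]
        for (s in 0:(k - 1)) pts <- rbind(pts, a + (b - a) * s / k)
      }
    }
  }
  structure(list(spacing = spacing, positions = unname(pts),
                 layout = sprintf("centered_hexagon(%d)", rings)),
            class = "lattice_spec")
}

#' @rdname hex_lattice
#' @export
row_lattice <- function(rows, spacing = 12.15) {
  stopifnot(length(rows) >= 1, spacing > 0)
  if (any(rows < 1)) stop("row lengths must all be >= 1")
  pts <- NULL
  s <- 0   # per-row half-offset keeping adjacent rows hex-nested
  for (r in seq_along(rows)) {
    n <- rows[r]
    if (r > 1) {
      # adjacent centred rows must sit half a spacing apart laterally
      s <- (s + (n - rows[r - 1]) / 2 + 0.5) %% 1
    }
    x <- ((seq_len(n) - 1) - (n - 1) / 2 + s) * spacing
    y <- rep((r - 1) * spacing * sqrt(3) / 2, n)
    pts <- rbind(pts, cbind(x, y))
  }
  pts[, 2] <- pts[, 2] - mean(range(pts[, 2]))
  structure(list(spacing = spacing, positions = unname(pts),
                 layout = sprintf("rows(%s)", paste(rows, collapse = ","))),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Bundle lattice %s: %d sites, spacing %.4g nm\n",
              x$layout, nrow(x$positions), x$spacing))
  invisible(x)
}

#' Enumerate bridgeable filament pairs
#'
#' Returns every unordered pair of lattice positions whose axis-to-axis
#' distance lies within `spacing +/- tol` -- the pairs a fascin
#' crossbridge can span. The default tolerance (0.5 nm) is far below the
#' gap to the second-neighbour distance (`sqrt(3) * spacing`).
#'
#' @param positions two-column matrix of (x, y) positions in nm, or a
#'   `lattice_spec`.
#' @param spacing target spacing, nm.
#' @param tol admissible deviation, nm (> 0).
#' @return integer matrix with columns `a`, `b` (row indices into
#'   `positions`, `a < b`), one row per bridgeable pair.
#' @export
bridgeable_pairs <- function(positions, spacing = 12.15, tol = 0.5) {
  if (inherits(positions, "lattice_spec")) {
    spacing <- positions$spacing
    positions <- positions$positions
  }
  stopifnot(tol > 0)
  n <- nrow(positions)
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("a", "b"))))
  d <- as.matrix(stats::dist(positions))
  hit <- which(abs(d - spacing) <= tol & upper.tri(d), arr.ind = TRUE)
  out <- cbind(a = as.integer(hit[, 1]), b = as.integer(hit[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Rotational phase shift between two filaments
#'
#' The axial rotation required to superimpose `other` onto `reference`,
#' viewed from the minus (pointed) end. With filament axes along +z and
#' barbed ends toward +z, the minus-end view looks along -z, so a
#' positive phase shift is counterclockwise in that view.
#'
#' @param reference,other [filament()] objects sharing helical parameters
#'   and axial register.
#' @return degrees in `(-180, 180]`.
#' @export
rotational_phase_shift <- function(reference, other) {
  if (!isTRUE(all.equal(reference$axial_offset, other$axial_offset)))
    stop("filaments must share axial register")
  wrap_180(other$rotation - reference$rotation)
}
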