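#' Crossbridge score parameters from a reference geometry
#'
#' Supplies the five (mu, sigma) pairs that parameterize crossbridge
#' scoring. Two modes exist:
#'
#' * `"idealized"` (default): all five mu are measured on the reference
#'   crossbridge -- an in-register filament pair (equal rotations, zero
#'   axial offset) at the standard spacing, up pose, at the candidate
#'   `(i, j)` whose four fiducial distances have the smallest mean. The
#'   optimum is then recentred on the filament midpoint through the
#'   exact helical screw equivalence (rotating both filaments by
#'   `k * twist` shifts the optimal indices by `-k` at identical
#'   geometry), so the reference bond sits clear of the filament ends;
#'   the common reference rotation is returned in the `reference`
#'   attribute. sigma_1..sigma_4 are 5% of the corresponding mu; the
#'   plane distance keeps sigma_5 = 0.25 nm. By construction the
#'   reference bond scores exactly `P = 1`.
#' * `"experimental"`: loads a transcribed experimental (mu, sigma) table from
#'   `inst/extdata/score_params_experimental.csv` if present. The table is not
#'   distributed with the package; requesting this mode without it is an
#'   error pointing at the transcription instructions.
#'
#' @param mode `"idealized"` or `"experimental"`.
#' @param fid a [fiducial_geometry()].
#' @param helix a [helical_params()].
#' @param spacing inter-axis distance of the reference pair, nm.
#' @param n_protomers filament length used for the reference pair.
#' @param m,tau sweep/threshold parameters stored in the result.
#' @return a [score_params()] whose `set` records the mode; idealized
#'   results also carry a `reference` attribute (`i`, `j`, `theta`, the
#'   five distances, spacing and filament length).
#' @export
synth_score_params <- function(mode = c("idealized", "experimental"),
                               fid = fiducial_geometry(),
                               helix = helical_params(), spacing = 12.15,
                               n_protomers = 16, m = 4, tau = 0.4) {
  mode <- match.arg(mode)
  if (mode == "experimental") {
    path <- system.file("extdata", "score_params_experimental.csv",
                        package = "fascinet")
    if (!nzchar(path) || !file.exists(path)) {
      stop("the experimental (mu, sigma) table is not packaged; ",
           "transcribe it to inst/extdata/score_params_experimental.csv ",
           "following inst/extdata/score_params_experimental_README.md, ",
           "or use mode = \"idealized\"", call. = FALSE)
    }
    tab <- utils::read.csv(path, comment.char = "#")
    return(score_params(tab$mu, tab$sigma, m = m, tau = tau, set = "experimental"))
  }
  filA <- filament(1L, c(0, 0), 0, n_protomers)
  filB <- filament(2L, c(spacing, 0), 0, n_protomers)
  best <- NULL
  for (i in seq_len(n_protomers - 2) - 1L) {
    for (j in seq_len(n_protomers - 3) - 1L) {
      d <- candidate_distances(filA, i, filB, j, helix, fid)
      if (is.null(best) || mean(d[1:4]) < best$score - 1e-12) {
        best <- list(score = mean(d[1:4]), i = i, j = j, d = d)
      }
    }
  }
  # recentre via the screw equivalence: candidate (i - k, j - k) at
  # common rotation k * twist has identical geometry
  k <- round((best$i + best$j + 3) / 2 - (n_protomers - 1) / 2)
  k <- max(min(k, best$i, best$j),
           best$i - (n_protomers - 3), best$j - (n_protomers - 4))
  theta_ref <- wrap_360(k * helix$twist)
  i_ref <- best$i - k
  j_ref <- best$j - k
  fA <- filament(1L, c(0, 0), theta_ref, n_protomers)
  fB <- filament(2L, c(spacing, 0), theta_ref, n_protomers)
  d_ref <- candidate_distances(fA, i_ref, fB, j_ref, helix, fid)
  mu <- d_ref
  sigma <- c(0.05 * d_ref[1:4], 0.25)
  out <- score_params(mu, sigma, m = m, tau = tau, set = "idealized")
  attr(out, "reference") <- list(i = i_ref, j = j_ref, d = d_ref,
                                 theta = theta_ref, spacing = spacing,
                                 n_protomers = n_protomers)
  out
}

# All candidate bonds between two filaments sorted by decreasing P
# (ties: up pose first, then i, then j) -- used to plant bridges while
# honouring protomer occupancy.
.sorted_bonds <- function(filA, filB, params, helix, fid) {
  rows <- list()
  for (pose in c("up", "down")) {
    a <- if (pose == "up") filA else filB
    b <- if (pose == "up") filB else filA
    for (i in seq_len(a$n_protomers - 2) - 1L) {
      for (j in seq_len(b$n_protomers - 3) - 1L) {
        P <- bond_probability(candidate_distances(a, i, b, j, helix, fid),
                              params)
        if (P >= params$tau)
          rows[[length(rows) + 1L]] <- data.frame(
            pose = pose, i = i, j = j, P = P, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df[order(-df$P, df$pose != "up", df$i, df$j), , drop = FALSE]
}

#' Bundle with planted filament rotations
#'
#' Builds a single actin plane (one row of bridgeable filaments) whose
#' rotations follow a planted pattern, then decorates every interface
#' with the highest-probability fascin bonds compatible with the
#' one-bond-per-protomer rule. The planted pattern is attached as
#' ground truth for closed-loop testing.
#'
#' Patterns: `"registered"` -- all rotations 0 (linear crossband);
#' `"slanted"` -- consecutive one-subunit-equivalent negative rotations;
#' `"chevron"` -- negative rotations up to a turning filament, then
#' positive; `"random"` -- uniform rotations.
#'
#' @param pattern one of `"registered"`, `"slanted"`, `"chevron"`,
#'   `"random"`.
#' @param n_filaments number of co-planar filaments (>= 3).
#' @param seed integer seed (used by `"random"` and recorded always).
#' @param n_protomers protomers per filament (default 21, about 1.5
#'   crossovers, so the axially drifting bonds of a slanted chain stay
#'   clear of the filament ends).
#' @param params a [score_params()].
#' @param helix,fid geometry.
#' @param max_bonds_per_pair cap on planted bonds per interface
#'   (default 1, the observed density of one fascin per interface per
#'   crossover).
#' @return a `fascin_bundle` with attribute `planted` (list with
#'   `pattern`, `rotations`, `seed`).
#' @export
synth_bundle_coords <- function(pattern = c("registered", "slanted",
                                            "chevron", "random"),
                                n_filaments = 5, seed = 1,
                                n_protomers = 21,
                                params = synth_score_params(),
                                helix = helical_params(),
                                fid = fiducial_geometry(),
                                max_bonds_per_pair = 1) {
  pattern <- match.arg(pattern)
  stopifnot(n_filaments >= 3)
  set.seed(seed)
  unit <- -abs(equivalent_rotation(helix, 2))  # about -26.6 deg
  # "registered" means all filaments share the reference rotation of
  # the score set (bonds then form mid-filament); patterns offset it
  base <- attr(params, "reference")$theta
  if (is.null(base)) base <- 0
  rot <- base + switch(pattern,
    registered = rep(0, n_filaments),
    slanted = cumsum(c(0, rep(unit, n_filaments - 1))),
    chevron = {
      turn <- ceiling(n_filaments / 2)
      steps <- c(0, rep(unit, turn - 1), rep(-unit, n_filaments - turn))
      cumsum(steps)
    },
    random = stats::runif(n_filaments, 0, 360) - base)
  lat <- row_lattice(n_filaments)
  cfg <- assembly_config(lat, n_filaments = n_filaments,
                         n_protomers = n_protomers, params = params,
                         helix = helix, fid = fid, seed = seed)
  bundle <- structure(list(filaments = list(), crossbridges = NULL,
                           occupancy = list(), cfg = cfg),
                      class = "fascin_bundle")
  for (k in seq_len(n_filaments)) {
    fil <- filament(k, lat$positions[k, ], rot[k], n_protomers)
    bundle <- .add_filament(bundle, fil, NULL)
  }
  for (k in seq_len(n_filaments - 1L)) {
    filA <- bundle$filaments[[k]]
    filB <- bundle$filaments[[k + 1L]]
    cand <- .sorted_bonds(filA, filB, params, helix, fid)
    if (is.null(cand)) next
    placed <- 0L
    for (r in seq_len(nrow(cand))) {
      if (placed >= max_bonds_per_pair) break
      abs1 <- if (cand$pose[r] == "up") filA$id else filB$id
      abs2 <- if (cand$pose[r] == "up") filB$id else filA$id
      p1 <- .abs1_protomers(cand$i[r])
      p2 <- .abs2_protomers(cand$j[r])
      if (any(p1 %in% bundle$occupancy[[as.character(abs1)]]) ||
          any(p2 %in% bundle$occupancy[[as.character(abs2)]])) next
      bundle$occupancy[[as.character(abs1)]] <-
        c(bundle$occupancy[[as.character(abs1)]], p1)
      bundle$occupancy[[as.character(abs2)]] <-
        c(bundle$occupancy[[as.character(abs2)]], p2)
      bundle$crossbridges <- rbind(
        bundle$crossbridges,
        data.frame(abs1_fil = abs1, abs2_fil = abs2,
                   i = cand$i[r], j = cand$j[r], P = cand$P[r]))
      placed <- placed + 1L
    }
  }
  bundle$crossbridges <- .canonical_bridges(bundle$crossbridges)
  attr(bundle, "planted") <- list(pattern = pattern, rotations = rot,
                                  seed = seed)
  bundle
}

#' Default multibody amplitude model
#'
#' Six eigenvectors with unit variances and zero means, the first three
#' masked as rotational -- the minimal structure of a multibody
#' amplitude analysis.
#'
#' @param n_eigen total eigenvectors.
#' @param n_rotational how many are rotational (masked in).
#' @return an [eigen_model()].
#' @export
default_eigen_model <- function(n_eigen = 6, n_rotational = 3) {
  stopifnot(n_rotational >= 1, n_rotational <= n_eigen)
  eigen_model(mean = rep(0, n_eigen), covariance = diag(n_eigen),
              mask = seq_len(n_eigen) <= n_rotational)
}

#' Synthetic multibody eigen amplitudes with planted outliers
#'
#' Samples particle amplitude vectors from the model's Gaussian,
#' rescales a planted fraction of them away from the mean (high-strain
#' crossbridges), and attaches Mahalanobis deviations plus uniform 3D
#' positions for spatial mapping.
#'
#' @param n_particles number of particles.
#' @param model an [eigen_model()].
#' @param outlier_fraction fraction of planted outliers in `[0, 1)`.
#' @param outlier_scale amplitude scale factor applied to outliers.
#' @param seed integer seed.
#' @param box length-3 extents (nm) of the uniform position box.
#' @return data.frame: `particle`, `x`, `y`, `z`, `amp.1..amp.p`,
#'   `deviation`, `is_outlier`.
#' @export
synth_eigen_amplitudes <- function(n_particles, model = default_eigen_model(),
                                   outlier_fraction = 0, outlier_scale = 5,
                                   seed = 1, box = c(400, 100, 100)) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 1)
  set.seed(seed)
  p <- length(model$mean)
  amp <- MASS::mvrnorm(n_particles, model$mean, model$covariance)
  amp <- matrix(amp, ncol = p)
  n_out <- floor(outlier_fraction * n_particles)
  is_out <- rep(FALSE, n_particles)
  if (n_out > 0) {
    idx <- sample(n_particles, n_out)
    is_out[idx] <- TRUE
    ctr <- matrix(model$mean, n_out, p, byrow = TRUE)
    amp[idx, ] <- ctr + outlier_scale * (amp[idx, , drop = FALSE] - ctr)
  }
  out <- data.frame(particle = seq_len(n_particles),
                    x = stats::runif(n_particles, 0, box[1]),
                    y = stats::runif(n_particles, 0, box[2]),
                    z = stats::runif(n_particles, 0, box[3]))
  colnames(amp) <- paste0("amp.", seq_len(p))
  out <- cbind(out, amp)
  out$deviation <- mahalanobis_distance(amp, model)
  out$is_outlier <- is_out
  attr(out, "seed") <- seed
  out
}

#' Synthetic bundle graph with planted clusters
#'
#' Emulates one well-ordered bundle region: `n_filaments` hexagonally
#' packed in three layers, partitioned into `k_clusters` planted
#' contiguous clusters (the defaults -- 24 filaments, 3 clusters of 8 --
#' match the scale of stable clusters observed at the modularity peak
#' of experimental bundles). Within-cluster interfaces carry dense,
#' low-strain crossbridges (near-complete decoration, about one fascin
#' per crossover); every between-cluster interface has its score scaled
#' down by `weak_factor`, implemented by inflating the strain of
#' boundary bridges. The planted labels are returned for recovery
#' scoring.
#'
#' @param n_filaments number of filaments (nodes).
#' @param k_clusters number of planted clusters (>= 1). Note that
#'   plain Newman modularity cannot resolve fewer than about three
#'   clusters at this graph size (the resolution limit): planted
#'   structure at `k_clusters = 2` is genuinely subdivided by the
#'   modularity optimum, whichever algorithm maximizes it.
#' @param weak_factor multiplicative interface-score penalty on
#'   between-cluster edges, in (0, 1).
#' @param region_length interface length, nm.
#' @param seed integer seed.
#' @param bridges_mean mean within-interface crossbridge count (about
#'   one per crossover over the region by default; small jitter).
#' @param strain_mean,strain_sd Gaussian parameters of per-bridge
#'   Mahalanobis deviations on within-cluster interfaces.
#' @return list with `bridges` (per-crossbridge records: filament pair,
#'   position, deviation), `graph` (via [build_bundle_graph()]),
#'   `labels` (named planted membership), `positions`, `seed`.
#' @export
synth_bundle_graph <- function(n_filaments = 24, k_clusters = 3,
                               weak_factor = 0.3, region_length = 400,
                               seed = 1, bridges_mean = 10,
                               strain_mean = 1.6, strain_sd = 0.3) {
  stopifnot(k_clusters >= 1, weak_factor > 0, weak_factor < 1)
  if (n_filaments < 2 * k_clusters)
    stop("n_filaments too small for ", k_clusters, " planted clusters")
  set.seed(seed)
  nr <- ceiling(n_filaments / 3)
  lat <- row_lattice(c(nr, nr, n_filaments - 2 * nr))
  pos <- lat$positions[seq_len(n_filaments), , drop = FALSE]
  # contiguous planted clusters: split along the bundle width
  o <- order(pos[, 1], pos[, 2])
  labels <- integer(n_filaments)
  labels[o] <- rep(seq_len(k_clusters),
                   diff(round(seq(0, n_filaments, length.out =
                                    k_clusters + 1))))
  pairs <- bridgeable_pairs(pos, lat$spacing)
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    between <- labels[a] != labels[b]
    N <- max(1L, round(stats::rnorm(1, bridges_mean, 1)))
    dev <- abs(stats::rnorm(N, strain_mean, strain_sd))
    if (between) {
      # scale the interface score by weak_factor: fis' = wf * fis
      # <=> 1 + Ebar' = (1 + Ebar) / wf, applied bridge-wise
      dev <- dev + (1 + mean(dev)) * (1 / weak_factor - 1)
    }
    mid <- (pos[a, ] + pos[b, ]) / 2
    rows[[length(rows) + 1L]] <- data.frame(
      filament_a = rep(a, N), filament_b = rep(b, N),
      x = rep(mid[1], N), y = rep(mid[2], N),
      z = sort(stats::runif(N, 0, region_length)),
      deviation = dev)
  }
  bridges <- do.call(rbind, rows)
  rownames(bridges) <- NULL
  graph <- build_bundle_graph(bridges, filaments = seq_len(n_filaments),
                              region_length = region_length)
  names(labels) <- as.character(seq_len(n_filaments))
  list(bridges = bridges, graph = graph, labels = labels,
       positions = pos, seed = seed)
}
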