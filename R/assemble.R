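#' Configuration for iterative bundle assembly
#'
#' @param lattice a `lattice_spec` ([hex_lattice()] / [row_lattice()]).
#' @param n_filaments number of filaments to place (defaults to the full
#'   lattice).
#' @param n_protomers protomers per filament: a single value, or a
#'   length-2 range from which each filament's length is drawn uniformly
#'   (the pairwise parameterization runs use `c(14, 19)`).
#' @param params a [score_params()].
#' @param helix a [helical_params()].
#' @param fid a [fiducial_geometry()].
#' @param theta_start,theta_end,theta_step rotation sweep grid for each
#'   added filament, degrees (defaults 0, 359.9, 0.1).
#' @param seed integer seed; every random draw in [assemble()] descends
#'   from it.
#' @param tol bridgeable-pair distance tolerance, nm.
#' @param first_site lattice row index where assembly starts, or `NULL`
#'   to pick a random site.
#' @param first_rotation absolute rotation of the first filament in
#'   degrees, or `NULL` to draw it uniformly (the default; bundle-element
#'   runs fix it to scan central-filament rotations).
#' @return an object of class `assembly_config`.
#' @export
assembly_config <- function(lattice, n_filaments = nrow(lattice$positions),
                            n_protomers = 16, params = synth_score_params(),
                            helix = helical_params(),
                            fid = fiducial_geometry(),
                            theta_start = 0, theta_end = 359.9,
                            theta_step = 0.1, seed = 1, tol = 0.5,
                            first_site = NULL, first_rotation = NULL) {
  stopifnot(inherits(lattice, "lattice_spec"), theta_step > 0,
            theta_end < 360, n_filaments >= 1)
  if (n_filaments > nrow(lattice$positions))
    stop("lattice exhausted: ", n_filaments, " filaments requested but only ",
         nrow(lattice$positions), " sites available")
  structure(list(lattice = lattice, n_filaments = as.integer(n_filaments),
                 n_protomers = n_protomers, params = params, helix = helix,
                 fid = fid, theta = list(start = theta_start, end = theta_end,
                                         step = theta_step),
                 seed = as.integer(seed), tol = tol,
                 first_site = first_site, first_rotation = first_rotation),
            class = "assembly_config")
}

.theta_grid <- function(cfg)
  seq(cfg$theta$start, cfg$theta$end, by = cfg$theta$step)

# protomers occupied by a bond on the ABS1-side / ABS2-side filament
.abs1_protomers <- function(i) c(i, i + 2L)
.abs2_protomers <- function(j) c(j + 1L, j + 3L)

#' Optimal rotation for a newly added filament
#'
#' Sweeps the rotation of a filament placed at `position` over the
#' configured angle grid. At each angle every candidate bond with
#' `P >= tau` against every bridgeable neighbour is nominated;
#' one-bond-per-protomer conflicts are resolved greedily by descending
#' `P`; the angle is scored by the summed probability of its accepted
#' bonds. The angle with the maximal overall score wins (ties go to the
#' smallest angle). If no angle admits any bond, a uniformly random
#' rotation is drawn from the current RNG stream and no bonds form.
#'
#' @param bundle a `fascin_bundle` under construction (see [assemble()]).
#' @param position length-2 lattice position of the new filament, nm.
#' @param cfg an [assembly_config()].
#' @param n_protomers protomer count for the new filament.
#' @return a list with `theta` (degrees), `score`, and `bonds` -- a
#'   data.frame (possibly empty) with columns `neighbor`, `abs1_on_new`,
#'   `i`, `j`, `P`.
#' @export
optimize_new_filament <- function(bundle, position, cfg,
                                  n_protomers = NULL) {
  if (is.null(n_protomers)) n_protomers <- .draw_n_protomers(cfg)
  nb_idx <- which(vapply(bundle$filaments, function(f) {
    d <- sqrt(sum((f$position - position)^2))
    abs(d - cfg$lattice$spacing) <= cfg$tol
  }, TRUE))
  if (!length(nb_idx))
    stop("new filament position has no bridgeable neighbour")
  theta_deg <- .theta_grid(cfg)
  all_cands <- list()
  hits <- NULL
  for (ni in nb_idx) {
    nb <- bundle$filaments[[ni]]
    occ <- bundle$occupancy[[as.character(nb$id)]]
    for (abs1_on_new in c(FALSE, TRUE)) {
      cands <- .pair_candidates(nb, position, n_protomers, 0,
                                new_is_abs2 = !abs1_on_new,
                                cfg$helix, cfg$fid, cfg$params)
      if (!length(cands)) next
      # drop candidates touching already-occupied neighbour protomers
      keep <- vapply(cands, function(cn) {
        pk <- if (abs1_on_new) .abs2_protomers(cn$j) else
          .abs1_protomers(cn$i)
        !any(pk %in% occ)
      }, TRUE)
      cands <- cands[keep]
      if (!length(cands)) next
      sw <- .sweep_candidates(cands, theta_deg, cfg$params)
      if (nrow(sw$hits)) {
        base <- length(all_cands)
        sw$hits$cand <- sw$hits$cand + base
        hits <- rbind(hits, sw$hits)
      }
      all_cands <- c(all_cands, lapply(cands, function(cn) {
        cn$neighbor <- nb$id; cn$neighbor_idx <- ni; cn
      }))
    }
  }
  empty_bonds <- data.frame(neighbor = integer(0), abs1_on_new = logical(0),
                            i = integer(0), j = integer(0), P = numeric(0))
  if (is.null(hits) || !nrow(hits)) {
    return(list(theta = stats::runif(1, 0, 360), score = 0,
                bonds = empty_bonds))
  }
  # deterministic greedy order: P desc, then neighbour id, pose "up"
  # (ABS1 on the existing filament) first, then i, then j
  ord_key <- vapply(all_cands, function(cn)
    cn$neighbor * 1e6 + cn$abs1_on_new * 5e5 + cn$i * 1e3 + cn$j, 0)
  # occupancy keys: filament slot * 1000 + protomer (slot 0 = new filament)
  occ_keys <- vapply(all_cands, function(cn) {
    if (cn$abs1_on_new) {
      c(.abs1_protomers(cn$i), cn$neighbor * 1000L + .abs2_protomers(cn$j))
    } else {
      c(.abs2_protomers(cn$j), cn$neighbor * 1000L + .abs1_protomers(cn$i))
    }
  }, integer(4))
  hc <- hits$cand
  ht <- hits$theta_idx
  hp <- hits$P
  o <- order(ht, -hp, ord_key[hc])
  hc <- hc[o]; ht <- ht[o]; hp <- hp[o]
  best_score <- -Inf
  best_theta_idx <- NA_integer_
  best_sel <- integer(0)
  r <- 1L
  n_hits <- length(hc)
  while (r <= n_hits) {
    ti <- ht[r]
    used <- integer(0)
    sel <- integer(0)
    score <- 0
    while (r <= n_hits && ht[r] == ti) {
      k <- occ_keys[, hc[r]]
      if (!any(k %in% used)) {
        used <- c(used, k)
        sel <- c(sel, r)
        score <- score + hp[r]
      }
      r <- r + 1L
    }
    if (score > best_score + 1e-12) {
      best_score <- score
      best_theta_idx <- ti
      best_sel <- sel
    }
  }
  bonds <- do.call(rbind, lapply(best_sel, function(s) {
    cn <- all_cands[[hc[s]]]
    data.frame(neighbor = cn$neighbor, abs1_on_new = cn$abs1_on_new,
               i = cn$i, j = cn$j, P = hp[s])
  }))
  list(theta = theta_deg[best_theta_idx], score = best_score, bonds = bonds)
}

.draw_n_protomers <- function(cfg) {
  np <- cfg$n_protomers
  if (length(np) == 2L) sample(seq(np[1], np[2]), 1L) else as.integer(np)
}

# Order in which lattice sites are filled: start from `first`, then
# repeatedly take the unplaced site with the most already-placed
# bridgeable neighbours (>= 2 required after the second filament),
# breaking ties by distance from the first site, then by angle.
.addition_order <- function(lattice, n_filaments, first, tol) {
  pos <- lattice$positions
  n <- nrow(pos)
  pairs <- bridgeable_pairs(pos, lattice$spacing, tol)
  adj <- lapply(seq_len(n), function(k)
    c(pairs[pairs[, 1] == k, 2], pairs[pairs[, 2] == k, 1]))
  placed <- first
  d0 <- sqrt(rowSums((pos - matrix(pos[first, ], n, 2, byrow = TRUE))^2))
  ang <- atan2(pos[, 2] - pos[first, 2], pos[, 1] - pos[first, 1])
  while (length(placed) < n_filaments) {
    open <- setdiff(seq_len(n), placed)
    nnb <- vapply(open, function(k) sum(adj[[k]] %in% placed), 0L)
    need <- if (length(placed) == 1L) 1L else 2L
    ok <- open[nnb >= need]
    if (!length(ok))
      stop("no remaining lattice site has ", need,
           " placed bridgeable neighbours")
    ok <- ok[order(-nnb[match(ok, open)], d0[ok], ang[ok])]
    placed <- c(placed, ok[1])
  }
  placed
}

#' Assemble a fascin-crosslinked bundle
#'
#' Iteratively builds a bundle on the configured lattice: the first
#' filament receives a random absolute rotation; each subsequent
#' filament is placed on the next lattice site honouring the
#' two-bridgeable-neighbours rule (one neighbour for the second
#' filament) and rotated by [optimize_new_filament()]. Accepted bonds
#' never change afterwards, and no protomer ever carries more than one
#' fascin.
#'
#' @param cfg an [assembly_config()].
#' @return an object of class `fascin_bundle`: a list with `filaments`
#'   (list of [filament()]), `crossbridges` (data.frame with one row per
#'   fascin: `filament_a < filament_b`, ABS1-side index `i`, ABS2-side
#'   index `j`, `pose` -- `"up"` when ABS1 engages `filament_a` --, `P`,
#'   `Ec`), `occupancy`, and the configuration used.
#' @export
assemble <- function(cfg) {
  stopifnot(inherits(cfg, "assembly_config"))
  set.seed(cfg$seed)
  first <- if (is.null(cfg$first_site))
    sample(nrow(cfg$lattice$positions), 1L) else as.integer(cfg$first_site)
  order_idx <- .addition_order(cfg$lattice, cfg$n_filaments, first, cfg$tol)
  bundle <- structure(list(filaments = list(), crossbridges = NULL,
                           occupancy = list(), cfg = cfg),
                      class = "fascin_bundle")
  for (step in seq_along(order_idx)) {
    site <- cfg$lattice$positions[order_idx[step], ]
    np <- .draw_n_protomers(cfg)
    if (step == 1L) {
      rot0 <- if (is.null(cfg$first_rotation))
        stats::runif(1, 0, 360) else cfg$first_rotation
      fil <- filament(step, site, rot0, np)
      bundle <- .add_filament(bundle, fil, NULL)
    } else {
      opt <- optimize_new_filament(bundle, site, cfg, np)
      fil <- filament(step, site, opt$theta, np)
      bundle <- .add_filament(bundle, fil, opt$bonds)
    }
  }
  bundle$crossbridges <- .canonical_bridges(bundle$crossbridges)
  bundle
}

.add_filament <- function(bundle, fil, bonds) {
  bundle$filaments[[length(bundle$filaments) + 1L]] <- fil
  bundle$occupancy[[as.character(fil$id)]] <- integer(0)
  if (!is.null(bonds) && nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      b <- bonds[r, ]
      if (b$abs1_on_new) {
        abs1 <- fil$id; abs2 <- b$neighbor
      } else {
        abs1 <- b$neighbor; abs2 <- fil$id
      }
      bundle$occupancy[[as.character(abs1)]] <-
        c(bundle$occupancy[[as.character(abs1)]], .abs1_protomers(b$i))
      bundle$occupancy[[as.character(abs2)]] <-
        c(bundle$occupancy[[as.character(abs2)]], .abs2_protomers(b$j))
      bundle$crossbridges <- rbind(
        bundle$crossbridges,
        data.frame(abs1_fil = abs1, abs2_fil = abs2, i = b$i, j = b$j,
                   P = b$P))
    }
  }
  bundle
}

# Canonicalize bridge records: filament_a < filament_b, pose relative to
# that ordering ("up" = ABS1 on filament_a), plus Ec.
.canonical_bridges <- function(raw) {
  if (is.null(raw) || !nrow(raw)) {
    return(data.frame(filament_a = integer(0), filament_b = integer(0),
                      i = integer(0), j = integer(0),
                      pose = character(0), P = numeric(0), Ec = numeric(0),
                      stringsAsFactors = FALSE))
  }
  up <- raw$abs1_fil < raw$abs2_fil
  out <- data.frame(
    filament_a = ifelse(up, raw$abs1_fil, raw$abs2_fil),
    filament_b = ifelse(up, raw$abs2_fil, raw$abs1_fil),
    i = raw$i, j = raw$j,
    pose = ifelse(up, "up", "down"),
    P = raw$P, Ec = -1 / raw$P, stringsAsFactors = FALSE)
  out[order(out$filament_a, out$filament_b, out$i), , drop = FALSE]
}

#' @export
print.fascin_bundle <- function(x, ...) {
  cat(sprintf("Fascin-crosslinked bundle: %d filaments, %d crossbridges\n",
              length(x$filaments), nrow(x$crossbridges)))
  if (nrow(x$crossbridges))
    cat(sprintf("  P range [%.3f, %.3f]; poses: %s\n",
                min(x$crossbridges$P), max(x$crossbridges$P),
                paste(names(table(x$crossbridges$pose)),
                      table(x$crossbridges$pose), collapse = ", ",
                      sep = ":")))
  invisible(x)
}

#' @export
summary.fascin_bundle <- function(object, ...) {
  rot <- vapply(object$filaments, `[[`, 0, "rotation")
  ref <- object$filaments[[1]]
  shifts <- vapply(object$filaments, rotational_phase_shift,
                   reference = ref, FUN.VALUE = 0)
  structure(list(n_filaments = length(object$filaments),
                 n_crossbridges = nrow(object$crossbridges),
                 rotations = rot, phase_shifts = shifts,
                 P = object$crossbridges$P,
                 pose = table(object$crossbridges$pose)),
            class = "summary.fascin_bundle")
}

#' @export
print.summary.fascin_bundle <- function(x, ...) {
  cat(sprintf("Bundle of %d filaments, %d fascin crossbridges\n",
              x$n_filaments, x$n_crossbridges))
  cat("Phase shifts vs filament 1 (deg):\n")
  print(round(x$phase_shifts, 1))
  if (length(x$P)) {
    cat("Crossbridge P: ")
    print(summary(x$P))
  }
  invisible(x)
}

#' @describeIn assemble end-on view of the bundle: filament axes and
#'   crossbridged interfaces (line width by crossbridge count).
#' @param x a `fascin_bundle`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fascin_bundle <- function(x, ...) {
  pos <- t(vapply(x$filaments, `[[`, numeric(2), "position"))
  graphics::plot(pos, asp = 1, pch = 16, cex = 2, col = "grey40",
                 xlab = "x (nm)", ylab = "y (nm)", ...)
  cb <- x$crossbridges
  if (nrow(cb)) {
    cnt <- stats::aggregate(P ~ filament_a + filament_b, cb, length)
    for (r in seq_len(nrow(cnt))) {
      a <- pos[cnt$filament_a[r], ]; b <- pos[cnt$filament_b[r], ]
      graphics::segments(a[1], a[2], b[1], b[2], lwd = cnt$P[r],
                         col = "tomato")
    }
  }
  graphics::text(pos[, 1], pos[, 2],
                 labels = vapply(x$filaments, `[[`, 0L, "id"),
                 col = "white", cex = 0.7)
  invisible(x)
}

#' Pairwise rotation-angle energy landscape
#'
#' Maps the best-bond probability, energy and pose of a filament pair at
#' the configured spacing over a grid of the two absolute rotation
#' angles. Cells where the best candidate misses `tau` hold `Ec = 0`.
#'
#' @param theta_a,theta_b rotation grids in degrees (default 0-180 in
#'   1-degree steps).
#' @param n_protomers protomers per filament (default 14, one crossover).
#' @param spacing inter-axis distance, nm.
#' @param params a [score_params()].
#' @param helix a [helical_params()].
#' @param fid a [fiducial_geometry()].
#' @return an object of class `pair_landscape`: list with the two grids
#'   and matrices `P`, `Ec`, `pose` (rows indexed by `theta_a`).
#' @export
pairwise_landscape <- function(theta_a = seq(0, 180, 1),
                               theta_b = seq(0, 180, 1),
                               n_protomers = 14, spacing = 12.15,
                               params = synth_score_params(),
                               helix = helical_params(),
                               fid = fiducial_geometry()) {
  na <- length(theta_a); nb <- length(theta_b)
  P <- matrix(0, na, nb)
  pose <- matrix(NA_character_, na, nb)
  for (ai in seq_len(na)) {
    filA <- filament(1L, c(0, 0), theta_a[ai], n_protomers)
    cands <- c(.pair_candidates(filA, c(spacing, 0), n_protomers, 0,
                                new_is_abs2 = TRUE, helix, fid, params),
               .pair_candidates(filA, c(spacing, 0), n_protomers, 0,
                                new_is_abs2 = FALSE, helix, fid, params))
    if (!length(cands)) next
    cands <- .order_candidates(cands, up_first_on_new = FALSE)
    sw <- .sweep_candidates(cands, theta_b, params, tau = Inf)
    P[ai, ] <- sw$best_P
    has <- sw$best_cand > 0
    pose[ai, has] <- ifelse(
      vapply(cands[sw$best_cand[has]], `[[`, TRUE, "abs1_on_new"),
      "down", "up")
  }
  Ec <- ifelse(P >= params$tau, -1 / P, 0)
  structure(list(theta_a = theta_a, theta_b = theta_b, P = P, Ec = Ec,
                 pose = pose, params = params, spacing = spacing,
                 n_protomers = n_protomers),
            class = "pair_landscape")
}

#' @export
print.pair_landscape <- function(x, ...) {
  nb <- sum(x$Ec < 0)
  cat(sprintf(
    "Pairwise landscape %d x %d cells: %d bonded (Ec < 0), %d empty\n",
    length(x$theta_a), length(x$theta_b), nb, length(x$Ec) - nb))
  invisible(x)
}

#' @describeIn pairwise_landscape image of the normalized energy
#'   landscape (bonded wells in colour, unbonded cells blank).
#' @param x a `pair_landscape`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pair_landscape <- function(x, ...) {
  z <- x$Ec
  z[z == 0] <- NA
  graphics::image(x$theta_a, x$theta_b, z,
                  xlab = expression(theta[A] * " (deg)"),
                  ylab = expression(theta[B] * " (deg)"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Parameterization sweep over m and tau
#'
#' Runs independent pairwise assemblies over a grid of the plasticity
#' factor `m` and the binding threshold `tau`: in each run filament A
#' receives a random rotation, filament B's rotation is optimized, and
#' whether a crossbridge formed is recorded. Filament lengths are drawn
#' uniformly from `n_protomers` per run.
#'
#' @param m_values,tau_values sweep grids (defaults 1-7 and 0.1-0.8).
#' @param runs independent runs per (m, tau) cell (default 50).
#' @param seed integer seed for the whole sweep.
#' @param base_params a [score_params()] supplying mu and sigma.
#' @param n_protomers length range for the pairwise filaments.
#' @param spacing inter-axis distance, nm.
#' @param theta_step sweep resolution for the optimized filament, deg.
#' @param helix,fid geometry, as elsewhere.
#' @return a data.frame of class `sweep_result` with one row per run:
#'   `m`, `tau`, `run`, `n_bonds`, `fraction` (bonded pairs / candidate
#'   pairs, here 0 or 1), `P_best`, `Ec_best` (0 when no bond).
#' @export
parameter_sweep <- function(m_values = 1:7,
                            tau_values = seq(0.1, 0.8, by = 0.1),
                            runs = 50, seed = 1,
                            base_params = synth_score_params(),
                            n_protomers = c(14, 19), spacing = 12.15,
                            theta_step = 0.1, helix = helical_params(),
                            fid = fiducial_geometry()) {
  stopifnot(runs >= 0)
  grid <- expand.grid(run = seq_len(runs), tau = tau_values, m = m_values)
  out <- vector("list", nrow(grid))
  set.seed(seed)
  lat <- row_lattice(2, spacing = spacing)
  for (g in seq_len(nrow(grid))) {
    pr <- score_params(base_params$mu, base_params$sigma,
                       m = grid$m[g], tau = grid$tau[g],
                       set = base_params$set)
    cfg <- assembly_config(lat, n_filaments = 2, n_protomers = n_protomers,
                           params = pr, helix = helix, fid = fid,
                           theta_step = theta_step, seed = seed)
    thetaA <- stats::runif(1, 0, 360)
    npA <- .draw_n_protomers(cfg)
    npB <- .draw_n_protomers(cfg)
    bundle <- structure(list(filaments = list(filament(1L, c(0, 0), thetaA,
                                                       npA)),
                             crossbridges = NULL,
                             occupancy = list(`1` = integer(0)), cfg = cfg),
                        class = "fascin_bundle")
    opt <- optimize_new_filament(bundle, c(spacing, 0), cfg, npB)
    nb <- nrow(opt$bonds)
    out[[g]] <- data.frame(m = grid$m[g], tau = grid$tau[g],
                           run = grid$run[g], n_bonds = nb,
                           fraction = as.numeric(nb > 0),
                           P_best = if (nb) max(opt$bonds$P) else 0,
                           Ec_best = if (nb) -1 / max(opt$bonds$P) else 0)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(m = numeric(0), tau = numeric(0), run = integer(0),
               n_bonds = integer(0), fraction = numeric(0),
               P_best = numeric(0), Ec_best = numeric(0))
  class(res) <- c("sweep_result", "data.frame")
  attr(res, "seed") <- seed
  res
}

#' Crossbridge-fraction summary of a parameter sweep
#'
#' @param sweep a `sweep_result` from [parameter_sweep()].
#' @return data.frame with one row per (m, tau) cell: `mean_fraction`,
#'   `median_fraction`, `runs`.
#' @export
crossbridge_fraction <- function(sweep) {
  if (!nrow(sweep)) {
    return(data.frame(m = numeric(0), tau = numeric(0),
                      mean_fraction = numeric(0),
                      median_fraction = numeric(0), runs = integer(0)))
  }
  agg <- stats::aggregate(fraction ~ m + tau, data = sweep, function(v)
    c(mean = mean(v), median = stats::median(v), runs = length(v)))
  data.frame(m = agg$m, tau = agg$tau,
             mean_fraction = agg$fraction[, "mean"],
             median_fraction = agg$fraction[, "median"],
             runs = as.integer(agg$fraction[, "runs"]))
}
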