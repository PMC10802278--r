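# Shared fixtures, memoized per test run.
.fx <- new.env(parent = emptyenv())

fx_helix <- function() {
  if (is.null(.fx$helix)) .fx$helix <- helical_params()
  .fx$helix
}

fx_fid <- function() {
  if (is.null(.fx$fid)) .fx$fid <- fiducial_geometry()
  .fx$fid
}

fx_params <- function() {
  if (is.null(.fx$sp)) .fx$sp <- synth_score_params()
  .fx$sp
}

# Independent brute-force maximizer for the filament-addition sweep:
# enumerates every candidate bond through candidate_distances() on a
# 1-degree grid, applies the same greedy occupancy rule, and returns
# the best angle and score. Shares no code with the sweep kernel.
oracle_optimize <- function(bundle, position, cfg, n_protomers,
                            step = 1) {
  helix <- cfg$helix; fid <- cfg$fid; params <- cfg$params
  nbs <- Filter(function(f) {
    d <- sqrt(sum((f$position - position)^2))
    abs(d - cfg$lattice$spacing) <= cfg$tol
  }, bundle$filaments)
  thetas <- seq(0, 360 - step, by = step)
  best <- list(score = -Inf, theta = NA)
  for (th in thetas) {
    newf <- filament(999L, position, th, n_protomers)
    cand <- NULL
    for (nb in nbs) {
      occ <- bundle$occupancy[[as.character(nb$id)]]
      for (i in seq_len(nb$n_protomers - 2) - 1L) {
        if (any(c(i, i + 2) %in% occ)) next
        for (j in seq_len(n_protomers - 3) - 1L) {
          P <- bond_probability(
            candidate_distances(nb, i, newf, j, helix, fid), params)
          if (P >= params$tau)
            cand <- rbind(cand, data.frame(nb = nb$id, P = P,
                                           pn = I(list(c(j + 1, j + 3))),
                                           pb = I(list(c(i, i + 2)))))
        }
      }
      for (i in seq_len(n_protomers - 2) - 1L) {
        for (j in seq_len(nb$n_protomers - 3) - 1L) {
          if (any(c(j + 1, j + 3) %in% occ)) next
          P <- bond_probability(
            candidate_distances(newf, i, nb, j, helix, fid), params)
          if (P >= params$tau)
            cand <- rbind(cand, data.frame(nb = nb$id, P = P,
                                           pn = I(list(c(i, i + 2))),
                                           pb = I(list(c(j + 1, j + 3)))))
        }
      }
    }
    score <- 0
    if (!is.null(cand)) {
      cand <- cand[order(-cand$P), , drop = FALSE]
      used_new <- integer(0)
      used_nb <- list()
      for (r in seq_len(nrow(cand))) {
        key <- as.character(cand$nb[r])
        if (any(cand$pn[[r]] %in% used_new) ||
            any(cand$pb[[r]] %in% used_nb[[key]])) next
        used_new <- c(used_new, cand$pn[[r]])
        used_nb[[key]] <- c(used_nb[[key]], cand$pb[[r]])
        score <- score + cand$P[r]
      }
    }
    if (score > best$score + 1e-12) best <- list(score = score, theta = th)
  }
  best
}

# Adjusted Rand index between two labelings (used when mclust is not
# the point of the test).
fx_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
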