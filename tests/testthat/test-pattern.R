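test_that("contact map tallies crossbridge anchors and conserves counts", {
  sp <- fx_params()
  cfg <- assembly_config(hex_lattice(1), n_filaments = 7, n_protomers = 16,
                         params = sp, seed = 3, first_site = 1,
                         first_rotation = 2)
  b <- assemble(cfg)
  cm <- contact_map(list(b))
  expect_equal(dim(cm), c(7, 16))
  expect_equal(rownames(cm), c(as.character(1:6), "7"))
  expect_equal(colnames(cm), LETTERS[1:16])
  # conservation: each bridge contributes one count on each filament
  expect_equal(sum(cm), 2 * nrow(b$crossbridges))
  # empty input
  expect_equal(sum(contact_map(list())), 0)
  # a single planted bond lands on exactly two cells
  b1 <- b
  b1$crossbridges <- b$crossbridges[1, , drop = FALSE]
  cm1 <- contact_map(list(b1))
  expect_equal(sum(cm1), 2)
  expect_equal(sum(cm1 > 0), 2)
  # protomer count must be 16
  cfg2 <- assembly_config(hex_lattice(1), n_filaments = 7, n_protomers = 14,
                          params = sp, seed = 3, first_site = 1,
                          first_rotation = 2)
  expect_error(contact_map(list(assemble(cfg2))), "16")
})

test_that("averaged contact maps keep three transversal layers", {
  sp <- fx_params()
  bundles <- lapply(1:5, function(k) {
    assemble(assembly_config(hex_lattice(1), n_filaments = 7,
                             n_protomers = 16, params = sp, seed = 100 + k,
                             first_site = 1,
                             first_rotation = (k - 1) * 2.5))
  })
  cm <- contact_map(bundles)
  expect_equal(sum(cm), 2 * sum(vapply(bundles, function(b)
    nrow(b$crossbridges), 0)))
  # sparse peaks: occupied protomer columns on the central filament
  # cluster into distinct axial positions rather than a uniform band
  central <- cm["7", ]
  expect_gt(sum(central > 0), 2)
  expect_lt(sum(central > 0), 16)
})

test_that("crossband classification recovers the canonical morphologies", {
  expect_equal(classify_crossband(c(0, 0, 0))$label, "linear")
  expect_equal(classify_crossband(c(-25, -25, -25))$label, "slanted")
  expect_equal(classify_crossband(c(-25, -25, 25, 25))$label, "chevron")
  # mirrored view canonicalizes to the same label
  expect_equal(classify_crossband(c(25, 25, -25, -25))$label, "chevron")
  expect_equal(classify_crossband(c(25, 25, 25))$label, "slanted")
  # mixed signs beyond one reversal, or out-of-bin shifts
  expect_equal(classify_crossband(c(-25, 25, -25))$label, "other")
  expect_equal(classify_crossband(c(-80, 0, 0))$label, "other")
  expect_error(classify_crossband(c(0)), "at least two")
})

test_that("planted crossband patterns are recovered exactly", {
  sp <- fx_params()
  for (pat in c("registered", "slanted", "chevron")) {
    b <- synth_bundle_coords(pat, n_filaments = 5, seed = 2, params = sp)
    cc <- classify_crossband(b, 1:5)
    want <- switch(pat, registered = "linear", slanted = "slanted",
                   chevron = "chevron")
    expect_equal(cc$label, want)
    expect_false(cc$flagged)
  }
  # an undecorated plane is flagged (random rotations cannot reach a
  # binding threshold this close to one)
  b0 <- synth_bundle_coords("random", n_filaments = 5, seed = 2,
                            params = score_params(fx_params()$mu,
                                                  fx_params()$sigma,
                                                  m = 4, tau = 0.999))
  cc0 <- classify_crossband(b0, 1:5)
  expect_true(cc0$flagged)
})

test_that("planted triplets reproduce the pose and offset rules", {
  sp <- fx_params()
  # rule 1: cumulative shift about 0 -> same pose, no axial offset
  reg <- extract_triplets(synth_bundle_coords("registered", 5, seed = 2,
                                              params = sp))
  expect_gt(nrow(reg), 0)
  expect_true(all(abs(reg$cumulative_shift) < 12.5))
  expect_true(all(reg$pose_match == "same"))
  expect_true(all(reg$axial_offset == 0))
  # rule 3: cumulative shift about -53 (two one-subunit-equivalent
  # rotations) -> same (down) pose, one full repeat offset
  sl <- extract_triplets(synth_bundle_coords("slanted", 5, seed = 2,
                                             params = sp))
  expect_gt(nrow(sl), 0)
  expect_true(all(abs(sl$cumulative_shift + 53.2) < 1))
  expect_true(all(sl$pose_match == "same"))
  expect_true(all(sl$axial_offset == 1))
  # chevron: slanted arms obey rule 3; the turning point is either the
  # strict rule-1 pattern or the wobble configuration (opposite poses,
  # half-repeat shift) that switches the crossband direction
  ch <- extract_triplets(synth_bundle_coords("chevron", 5, seed = 2,
                                             params = sp))
  expect_gt(nrow(ch), 0)
  turn <- abs(ch$cumulative_shift) < 12.5
  expect_true(any(turn) && any(!turn))
  expect_true(all((ch$pose_match[turn] == "same" &
                     ch$axial_offset[turn] == 0) |
                    (ch$pose_match[turn] == "opposite" &
                       ch$axial_offset[turn] == 0.5)))
  expect_true(all(ch$axial_offset[!turn] == 1 &
                    ch$pose_match[!turn] == "same"))
  # rule 2: a single one-subunit-equivalent cumulative rotation ->
  # opposite poses, half-repeat offset (planted directly)
  h <- fx_helix(); fid <- fx_fid()
  lat <- row_lattice(3)
  cfg <- assembly_config(lat, n_filaments = 3, n_protomers = 21,
                         params = sp, seed = 1)
  b <- structure(list(filaments = list(), crossbridges = NULL,
                      occupancy = list(), cfg = cfg),
                 class = "fascin_bundle")
  rots <- c(0, -13.3, -26.6)
  for (k in 1:3)
    b <- fascinet:::.add_filament(
      b, filament(k, lat$positions[k, ], rots[k], 21), NULL)
  raw <- NULL
  for (k in 1:2) {
    bb <- best_bond(b$filaments[[k]], b$filaments[[k + 1]], sp, h, fid)
    abs1 <- if (bb$pose == "up") k else k + 1
    abs2 <- if (bb$pose == "up") k + 1 else k
    raw <- rbind(raw, data.frame(abs1_fil = abs1, abs2_fil = abs2,
                                 i = bb$i, j = bb$j, P = bb$P))
  }
  b$crossbridges <- fascinet:::.canonical_bridges(raw)
  tt <- extract_triplets(b)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$cumulative_shift, -26.6, tolerance = 1e-6)
  expect_equal(tt$pose_match, "opposite")
  expect_equal(tt$axial_offset, 0.5)
})

test_that("triplet extraction is invariant under mirrored views", {
  sp <- fx_params()
  b <- synth_bundle_coords("chevron", 5, seed = 7, params = sp)
  tt <- extract_triplets(b)
  # reverse the filament order (mirror the plane) and re-extract
  bm <- b
  n <- length(b$filaments)
  pos <- t(vapply(b$filaments, `[[`, numeric(2), "position"))
  for (k in seq_len(n)) {
    bm$filaments[[k]] <- b$filaments[[n + 1 - k]]
    bm$filaments[[k]]$id <- k
    bm$filaments[[k]]$position <- pos[k, ]
  }
  cb <- b$crossbridges
  relabel <- function(id) n + 1L - id
  a2 <- relabel(cb$filament_a); b2 <- relabel(cb$filament_b)
  abs1 <- ifelse(cb$pose == "up", a2, b2)
  bm$crossbridges <- fascinet:::.canonical_bridges(data.frame(
    abs1_fil = abs1, abs2_fil = ifelse(cb$pose == "up", b2, a2),
    i = cb$i, j = cb$j, P = cb$P))
  tm <- extract_triplets(bm)
  key <- function(t) do.call(paste, c(t[order(t$cumulative_shift,
                                              t$axial_offset),
                                        c("cumulative_shift",
                                          "axial_offset", "pose_match")],
                                      sep = "|"))
  expect_equal(key(tm), key(tt))
})

test_that("triplet scatter aggregates across bundles", {
  sp <- fx_params()
  expect_equal(nrow(triplet_scatter(list())), 0)
  pair <- synth_bundle_coords("registered", 3, seed = 1, params = sp)
  pair$filaments <- pair$filaments[1:2]
  pair$crossbridges <- pair$crossbridges[
    pair$crossbridges$filament_b <= 2, , drop = FALSE]
  expect_equal(nrow(triplet_scatter(list(pair))), 0)
  two <- triplet_scatter(list(
    synth_bundle_coords("registered", 4, seed = 1, params = sp),
    synth_bundle_coords("slanted", 4, seed = 1, params = sp)))
  expect_true(all(c(1, 2) %in% two$bundle))
  expect_true(all(two$axial_offset %% 0.5 == 0))
  expect_true(all(two$cumulative_shift > -180 & two$cumulative_shift <= 180))
})
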