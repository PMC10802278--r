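test_that("Mahalanobis deviations match closed forms", {
  m2 <- eigen_model(mean = c(0, 0), covariance = diag(2))
  expect_equal(mahalanobis_distance(c(0, 0), m2), 0)
  expect_equal(mahalanobis_distance(c(1, 0), m2), 1)
  m4 <- eigen_model(mean = c(0, 0), covariance = diag(c(4, 9)))
  expect_equal(mahalanobis_distance(c(2, 3), m4), sqrt(2))
  # masked subspace: ignored coordinates do not contribute
  m3 <- eigen_model(mean = rep(0, 3), covariance = diag(3),
                    mask = c(TRUE, TRUE, FALSE))
  expect_equal(mahalanobis_distance(c(3, 4, 100), m3), 5)
  expect_error(mahalanobis_distance(c(1, 2, 3), m2), "dimension")
  sing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(eigen_model(c(0, 0), sing), "regulariz")
})

test_that("interface score arithmetic and monotonicity", {
  expect_equal(interface_score(0, 5, 0), 0)
  expect_equal(interface_score(4, 2, 1), 1)
  expect_equal(interface_score(1, 1, 0), 1)
  expect_error(interface_score(3, 0, 1), "L")
  # strictly decreasing in Ebar, strictly increasing in N
  e <- seq(0, 5, 0.5)
  expect_true(all(diff(interface_score(4, 400, e)) < 0))
  n <- 0:10
  s <- interface_score(n, 400, 1.5)
  expect_true(all(diff(s) > 0))
})

test_that("bundle graphs honour the at-least-one-bridge edge rule", {
  br <- data.frame(filament_a = c(1, 1, 1), filament_b = c(2, 2, 2),
                   x = 0, y = 0, z = c(10, 50, 90),
                   deviation = c(1, 2, 3))
  g <- build_bundle_graph(br, filaments = 1:3, region_length = 400)
  expect_equal(igraph::vcount(g), 3)   # isolated filament retained
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$N, 3)
  expect_equal(igraph::E(g)$Ebar, 2)
  expect_equal(igraph::E(g)$fis, (3 / 400) / (1 + 2))
  expect_error(build_bundle_graph(br, filaments = 1:1), "unknown filament")
  # generator round trip: edge set equals the planted adjacency
  gsy <- synth_bundle_graph(n_filaments = 12, k_clusters = 2, seed = 4)
  pairs <- bridgeable_pairs(gsy$positions, 12.15)
  g2 <- gsy$graph
  ends <- igraph::ends(g2, igraph::E(g2))
  got <- paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
               pmax(as.integer(ends[, 1]), as.integer(ends[, 2])))
  expect_setequal(got, paste(pairs[, 1], pairs[, 2]))
})

test_that("ward clustering splits planted cliques at the weak link", {
  # two 4-cliques of strong interfaces joined by one weak edge
  br <- NULL
  for (p in combn(1:4, 2, simplify = FALSE))
    br <- rbind(br, data.frame(filament_a = p[1], filament_b = p[2],
                               x = 0, y = 0, z = 1:10, deviation = 0.5))
  for (p in combn(5:8, 2, simplify = FALSE))
    br <- rbind(br, data.frame(filament_a = p[1], filament_b = p[2],
                               x = 0, y = 0, z = 1:10, deviation = 0.5))
  br <- rbind(br, data.frame(filament_a = 4, filament_b = 5, x = 0, y = 0,
                             z = 200, deviation = 12))
  g <- build_bundle_graph(br, filaments = 1:8, region_length = 400)
  cl <- hierarchical_cluster(g)
  hc <- cl[[1]]$hclust
  # final merge joins exactly the two cliques
  two <- cutree(hc, k = 2)
  expect_equal(length(unique(two[as.character(1:4)])), 1)
  expect_equal(length(unique(two[as.character(5:8)])), 1)
  expect_false(two[["1"]] == two[["8"]])
  # normalized heights live in [0, 1] with max exactly 1
  expect_true(all(hc$height >= 0 & hc$height <= 1 + 1e-12))
  expect_equal(max(hc$height), 1)
  expect_error(hierarchical_cluster(build_bundle_graph(
    data.frame(filament_a = 1, filament_b = 1, x = 0, y = 0, z = 0,
               deviation = 0)[0, ], filaments = 1)), "single-node")
})

test_that("joint normalization shares one distance axis across graphs", {
  g1 <- synth_bundle_graph(n_filaments = 12, seed = 1, k_clusters = 2)
  g2 <- synth_bundle_graph(n_filaments = 18, seed = 2, k_clusters = 2)
  cl <- hierarchical_cluster(list(g1$graph, g2$graph))
  hmax <- vapply(cl, function(d) max(d$hclust$height), 0)
  expect_equal(max(hmax), 1)
  expect_equal(cl[[1]]$max_height, cl[[2]]$max_height)
})

test_that("disconnected components merge at normalized distance one", {
  br <- rbind(
    data.frame(filament_a = 1, filament_b = 2, x = 0, y = 0, z = 1:5,
               deviation = 1),
    data.frame(filament_a = 3, filament_b = 4, x = 0, y = 0, z = 1:5,
               deviation = 1))
  g <- build_bundle_graph(br, filaments = 1:4, region_length = 400)
  cl <- hierarchical_cluster(g)
  expect_true(cl[[1]]$disconnected)
  hc <- cl[[1]]$hclust
  expect_equal(max(hc$height), 1)
  comp <- cutree(hc, k = 2)
  expect_equal(length(unique(comp[c("1", "2")])), 1)
  expect_equal(length(unique(comp[c("3", "4")])), 1)
})

test_that("cluster metrics match the standard graph formulas", {
  br <- NULL
  for (p in combn(1:4, 2, simplify = FALSE))
    br <- rbind(br, data.frame(filament_a = p[1], filament_b = p[2],
                               x = 0, y = 0, z = 1:10, deviation = 0.5))
  for (p in combn(5:8, 2, simplify = FALSE))
    br <- rbind(br, data.frame(filament_a = p[1], filament_b = p[2],
                               x = 0, y = 0, z = 1:10, deviation = 0.5))
  g <- build_bundle_graph(br, filaments = 1:8, region_length = 400)
  cl <- hierarchical_cluster(g)
  met <- cluster_metrics(cl[[1]], g)
  cv <- met$curves
  # whole graph in one cluster: modularity 0
  expect_equal(cv$modularity[cv$n_clusters == 1], 0, tolerance = 1e-10)
  # two disconnected equal cliques in their own communities: 0.5
  expect_equal(cv$modularity[cv$n_clusters == 2], 0.5)
  expect_equal(cv$transitivity[cv$n_clusters == 2], 1)   # cliques
  expect_equal(cv$min_size[cv$n_clusters == 2], 4)
  expect_equal(cv$max_size[cv$n_clusters == 2], 4)
  # a 3-path cluster has zero transitivity
  path <- data.frame(filament_a = c(1, 2), filament_b = c(2, 3),
                     x = 0, y = 0, z = c(1, 2), deviation = 0)
  gp <- build_bundle_graph(path, filaments = 1:3, region_length = 400)
  expect_equal(fascinet:::.mean_cluster_transitivity(gp, c(1, 1, 1)), 0)
  # clusters below three nodes are excluded from the average
  expect_true(is.na(fascinet:::.mean_cluster_transitivity(gp, c(1, 1, 2))))
})

test_that("metrics are invariant to relabeling and weight rescaling", {
  gsy <- synth_bundle_graph(n_filaments = 12, seed = 9, k_clusters = 2)
  g <- gsy$graph
  met <- cluster_metrics(hierarchical_cluster(g)[[1]], g)
  # uniform rescaling of all interface scores
  g2 <- g
  igraph::E(g2)$fis <- igraph::E(g2)$fis * 7.3
  met2 <- cluster_metrics(hierarchical_cluster(g2)[[1]], g2)
  expect_equal(met$curves$modularity, met2$curves$modularity,
               tolerance = 1e-9)
  expect_equal(met$curves$transitivity, met2$curves$transitivity)
  # normalized distances are invariant up to the eps regularizer in the
  # inverse-score dissimilarity
  expect_equal(met$curves$distance, met2$curves$distance, tolerance = 1e-3)
  # node relabeling: fresh names leave every curve unchanged
  g3 <- g
  igraph::V(g3)$name <- paste0("fil_", seq_len(igraph::vcount(g)))
  met3 <- cluster_metrics(hierarchical_cluster(g3)[[1]], g3)
  expect_equal(met3$curves$modularity, met$curves$modularity,
               tolerance = 1e-9)
  expect_equal(met3$curves$transitivity, met$curves$transitivity)
})

test_that("planted partitions are recovered at the modularity peak", {
  aris <- numeric(20)
  boundary_ok <- logical(20)
  for (s in 1:20) {
    gsy <- synth_bundle_graph(weak_factor = 0.3, seed = s)
    cl <- hierarchical_cluster(gsy$graph)
    met <- cluster_metrics(cl[[1]], gsy$graph)
    part <- met$peaks$modularity$partition
    aris[s] <- fx_ari(part, gsy$labels[names(part)])
    g <- gsy$graph
    ends <- igraph::ends(g, igraph::E(g))
    w <- igraph::E(g)$fis
    btw <- part[ends[, 1]] != part[ends[, 2]]
    boundary_ok[s] <- max(w[btw]) < min(w[!btw])
  }
  expect_true(all(aris >= 0.9))
  # every between-cluster boundary runs along the worst interfaces
  expect_true(all(boundary_ok))
})

test_that("spatial maps tabulate deviations and rank planted outliers", {
  expect_equal(nrow(spatial_map(data.frame(x = numeric(0), y = numeric(0),
                                           z = numeric(0),
                                           deviation = numeric(0)))), 0)
  const <- spatial_map(data.frame(x = 1:5, y = 1, z = 1, deviation = 2))
  expect_true(all(const$decile == const$decile[1]))
  amp <- synth_eigen_amplitudes(500, outlier_fraction = 0.05,
                                outlier_scale = 5, seed = 3)
  sm <- spatial_map(amp)
  expect_gte(min(sm$decile[sm$is_outlier]), 9)
  pdb <- tempfile(fileext = ".pdb")
  spatial_map(amp[1:10, ], pdb_file = pdb)
  expect_true(file.exists(pdb))
  got <- bio3d::read.pdb(pdb)
  expect_equal(nrow(got$atom), 10)
  expect_equal(got$atom$b, sm$deviation[1:10], tolerance = 1e-2)
})
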