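#' Multibody eigenvector amplitude model
#'
#' Describes the Gaussian distribution of per-particle multibody
#' refinement amplitudes: a mean vector, a covariance matrix, and a mask
#' selecting the eigenvectors that correspond to rotational
#' displacements (the subspace in which crossbridge strain is measured).
#'
#' @param mean numeric mean amplitude vector.
#' @param covariance covariance matrix over all eigenvectors (symmetric,
#'   positive-definite on the masked subspace).
#' @param mask logical vector selecting the rotational eigenvectors
#'   (>= 1 selected).
#' @param labels optional eigenvector names.
#' @return an object of class `eigen_model`.
#' @export
eigen_model <- function(mean, covariance, mask = rep(TRUE, length(mean)),
                        labels = paste0("eig", seq_along(mean))) {
  covariance <- as.matrix(covariance)
  p <- length(mean)
  stopifnot(nrow(covariance) == p, ncol(covariance) == p,
            length(mask) == p, sum(mask) >= 1L)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  sub <- covariance[mask, mask, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance is singular on the selected subspace; ",
         "regularize it (e.g. add a small ridge) before use")
  structure(list(mean = as.numeric(mean), covariance = covariance,
                 mask = as.logical(mask), labels = labels),
            class = "eigen_model")
}

#' Mahalanobis deviation of an amplitude vector
#'
#' `sqrt((x - mean)' Sigma^-1 (x - mean))` restricted to the rotational
#' eigenvector subspace selected by the model mask -- the per-crossbridge
#' strain proxy used in interface scoring.
#'
#' @param x amplitude vector (or matrix, one row per particle) matching
#'   the model dimension.
#' @param model an [eigen_model()].
#' @return non-negative scalar (or vector, one per row).
#' @export
mahalanobis_distance <- function(x, model) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(model$mean))
    stop("amplitude dimension does not match the eigen model")
  m <- model$mask
  d2 <- stats::mahalanobis(x[, m, drop = FALSE], model$mean[m],
                           model$covariance[m, m, drop = FALSE])
  sqrt(pmax(d2, 0))
}

#' Filament interface score (F.I.S.)
#'
#' `(N / L) / (1 + Ebar)`: the crossbridge density of an inter-filament
#' interface discounted by the mean Mahalanobis deviation of its
#' crossbridges. An interface with no crossbridges scores 0.
#'
#' @param N number of fascin crossbridges along the interface.
#' @param L interface length, nm (> 0).
#' @param Ebar mean Mahalanobis deviation of those crossbridges (>= 0
#'   when `N > 0`).
#' @return the interface score (vectorized).
#' @export
interface_score <- function(N, L, Ebar) {
  if (any(L <= 0)) stop("interface length L must be > 0")
  ifelse(N == 0, 0, (N / L) / (1 + Ebar))
}

#' Build a weighted bundle graph from crossbridge records
#'
#' Nodes are filaments; two filaments are joined by an edge if at least
#' one fascin bridges them within the region; each edge is weighted by
#' its [interface_score()] with `L` equal to the region length.
#'
#' @param bridges data.frame with one row per crossbridge: columns
#'   `filament_a`, `filament_b`, and either `deviation` (Mahalanobis
#'   distance) or `amplitudes` to be scored against `model`.
#' @param filaments vector of all filament ids in the region (isolated
#'   filaments are retained as unconnected nodes); defaults to the ids
#'   present in `bridges`.
#' @param region_length interface length `L`, nm (default 400, a
#'   well-ordered bundle region).
#' @param model optional [eigen_model()] used when `bridges` carries raw
#'   amplitudes instead of precomputed deviations.
#' @return an `igraph` graph with vertex attribute `name` and edge
#'   attributes `N`, `Ebar`, `fis`.
#' @export
build_bundle_graph <- function(bridges, filaments = NULL,
                               region_length = 400, model = NULL) {
  stopifnot(region_length > 0)
  if (!("deviation" %in% names(bridges))) {
    if (is.null(model))
      stop("bridges lack a 'deviation' column and no eigen model given")
    amp <- as.matrix(bridges[, grep("^amp", names(bridges)), drop = FALSE])
    bridges$deviation <- mahalanobis_distance(amp, model)
  }
  ids <- if (is.null(filaments))
    sort(unique(c(bridges$filament_a, bridges$filament_b))) else
      sort(unique(filaments))
  bad <- setdiff(c(bridges$filament_a, bridges$filament_b), ids)
  if (length(bad))
    stop("crossbridge references unknown filament(s): ",
         paste(utils::head(bad), collapse = ", "))
  if (nrow(bridges)) {
    key <- paste(pmin(bridges$filament_a, bridges$filament_b),
                 pmax(bridges$filament_a, bridges$filament_b), sep = "-")
    agg_n <- tapply(key, key, length)
    agg_e <- tapply(bridges$deviation, key, mean)
    ab <- do.call(rbind, strsplit(names(agg_n), "-", fixed = TRUE))
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        N = as.integer(agg_n),
                        Ebar = as.numeric(agg_e),
                        fis = interface_score(as.integer(agg_n),
                                              region_length,
                                              as.numeric(agg_e)))
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        N = integer(0), Ebar = numeric(0),
                        fis = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  g$region_length <- region_length
  g
}

# Pairwise dissimilarity used for ward clustering: adjacent nodes take
# 1 / (fis + eps); non-adjacent pairs take the shortest-path sum of
# adjacent dissimilarities, so weak interfaces become the preferred
# split points.
.graph_dissimilarity <- function(graph, eps = 1e-6) {
  w <- 1 / (igraph::E(graph)$fis + eps)
  D <- igraph::distances(graph, weights = w)
  D
}

#' Ward hierarchical clustering of a bundle graph
#'
#' Clusters the filaments of one or more bundle graphs by Ward linkage
#' on an interface-derived dissimilarity (the inverse interface score,
#' summed along shortest paths for non-adjacent filaments), then
#' normalizes all linkage heights by the maximum across the supplied
#' graph set so curves from different bundles share one distance axis.
#' Components of a disconnected graph are clustered independently and
#' merged at normalized distance 1.
#'
#' @param graphs a single igraph bundle graph (from
#'   [build_bundle_graph()]) or a list of them.
#' @param eps regularizer added to the interface score before inversion.
#' @return a list of class `bundle_clustering`, one element per graph,
#'   each with the `hclust` tree (`merge`/`height` on the normalized
#'   scale), the node `labels`, and `max_height` (the global pre-
#'   normalization maximum).
#' @export
hierarchical_cluster <- function(graphs, eps = 1e-6) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  prelim <- lapply(graphs, function(g) {
    if (igraph::vcount(g) < 2L)
      stop("single-node graph: clustering is degenerate")
    D <- .graph_dissimilarity(g, eps)
    finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
    list(D = D, finite_max = if (length(finite)) max(finite) else 0)
  })
  trees <- lapply(prelim, function(pr) {
    D <- pr$D
    disconnected <- any(!is.finite(D))
    if (disconnected) {
      # cluster components independently; stitch at a sentinel height
      D[!is.finite(D)] <- pr$finite_max * 10 + 10
    }
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
    list(hc = hc, disconnected = disconnected,
         cut = if (disconnected) pr$finite_max * 5 else Inf)
  })
  max_h <- max(vapply(trees, function(tr)
    max(tr$hc$height[tr$hc$height < tr$cut], 0), 0))
  if (max_h <= 0) max_h <- 1
  out <- lapply(trees, function(tr) {
    hc <- tr$hc
    h <- hc$height / max_h
    h[hc$height >= tr$cut] <- 1   # component merges pinned at 1
    hc$height <- h
    structure(list(hclust = hc, labels = hc$labels,
                   max_height = max_h, disconnected = tr$disconnected),
              class = "bundle_dendrogram")
  })
  structure(out, class = "bundle_clustering")
}

#' @export
print.bundle_clustering <- function(x, ...) {
  cat(sprintf("Bundle clustering of %d graph(s); shared max height %.4g\n",
              length(x), x[[1]]$max_height))
  invisible(x)
}

#' Transitivity, modularity and cluster-size curves
#'
#' Cuts a clustered bundle at every merge height and computes, per cut:
#' the average transitivity over clusters of at least three filaments
#' (3 x triangles / connected triples within each cluster subgraph),
#' the weighted Newman modularity of the partition (edge weights =
#' interface scores), and the minimum / mean / maximum cluster sizes.
#' Peaks are the arg-max of each curve, ties resolved to the smaller
#' linkage distance.
#'
#' @param dend one `bundle_dendrogram` element of a
#'   [hierarchical_cluster()] result.
#' @param graph the igraph bundle graph the dendrogram was built from.
#' @return a list of class `cluster_metrics` with `curves` (data.frame:
#'   `distance`, `n_clusters`, `transitivity`, `modularity`,
#'   `min_size`, `mean_size`, `max_size`) and `peaks` (named list with
#'   the transitivity- and modularity-peak distances and partitions).
#' @export
cluster_metrics <- function(dend, graph) {
  hc <- dend$hclust
  n <- length(hc$labels)
  vnames <- igraph::V(graph)$name
  heights <- sort(hc$height)   # merge m leaves n - m clusters
  rows <- list()
  parts <- list()
  for (k in n:1) {
    memb <- stats::cutree(hc, k = k)
    memb <- memb[match(vnames, names(memb))]
    sizes <- as.numeric(table(memb))
    trans <- .mean_cluster_transitivity(graph, memb)
    mod <- igraph::modularity(graph, memb,
                              weights = igraph::E(graph)$fis)
    rows[[length(rows) + 1L]] <- data.frame(
      distance = if (k == n) 0 else heights[n - k],
      n_clusters = k, transitivity = trans,
      modularity = mod, min_size = min(sizes), mean_size = mean(sizes),
      max_size = max(sizes))
    parts[[length(parts) + 1L]] <- memb
  }
  curves <- do.call(rbind, rows)
  # arg-max ignoring cuts where the metric is undefined; ties resolve
  # to the smallest linkage distance
  pk <- function(v) which(v >= max(v, na.rm = TRUE) - 1e-12)[1]
  it <- pk(curves$transitivity)
  im <- pk(curves$modularity)
  structure(list(
    curves = curves,
    peaks = list(
      transitivity = list(distance = curves$distance[it],
                          partition = parts[[it]]),
      modularity = list(distance = curves$distance[im],
                        partition = parts[[im]]))),
    class = "cluster_metrics")
}

.mean_cluster_transitivity <- function(graph, membership) {
  vals <- vapply(unique(membership), function(cl) {
    vs <- which(membership == cl)
    if (length(vs) < 3L) return(NA_real_)
    sg <- igraph::induced_subgraph(graph, vs)
    tr <- igraph::transitivity(sg, type = "global")
    if (is.nan(tr)) 0 else tr
  }, 0)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat("Cluster metric curves over", nrow(x$curves), "cut heights\n")
  cat(sprintf("  transitivity peak at distance %.3f; modularity peak at %.3f\n",
              x$peaks$transitivity$distance, x$peaks$modularity$distance))
  invisible(x)
}

#' @describeIn cluster_metrics plot the transitivity and modularity
#'   curves against normalized linkage distance, with peak markers.
#' @param x a `cluster_metrics` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cluster_metrics <- function(x, ...) {
  cv <- x$curves
  graphics::matplot(cv$distance, cbind(cv$transitivity, cv$modularity),
                    type = "s", lty = 1, col = c("steelblue", "tomato"),
                    xlab = "normalized linkage distance", ylab = "metric",
                    ...)
  graphics::abline(v = x$peaks$transitivity$distance, lty = 2,
                   col = "steelblue")
  graphics::abline(v = x$peaks$modularity$distance, lty = 2,
                   col = "tomato")
  graphics::legend("topright", c("transitivity", "modularity"),
                   col = c("steelblue", "tomato"), lty = 1, bty = "n")
  invisible(x)
}

#' Spatial map of crossbridge deviations
#'
#' Tabulates per-crossbridge positions with their Mahalanobis
#' deviations for visual inspection, optionally writing a pseudo-atom
#' PDB file (one atom per crossbridge, deviation in the B-factor
#' column).
#'
#' @param deviations data.frame with columns `x`, `y`, `z` (nm) and
#'   `deviation` (plus any id columns, carried through).
#' @param pdb_file optional path; when given, pseudo-atoms are written
#'   there via [bio3d::write.pdb()] (coordinates converted to Angstrom).
#' @return the input table, invisibly augmented with a `decile` column
#'   (1 = lowest deviation decile).
#' @export
spatial_map <- function(deviations, pdb_file = NULL) {
  stopifnot(all(c("x", "y", "z", "deviation") %in% names(deviations)))
  out <- deviations
  if (nrow(out)) {
    qs <- stats::quantile(out$deviation, probs = seq(0, 1, 0.1),
                          names = FALSE, type = 7)
    out$decile <- pmin(findInterval(out$deviation, qs[-11],
                                    rightmost.closed = FALSE), 10L)
  } else out$decile <- integer(0)
  if (!is.null(pdb_file)) {
    if (nrow(out)) {
      bio3d::write.pdb(file = pdb_file,
                       xyz = as.numeric(t(as.matrix(out[, c("x", "y", "z")]
                                                    * 10))),
                       resno = seq_len(nrow(out)),
                       resid = rep("XBR", nrow(out)),
                       elety = rep("C", nrow(out)),
                       b = out$deviation)
    } else {
      writeLines("END", pdb_file)
    }
  }
  out
}
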