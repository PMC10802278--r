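#' Serialize a bundle to JSON
#'
#' Writes filament ids, lattice positions, rotations, protomer counts
#' and the crossbridge table; [read_bundle_json()] restores a
#' `fascin_bundle` usable by the pattern analyses (the scoring
#' configuration is summarized, not round-tripped).
#'
#' @param bundle a `fascin_bundle`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bundle_json <- function(bundle, file) {
  fl <- lapply(bundle$filaments, function(f)
    list(id = f$id, position = f$position, rotation = f$rotation,
         n_protomers = f$n_protomers, axial_offset = f$axial_offset))
  obj <- list(
    spacing = bundle$cfg$lattice$spacing,
    tol = bundle$cfg$tol,
    helix = list(twist = bundle$cfg$helix$twist,
                 rise = bundle$cfg$helix$rise),
    seed = bundle$cfg$seed,
    filaments = fl,
    crossbridges = bundle$crossbridges)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_bundle_json
#' @export
read_bundle_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  lat <- structure(list(spacing = obj$spacing,
                        positions = do.call(rbind, lapply(
                          obj$filaments$position,
                          function(p) as.numeric(p))),
                        layout = "restored"),
                   class = "lattice_spec")
  helix <- helical_params(obj$helix$twist, obj$helix$rise)
  fils <- lapply(seq_len(nrow(obj$filaments)), function(k)
    filament(obj$filaments$id[k],
             as.numeric(obj$filaments$position[[k]]),
             obj$filaments$rotation[k],
             obj$filaments$n_protomers[k],
             obj$filaments$axial_offset[k]))
  cb <- as.data.frame(obj$crossbridges)
  if (!nrow(cb)) cb <- .canonical_bridges(NULL)
  structure(list(filaments = fils, crossbridges = cb,
                 occupancy = NULL,
                 cfg = list(lattice = lat, helix = helix, tol = obj$tol,
                            seed = obj$seed)),
            class = "fascin_bundle")
}

#' Export bundle fiducial sites as PDB pseudo-atoms
#'
#' One pseudo-atom per fiducial site of every protomer, for visual
#' inspection of assembled geometry in a molecular viewer. Coordinates
#' are converted from nm to Angstrom. Chains map to filaments; each
#' site is written as its own residue with the parent amino-acid code
#' (ASP for D24, ARG for R95, SER for S350) and residue number
#' `10 * protomer + site` so the protomer index survives the format's
#' fixed-width fields.
#'
#' @param bundle a `fascin_bundle`.
#' @param file output PDB path.
#' @param fid a [fiducial_geometry()].
#' @return `file`, invisibly.
#' @export
write_bundle_pdb <- function(bundle, file, fid = fiducial_geometry()) {
  helix <- bundle$cfg$helix
  aa <- c(D24 = "ASP", R95 = "ARG", S350 = "SER")
  xyz <- NULL
  resno <- integer(0)
  chain <- character(0)
  resid <- character(0)
  for (f in bundle$filaments) {
    for (k in seq_len(f$n_protomers) - 1L) {
      for (s in seq_along(fid)) {
        res <- names(fid)[s]
        xyz <- rbind(xyz, protomer_site(f, k, res, helix, fid) * 10)
        resno <- c(resno, 10L * k + s)
        chain <- c(chain, LETTERS[(f$id - 1L) %% 26 + 1L])
        resid <- c(resid, if (res %in% names(aa)) aa[[res]] else "UNK")
      }
    }
  }
  bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                   resno = resno, chain = chain, resid = resid,
                   elety = rep("CA", nrow(xyz)))
  invisible(file)
}

#' Export a contact map as CSV
#'
#' @param map a `contact_map` matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_contact_map_csv <- function(map, file) {
  df <- as.data.frame(unclass(map))
  df <- cbind(filament = rownames(map), df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a bundle graph as GraphML
#'
#' @param graph an igraph bundle graph.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bundle_graphml <- function(graph, file) {
  igraph::write_graph(graph, file, format = "graphml")
  invisible(file)
}

#' Export a bundle dendrogram as Newick
#'
#' Converts the normalized-height `hclust` tree to a phylo object and
#' writes Newick text.
#'
#' @param dend a `bundle_dendrogram` (one element of a
#'   [hierarchical_cluster()] result).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, file) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file)
  invisible(file)
}
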