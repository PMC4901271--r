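# Surface-based searchlight: geodesic disks on a triangulated cortical mesh
# and per-vertex RDMs from the voxel patterns inside each disk.

#' Triangulated cortical surface mesh
#'
#' @param vertex_coords numeric `n x 3` matrix of vertex coordinates in mm.
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param vertex_to_voxel per-vertex voxel id (`NA` for vertices without a
#'   mapped voxel); several vertices may map to the same voxel.
#' @return An object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertex_coords, faces, vertex_to_voxel = NULL) {
  vertex_coords <- as.matrix(vertex_coords)
  stopifnot(ncol(vertex_coords) == 3L)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  nv <- nrow(vertex_coords)
  if (any(faces < 1L) || any(faces > nv)) stop("faces reference invalid vertices")
  if (is.null(vertex_to_voxel)) vertex_to_voxel <- rep(NA_character_, nv)
  if (length(vertex_to_voxel) != nv) stop("one voxel id (or NA) per vertex required")
  el <- mesh_edges(faces, vertex_coords)
  if (any(el$length <= 0)) stop("mesh has zero-length edges")
  structure(list(vertex_coords = vertex_coords, faces = faces,
                 vertex_to_voxel = as.character(vertex_to_voxel)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d mapped voxels\n",
              nrow(x$vertex_coords), nrow(x$faces),
              length(unique(stats::na.omit(x$vertex_to_voxel)))))
  invisible(x)
}

# Unique undirected edges of the face set with their Euclidean lengths.
mesh_edges <- function(faces, coords) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] - coords[e[, 2], , drop = FALSE])^2))
  list(edges = e, length = len)
}

# One-step unfolding shortcuts: for every interior edge (b, d) shared by two
# triangles with opposite vertices a and e, unfold the two triangles into a
# common plane about (b, d); if the straight segment a-e crosses the shared
# edge, its unfolded length is a valid geodesic upper bound tighter than any
# path through b or d, and (a, e) is added as an auxiliary graph edge.  This
# first-order correction greatly reduces the anisotropy of the edge-graph
# metric (on a flat quad it recovers the second diagonal exactly).
quad_shortcuts <- function(faces, coords) {
  all_e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  fidx <- rep.int(seq_len(nrow(faces)), 3)
  key <- paste(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  grp <- split(seq_along(key), key)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  d3 <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  for (idx in grp) {
    if (length(idx) != 2L) next                  # boundary or non-manifold edge
    b <- min(all_e[idx[1], ]); d <- max(all_e[idx[1], ])
    a <- setdiff(faces[fidx[idx[1]], ], c(b, d))
    e <- setdiff(faces[fidx[idx[2]], ], c(b, d))
    if (length(a) != 1L || length(e) != 1L || a == e) next
    L <- d3(b, d)
    ab <- d3(a, b); ad <- d3(a, d); eb <- d3(e, b); ed <- d3(e, d)
    xa <- (ab^2 + L^2 - ad^2) / (2 * L); ya <- sqrt(max(ab^2 - xa^2, 0))
    xe <- (eb^2 + L^2 - ed^2) / (2 * L); ye <- -sqrt(max(eb^2 - xe^2, 0))
    if (ya <= 0 || ye >= 0) next                 # degenerate triangle
    x0 <- xa + (xe - xa) * ya / (ya - ye)        # crossing of a-e with the shared edge
    if (x0 < 0 || x0 > L) next                   # geodesic bends around b or d instead
    from <- c(from, a); to <- c(to, e)
    w <- c(w, sqrt((xa - xe)^2 + (ya - ye)^2))
  }
  list(edges = cbind(from, to), length = w)
}

mesh_graph <- function(mesh, unfold = TRUE) {
  el <- mesh_edges(mesh$faces, mesh$vertex_coords)
  edges <- el$edges; len <- el$length
  if (unfold) {
    sc <- quad_shortcuts(mesh$faces, mesh$vertex_coords)
    if (nrow(sc$edges)) { edges <- rbind(edges, sc$edges); len <- c(len, sc$length) }
  }
  g <- igraph::make_graph(t(edges), n = nrow(mesh$vertex_coords), directed = FALSE)
  igraph::E(g)$weight <- len
  g
}

#' Geodesic distances from a source vertex
#'
#' Approximates geodesic distance by the length of the shortest path along
#' mesh edges (Dijkstra's algorithm, edge weights = Euclidean edge lengths),
#' as is standard for surface-based searchlight construction.  By default
#' the edge graph is augmented with one-step unfolding shortcuts across each
#' pair of adjacent triangles, which removes most of the directional bias of
#' the raw edge-graph metric (on a flat grid mesh it makes disk membership
#' agree with the Euclidean disk); `unfold = FALSE` gives the raw edge-graph
#' distance.  Only vertices within `cutoff_mm` are returned.
#'
#' @param mesh a [surface_mesh()].
#' @param source source vertex index.
#' @param cutoff_mm maximum distance; `Inf` returns all reachable vertices.
#' @param unfold augment the graph with unfolded-quad shortcuts (default
#'   `TRUE`).
#' @return named numeric vector, distance (mm) per vertex index (including
#'   the source at 0); unreachable or beyond-cutoff vertices are omitted.
#' @export
geodesic_distances <- function(mesh, source, cutoff_mm = Inf, unfold = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  g <- mesh_graph(mesh, unfold = unfold)
  d <- igraph::distances(g, v = source, algorithm = "dijkstra")[1, ]
  names(d) <- seq_along(d)
  d[is.finite(d) & d <= cutoff_mm]
}

#' Searchlight disk
#'
#' @param center_vertex center vertex index.
#' @param member_voxels unique, nonempty voxel id list.
#' @return An object of class `"searchlight_disk"`.
#' @export
searchlight_disk <- function(center_vertex, member_voxels) {
  if (!length(member_voxels)) stop("a searchlight disk cannot be empty")
  if (anyDuplicated(member_voxels)) stop("a voxel may appear only once in a searchlight")
  structure(list(center_vertex = as.integer(center_vertex),
                 member_voxels = as.character(member_voxels)),
            class = "searchlight_disk")
}

#' Build geodesic searchlight disks
#'
#' For every vertex, collects all vertices strictly less than `radius_mm`
#' away in geodesic space (shortest path on the mesh) and maps them to
#' voxels.  Voxels are deduplicated after distance selection, so each voxel
#' appears only once in a disk even when it is nearest neighbour to several
#' vertices.  Vertices whose disk contains no mapped voxel are dropped (and
#' counted in the `n_dropped` attribute).
#'
#' @param mesh a [surface_mesh()].
#' @param radius_mm disk radius in mm (> 0, strict inequality at the
#'   boundary); default 9.
#' @param quiet suppress the message about dropped vertices.
#' @param unfold see [geodesic_distances()].
#' @return list of [searchlight_disk()], named by center vertex; attribute
#'   `n_dropped` counts the vertices without any mapped voxel in range.
#' @export
build_disks <- function(mesh, radius_mm = 9, quiet = FALSE, unfold = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (radius_mm <= 0) stop("radius must be positive")
  g <- mesh_graph(mesh, unfold = unfold)
  dall <- igraph::distances(g, algorithm = "dijkstra")
  nv <- nrow(mesh$vertex_coords)
  disks <- vector("list", nv)
  for (v in seq_len(nv)) {
    memb <- which(dall[v, ] < radius_mm)            # strict: "less than r away"
    vox <- mesh$vertex_to_voxel[memb]
    vox <- unique(vox[!is.na(vox)])                 # dedupe after selection
    if (length(vox)) disks[[v]] <- searchlight_disk(v, vox)
  }
  dropped <- sum(vapply(disks, is.null, TRUE))
  if (dropped && !quiet)
    message(sprintf("build_disks: dropped %d vertices with no mapped voxel in range", dropped))
  disks <- disks[!vapply(disks, is.null, TRUE)]
  names(disks) <- vapply(disks, function(d) as.character(d$center_vertex), "")
  attr(disks, "n_dropped") <- dropped
  disks
}

#' Per-disk searchlight RDMs
#'
#' Computes a correlation-distance RDM ([correlation_rdm()]) from the voxel
#' patterns inside every searchlight disk.  A disk with fewer than 2 voxels
#' cannot support a rank correlation; its RDM is returned with every entry
#' missing (flagged via the `n_missing` attribute) rather than raising an
#' error, so one degenerate vertex never aborts a whole-map run.
#'
#' @param disks list of [searchlight_disk()] from [build_disks()].
#' @param patterns a [spatial_patterns()] containing every member voxel.
#' @return named list (by center vertex) of [rdm()] objects.
#' @export
searchlight_rdms <- function(disks, patterns) {
  stopifnot(inherits(patterns, "spatial_patterns"))
  n <- nrow(patterns$data)
  lapply(disks, function(d) {
    if (!all(d$member_voxels %in% patterns$voxel_ids))
      stop(sprintf("disk at vertex %d references voxels missing from the patterns",
                   d$center_vertex))
    if (length(d$member_voxels) < 2L) {
      out <- rdm(rep(NA_real_, n * (n - 1) / 2), n,
                 metric = "correlation_distance",
                 condition_labels = patterns$condition_labels)
      attr(out, "n_missing") <- n * (n - 1) / 2
      return(out)
    }
    correlation_rdm(patterns$data[, d$member_voxels, drop = FALSE], quiet = TRUE)
  })
}

#' Per-vertex similarity map between searchlight RDMs and a model RDM
#'
#' @param sl_rdms named list of per-vertex [rdm()]s from [searchlight_rdms()].
#' @param model_rdm an [rdm()].
#' @return data.frame with columns `vertex` and `similarity` (Spearman R).
#' @export
searchlight_similarity_map <- function(sl_rdms, model_rdm) {
  sim <- vapply(sl_rdms, function(r)
    suppressWarnings(compare_rdms(r, model_rdm)), numeric(1))
  data.frame(vertex = as.integer(names(sl_rdms)), similarity = unname(sim))
}
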