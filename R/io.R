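# Plain-text serialization: square-CSV and condensed-CSV RDM exports,
# OFF-style meshes, tidy time-course tables, similarity maps, JSON run
# manifests, and (optionally, via the png package) image stacks.

#' Write an RDM as a square CSV
#'
#' Square form with condition labels as header/rownames and empty cells on
#' the (undefined) diagonal.
#'
#' @param x an [rdm()].
#' @param path output file.
#' @export
write_rdm_csv <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  m <- rdm_square(x)
  ch <- matrix(sprintf("%.17g", m), nrow(m))
  ch[is.na(m)] <- ""
  diag(ch) <- ""
  tab <- cbind(condition = x$condition_labels, ch)
  colnames(tab) <- c("condition", x$condition_labels)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an RDM in condensed text form
#'
#' A small header (n_conditions, metric, labels) followed by one condensed
#' value per line at full double precision (17 significant digits), so the
#' round trip is bit-exact.
#'
#' @param x an [rdm()].
#' @param path file path.
#' @return `read_rdm_condensed` returns an [rdm()].
#' @export
write_rdm_condensed <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_conditions,%d", x$n_conditions),
               sprintf("# metric,%s", x$metric),
               sprintf("# labels,%s", paste(x$condition_labels, collapse = ";")),
               "value",
               sprintf("%.17g", x$values)), con)
  invisible(path)
}

#' @rdname write_rdm_condensed
#' @export
read_rdm_condensed <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) sub(paste0("# ", key, ","), "", hdr[startsWith(hdr, paste0("# ", key, ","))])
  vals <- as.numeric(lines[-seq_len(length(hdr) + 1L)])
  rdm(vals, as.integer(get("n_conditions")), metric = get("metric"),
      condition_labels = strsplit(get("labels"), ";", fixed = TRUE)[[1]])
}

#' Write a similarity time course as tidy CSV
#'
#' Long format: one row per (subject, timepoint) with columns `subject`,
#' `time_ms`, `value`, `label`.
#'
#' @param tc a [similarity_timecourse()].
#' @param path output file.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "similarity_timecourse"))
  df <- data.frame(subject = rep(rownames(tc$values), times = ncol(tc$values)),
                   time_ms = rep(tc$times_ms, each = nrow(tc$values)),
                   value = as.vector(tc$values), label = tc$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-vertex similarity map as CSV
#'
#' @param map data.frame with columns `vertex` and `similarity` (from
#'   [searchlight_similarity_map()]), or any data.frame.
#' @param path output file.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a surface mesh as OFF-style text
#'
#' Standard OFF layout (vertex and face counts, vertex coordinates, then
#' triangles with 0-based indices).  The vertex-to-voxel mapping travels in
#' a companion CSV (`<path>.voxels.csv`, columns `vertex`, `voxel_id`).
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.off` file.
#' @return `read_mesh_off` returns a [surface_mesh()].
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertex_coords); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  writeLines(c("OFF", sprintf("%d %d 0", nv, nf),
               apply(mesh$vertex_coords, 1L, function(v) paste(sprintf("%.17g", v), collapse = " ")),
               apply(mesh$faces, 1L, function(f) paste(c(3L, f - 1L), collapse = " "))), con)
  close(con)
  utils::write.csv(data.frame(vertex = seq_len(nv), voxel_id = mesh$vertex_to_voxel),
                   paste0(path, ".voxels.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  nv <- counts[1]; nf <- counts[2]
  coords <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  faces <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(l, " ")[[1]])[-1] + 1L))
  vox_path <- paste0(path, ".voxels.csv")
  vox <- if (file.exists(vox_path)) {
    tab <- utils::read.csv(vox_path, colClasses = c("integer", "character"))
    tab$voxel_id[order(tab$vertex)]
  } else NULL
  surface_mesh(coords, faces, vertex_to_voxel = vox)
}

#' Write images as PNG files
#'
#' Requires the `png` package; values are clipped to `[0, 1]`.
#'
#' @param images list of height x width x channels arrays (or matrices).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the written files.
#' @export
write_images_png <- function(images, dir, prefix = "image") {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG images")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(images), function(i) {
    p <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
    png::writePNG(pmin(pmax(images[[i]], 0), 1), p)
    p
  }, "")
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the full
#' configuration, the master seed, the package version and a configuration
#' checksum.
#'
#' @param cfg configuration list.
#' @param path output `.json` file.
#' @param extra optional named list of additional fields.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  payload <- c(list(package = "neurorsa",
                    version = as.character(utils::packageVersion("neurorsa")),
                    config = cfg,
                    config_checksum = config_checksum(cfg)),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Order-stable FNV-1a style checksum of the deparsed configuration.
config_checksum <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 2166136261
  for (cc in utf8ToInt(txt)) h <- ((bitwXor(as.integer(h %% 2^31), cc)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
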