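#' Build a recursively subdivided icosahedron ("icosphere")
#'
#' Source spaces are laid out on the topology of a recursively subdivided
#' icosahedron: order 0 is the 12-vertex icosahedron, each subdivision
#' splits every triangle into four and projects new vertices to the unit
#' sphere, giving `10 * 4^order + 2` vertices (162 at order 2, 10,242 at
#' order 5 -- the low- and high-density source spaces used per
#' hemisphere).
#'
#' @param order subdivision count (>= 0).
#' @param radius sphere radius (mm scale of the returned coordinates).
#' @param hemisphere tag stored on the mesh.
#' @return a `cortical_mesh`: list with `vertices` (n x 3 matrix),
#'   `triangles` (m x 3 integer matrix, 1-based), `hemisphere`.
#' @export
build_icosphere <- function(order, radius = 1, hemisphere = "lh") {
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(order)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- vector("list", 0)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (is.null(id)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        nv <<- nv + 1L
        verts[[length(verts) + 1L]] <<- m
        id <- nv
        edge_mid[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c_, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- nf
  }
  structure(list(vertices = v * radius, triangles = f,
                 hemisphere = hemisphere),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %s: %d vertices, %d triangles\n",
              x$hemisphere, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Geodesic distances from one vertex along the mesh graph
#'
#' Dijkstra over the triangle edge graph with Euclidean edge lengths;
#' used by the optional geodesic patch mode.
#'
#' @keywords internal
mesh_geodesic <- function(mesh, from) {
  n <- nrow(mesh$vertices)
  edges <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
                 mesh$triangles[, c(3, 1)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  len <- sqrt(rowSums((mesh$vertices[edges[, 1], , drop = FALSE] -
                       mesh$vertices[edges[, 2], , drop = FALSE])^2))
  adj <- split(seq_len(nrow(edges)), edges[, 1])
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (e in adj[[as.character(u)]]) {
      vtx <- edges[e, 2]
      if (dist[u] + len[e] < dist[vtx]) dist[vtx] <- dist[u] + len[e]
    }
  }
  dist
}

#' Build low-density patches on a high-density mesh
#'
#' For each low-density source point, the patch is the set of
#' high-density vertices within `disc_diameter / 2` of it -- a disc of
#' about 1 cm diameter on the cortical surface in the study geometry.
#' Distance is Euclidean (chord) by default, with a geodesic
#' (edge-graph) mode available; each patch always contains at least its
#' own vertex.
#'
#' @param mesh high-density `cortical_mesh`.
#' @param low_density_ids vertex indices of the low-density source space.
#' @param disc_diameter patch disc diameter, same units as the mesh (mm).
#' @param method "chord" (default) or "geodesic".
#' @return a `source_space`: list with `high_density_ids`,
#'   `low_density_ids`, and `patch_map` (list: low id -> high ids).
#' @export
build_patches <- function(mesh, low_density_ids, disc_diameter = 10,
                          method = c("chord", "geodesic")) {
  method <- match.arg(method)
  if (length(low_density_ids) == 0)
    stop("low_density_ids must be non-empty", call. = FALSE)
  if (any(low_density_ids < 1 | low_density_ids > nrow(mesh$vertices)))
    stop("low_density_ids outside mesh vertex range", call. = FALSE)
  r <- disc_diameter / 2
  patch_map <- lapply(low_density_ids, function(i) {
    d <- if (method == "chord") {
      sqrt(colSums((t(mesh$vertices) - mesh$vertices[i, ])^2))
    } else mesh_geodesic(mesh, i)
    ids <- which(d <= r)
    if (!(i %in% ids)) ids <- sort(c(i, ids))
    ids
  })
  names(patch_map) <- as.character(low_density_ids)
  structure(list(high_density_ids = seq_len(nrow(mesh$vertices)),
                 low_density_ids = low_density_ids,
                 patch_map = patch_map),
            class = "source_space")
}

#' Average high-density activity into the low-density source space
#'
#' Each low-density source's signal is the unweighted sample-wise mean of
#' the high-density rows in its patch.
#'
#' @param rec high-density [source_recording()]; rows must correspond to
#'   the mesh's high-density vertex ids.
#' @param space a `source_space` from [build_patches()].
#' @return a low-density [source_recording()] (one row per low-density
#'   id), inheriting fs, mask and metadata.
#' @export
average_patch_activity <- function(rec, space) {
  need <- unique(unlist(space$patch_map))
  if (max(need) > nrow(rec$data))
    stop("patch references a row missing from the recording", call. = FALSE)
  out <- t(vapply(space$patch_map, function(ids) {
    colMeans(rec$data[ids, , drop = FALSE])
  }, numeric(ncol(rec$data))))
  src <- rec$sources[space$low_density_ids, , drop = FALSE]
  src$id <- space$low_density_ids
  source_recording(out, rec$fs, sources = src, subject = rec$subject,
                   mask = rec$mask, truth = rec$truth,
                   boundaries = rec$boundaries,
                   vertical_axis = rec$vertical_axis)
}

#' Region label on a mesh
#'
#' @param name atlas label string.
#' @param vertex_ids vertex indices belonging to the label.
#' @param hemisphere hemisphere tag.
#' @return a `region_label` list.
#' @export
region_label <- function(name, vertex_ids, hemisphere = "lh") {
  structure(list(name = name, vertex_ids = sort(unique(as.integer(vertex_ids))),
                 hemisphere = hemisphere),
            class = "region_label")
}

#' Construct the inferior Rolandic ROI
#'
#' A sphere is centred on the most inferior vertex (minimal vertical
#' coordinate) of the union of the pre- and post-central gyrus labels,
#' with radius half the Euclidean distance between that union's most
#' inferior and most superior vertices. The ROI is the intersection of
#' this sphere with the union of the two labels.
#'
#' @param mesh `cortical_mesh` the labels refer to.
#' @param precentral,postcentral `region_label`s (same hemisphere).
#' @param vertical_axis which coordinate axis is vertical: 1, 2 or 3, or
#'   an axis name "x"/"y"/"z".
#' @return a `region_label` named "inferiorRolandic".
#' @export
inferior_rolandic_roi <- function(mesh, precentral, postcentral,
                                  vertical_axis = 3) {
  if (precentral$hemisphere != postcentral$hemisphere)
    stop("labels must share a hemisphere", call. = FALSE)
  if (is.character(vertical_axis))
    vertical_axis <- match(vertical_axis, c("x", "y", "z"))
  ids <- union(precentral$vertex_ids, postcentral$vertex_ids)
  if (length(ids) == 0) stop("labels are empty", call. = FALSE)
  vv <- mesh$vertices[ids, , drop = FALSE]
  z <- vv[, vertical_axis]
  if (max(z) - min(z) < 1e-9)
    stop("degenerate label: no vertical extent", call. = FALSE)
  lo <- ids[which.min(z)]
  hi <- ids[which.max(z)]
  center <- mesh$vertices[lo, ]
  radius <- sqrt(sum((mesh$vertices[hi, ] - center)^2)) / 2
  d <- sqrt(rowSums((vv - matrix(center, nrow(vv), 3, byrow = TRUE))^2))
  region_label("inferiorRolandic", ids[d <= radius],
               hemisphere = precentral$hemisphere)
}

#' Read and write simple mesh / label text formats
#'
#' Meshes are stored as plain text: a header line
#' `mesh <hemisphere> <n_vertices> <n_triangles>`, then vertex lines
#' (x y z in mm) and 1-based triangle lines. Labels are one vertex index
#' per line under a `label <name> <hemisphere>` header; `#` comments are
#' allowed.
#'
#' @param path file path.
#' @return [read_mesh()] a `cortical_mesh`; [read_label()] a
#'   `region_label`.
#' @export
read_mesh <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  if (hd[1] != "mesh") stop("not a mesh file: ", path, call. = FALSE)
  nv <- as.integer(hd[3]); nf <- as.integer(hd[4])
  num <- function(rows) do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                              as.numeric))
  v <- num(ln[2:(1 + nv)])
  f <- num(ln[(2 + nv):(1 + nv + nf)])
  structure(list(vertices = v, triangles = matrix(as.integer(f), ncol = 3),
                 hemisphere = hd[2]),
            class = "cortical_mesh")
}

#' @rdname read_mesh
#' @param mesh a `cortical_mesh` to write.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("mesh %s %d %d", mesh$hemisphere,
                     nrow(mesh$vertices), nrow(mesh$triangles)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(mesh$triangles, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_label <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  if (hd[1] != "label") stop("not a label file: ", path, call. = FALSE)
  region_label(hd[2], as.integer(ln[-1]), hemisphere = hd[3])
}

#' @rdname read_mesh
#' @param label a `region_label` to write.
#' @export
write_label <- function(label, path) {
  writeLines(c(sprintf("label %s %s", label$name, label$hemisphere),
               as.character(label$vertex_ids)), path)
  invisible(path)
}
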