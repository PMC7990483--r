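# Image-based hexahedral meshing: one hex per selected voxel with shared
# corner nodes, dura membrane shells on the brain surface, rigid-skull node
# fixation, restricted Laplacian surface smoothing, and quality reporting.

#' Construct a hex mesh object
#' @param nodes N x 3 matrix of node coordinates, mm.
#' @param hexes E x 8 integer matrix of node indices (VTK hexahedron order).
#' @param hex_tissue Character vector, tissue tag per hex.
#' @param hex_voxel Integer vector, linear index of the source voxel (element
#'   to voxel identity used for segment mapping).
#' @param shells S x 4 integer matrix of node indices (quads), or NULL.
#' @param shell_thickness Numeric per shell, mm.
#' @param shell_tissue Character per shell (`"dura"` or `"skull"`).
#' @param node_sets Named list of integer node-index vectors.
#' @param grid_dim Dimensions of the source label grid.
#' @return Object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, hexes, hex_tissue, hex_voxel,
                     shells = NULL, shell_thickness = numeric(),
                     shell_tissue = character(),
                     node_sets = list(), grid_dim = NULL) {
  stopifnot(ncol(nodes) == 3, ncol(hexes) == 8,
            nrow(hexes) == length(hex_tissue))
  if (max(hexes) > nrow(nodes)) stop("hex node index out of range")
  structure(list(nodes = nodes, hexes = hexes, hex_tissue = hex_tissue,
                 hex_voxel = hex_voxel, shells = shells,
                 shell_thickness = shell_thickness,
                 shell_tissue = shell_tissue,
                 node_sets = node_sets, grid_dim = grid_dim),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("hex_mesh:", nrow(x$nodes), "nodes,", nrow(x$hexes), "hexes,",
      if (is.null(x$shells)) 0 else nrow(x$shells), "shells\n")
  print(table(x$hex_tissue))
  for (nm in names(x$node_sets)) {
    cat("  node set", nm, ":", length(x$node_sets[[nm]]), "nodes\n")
  }
  invisible(x)
}

# linear index helpers on the (nx+1)(ny+1)(nz+1) corner lattice
.corner_id <- function(i, j, k, nd) {
  1L + i + (nd[1] + 1L) * (j + (nd[2] + 1L) * k)
}

#' Convert a label volume to a hexahedral mesh
#'
#' One hexahedron per voxel of the requested tissues, with corner nodes shared
#' between face-adjacent voxels.  Boundary faces (faces with no selected
#' neighbour voxel) receive 20 um dura membrane shells where the neighbouring
#' voxel is dura or skull; outside the craniotomy window those faces also
#' receive rigid skull shells and their nodes enter the `skull_fixed` set.
#' Boundary nodes inside the window form `craniotomy_free`.
#'
#' @param vol A [label_volume()].
#' @param tissues Character vector of tissue names to mesh.
#' @param craniotomy_window List with `x` and `y` world ranges (mm) of the
#'   skull opening; boundary nodes with `z > 0` inside it are left free.
#' @param dura_thickness Dura shell thickness, mm.
#' @return A [hex_mesh()].
#' @export
voxel_to_hex <- function(vol, tissues = c("grey", "white", "csf", "ventricle"),
                         craniotomy_window = list(x = c(0.5, 6.5),
                                                  y = c(-3.5, 3.5)),
                         dura_thickness = 0.02) {
  stopifnot(inherits(vol, "label_volume"))
  lab <- vol$label_map
  codes <- lab[tissues]
  sel <- array(vol$data %in% codes, dim = dim(vol$data))
  if (!any(sel)) stop("no voxels of requested tissue(s): ",
                      paste(tissues, collapse = ", "))
  nd <- dim(vol$data)
  h <- vol$voxel_size
  idx <- which(sel)                       # linear voxel indices, column-major
  ijk <- arrayInd(idx, nd) - 1L           # 0-based voxel indices

  # eight corner ids per hex, VTK ordering (bottom CCW, then top)
  off <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  corner <- matrix(0L, nrow = length(idx), ncol = 8L)
  for (c8 in 1:8) {
    corner[, c8] <- .corner_id(ijk[, 1] + off[c8, 1], ijk[, 2] + off[c8, 2],
                               ijk[, 3] + off[c8, 3], nd)
  }
  used <- sort(unique(as.vector(corner)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  hexes <- matrix(remap[corner], ncol = 8L)

  # node coordinates: voxel corners (centres offset by half a voxel)
  u0 <- used - 1L
  ci <- u0 %% (nd[1] + 1L)
  cj <- (u0 %/% (nd[1] + 1L)) %% (nd[2] + 1L)
  ck <- u0 %/% ((nd[1] + 1L) * (nd[2] + 1L))
  nodes <- cbind(vol$origin[1] + (ci - 0.5) * h[1],
                 vol$origin[2] + (cj - 0.5) * h[2],
                 vol$origin[3] + (ck - 0.5) * h[3])

  tissue_name <- names(lab)[match(vol$data[idx], lab)]

  # boundary faces: neighbour voxel (per face direction) not selected
  pad <- array(FALSE, dim = nd + 2L)
  pad[2:(nd[1] + 1L), 2:(nd[2] + 1L), 2:(nd[3] + 1L)] <- sel
  padlab <- array(lab[["background"]], dim = nd + 2L)
  padlab[2:(nd[1] + 1L), 2:(nd[2] + 1L), 2:(nd[3] + 1L)] <- vol$data
  # face -> local corner quadruple (VTK hex corner numbers), outward per dir
  face_corners <- list(`-x` = c(1L, 4L, 8L, 5L), `+x` = c(2L, 3L, 7L, 6L),
                       `-y` = c(1L, 2L, 6L, 5L), `+y` = c(4L, 3L, 7L, 8L),
                       `-z` = c(1L, 2L, 3L, 4L), `+z` = c(5L, 6L, 7L, 8L))
  dirs <- list(`-x` = c(-1L, 0L, 0L), `+x` = c(1L, 0L, 0L),
               `-y` = c(0L, -1L, 0L), `+y` = c(0L, 1L, 0L),
               `-z` = c(0L, 0L, -1L), `+z` = c(0L, 0L, 1L))
  shell_nodes <- NULL; shell_lab <- character(); shell_th <- numeric()
  boundary_nodes <- integer()
  for (d in names(dirs)) {
    dd <- dirs[[d]]
    ni <- ijk[, 1] + 1L + dd[1] + 1L   # +1 pad, +1 1-based
    nj <- ijk[, 2] + 1L + dd[2] + 1L
    nk <- ijk[, 3] + 1L + dd[3] + 1L
    nb_lin <- cbind(ni, nj, nk)
    is_bound <- !pad[nb_lin]
    if (!any(is_bound)) next
    quad <- hexes[is_bound, face_corners[[d]], drop = FALSE]
    boundary_nodes <- c(boundary_nodes, as.vector(quad))
    nb_label <- padlab[nb_lin][is_bound]
    adjoins_dura <- nb_label %in% c(lab[["dura_surface"]], lab[["skull"]])
    if (any(adjoins_dura)) {
      shell_nodes <- rbind(shell_nodes, quad[adjoins_dura, , drop = FALSE])
      shell_lab <- c(shell_lab, rep("dura", sum(adjoins_dura)))
      shell_th <- c(shell_th, rep(dura_thickness, sum(adjoins_dura)))
    }
  }
  boundary_nodes <- sort(unique(boundary_nodes))

  # craniotomy window: dorsal boundary nodes inside the opening stay free
  bx <- nodes[boundary_nodes, 1]; by <- nodes[boundary_nodes, 2]
  bz <- nodes[boundary_nodes, 3]
  in_window <- bx >= craniotomy_window$x[1] & bx <= craniotomy_window$x[2] &
    by >= craniotomy_window$y[1] & by <= craniotomy_window$y[2] & bz > 0
  craniotomy_free <- boundary_nodes[in_window]
  skull_fixed <- boundary_nodes[!in_window]

  # skull shells: boundary dura faces entirely outside the window (rigid)
  if (!is.null(shell_nodes)) {
    ctr_in_win <- matrix(nodes[shell_nodes, 1], ncol = 4)
    cy <- matrix(nodes[shell_nodes, 2], ncol = 4)
    cz <- matrix(nodes[shell_nodes, 3], ncol = 4)
    face_free <- rowMeans(ctr_in_win) >= craniotomy_window$x[1] &
      rowMeans(ctr_in_win) <= craniotomy_window$x[2] &
      rowMeans(cy) >= craniotomy_window$y[1] &
      rowMeans(cy) <= craniotomy_window$y[2] & rowMeans(cz) > 0
    n_sk <- sum(!face_free)
    if (n_sk > 0) {
      shell_nodes <- rbind(shell_nodes, shell_nodes[!face_free, , drop = FALSE])
      shell_lab <- c(shell_lab, rep("skull", n_sk))
      shell_th <- c(shell_th, rep(0, n_sk))
    }
  }

  # CSF/cortex interface: nodes on faces between csf and grey voxels
  interface_nodes <- integer()
  if (all(c("csf", "grey") %in% tissues)) {
    is_csf <- vol$data[idx] == lab[["csf"]]
    for (d in names(dirs)) {
      dd <- dirs[[d]]
      nb_lab <- padlab[cbind(ijk[, 1] + 2L + dd[1], ijk[, 2] + 2L + dd[2],
                             ijk[, 3] + 2L + dd[3])]
      hit <- is_csf & nb_lab == lab[["grey"]]
      if (any(hit)) {
        interface_nodes <- c(interface_nodes,
                             as.vector(hexes[hit, face_corners[[d]]]))
      }
    }
    interface_nodes <- sort(unique(interface_nodes))
  }

  hex_mesh(nodes, hexes, tissue_name, idx,
           shells = shell_nodes, shell_thickness = shell_th,
           shell_tissue = shell_lab,
           node_sets = list(skull_fixed = skull_fixed,
                            craniotomy_free = craniotomy_free,
                            outer_surface = boundary_nodes,
                            csf_cortex_interface = interface_nodes),
           grid_dim = nd)
}

# corner-neighbour table for trilinear Jacobians: for corner c the three
# corners reached along the +/-xi, +/-eta, +/-zeta edges, with parametric sign
.hex_corner_neighbours <- local({
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  nb <- array(0L, dim = c(8, 3)); sg <- array(0, dim = c(8, 3))
  for (c8 in 1:8) for (ax in 1:3) {
    flip <- coords[c8, ]; flip[ax] <- 1 - flip[ax]
    nb[c8, ax] <- which(apply(coords, 1, function(r) all(r == flip)))
    sg[c8, ax] <- 1 - 2 * coords[c8, ax]
  }
  list(nb = nb, sg = sg)
})

#' Corner Jacobians of every hexahedron
#'
#' @param mesh A `hex_mesh`.
#' @param scaled If TRUE divide each corner determinant by the product of the
#'   three incident edge lengths (scaled Jacobian, 1 for a cube).
#' @return E x 8 matrix of (scaled) corner Jacobian determinants.
#' @export
corner_jacobians <- function(mesh, scaled = FALSE) {
  nb <- .hex_corner_neighbours$nb; sg <- .hex_corner_neighbours$sg
  E <- nrow(mesh$hexes)
  out <- matrix(0, E, 8)
  X <- mesh$nodes
  for (c8 in 1:8) {
    p0 <- mesh$hexes[, c8]
    d <- lapply(1:3, function(ax) {
      (X[mesh$hexes[, nb[c8, ax]], , drop = FALSE] -
         X[p0, , drop = FALSE]) * sg[c8, ax]
    })
    det <- d[[1]][, 1] * (d[[2]][, 2] * d[[3]][, 3] - d[[2]][, 3] * d[[3]][, 2]) -
           d[[1]][, 2] * (d[[2]][, 1] * d[[3]][, 3] - d[[2]][, 3] * d[[3]][, 1]) +
           d[[1]][, 3] * (d[[2]][, 1] * d[[3]][, 2] - d[[2]][, 2] * d[[3]][, 1])
    if (scaled) {
      len <- sqrt(rowSums(d[[1]]^2)) * sqrt(rowSums(d[[2]]^2)) *
        sqrt(rowSums(d[[3]]^2))
      det <- det / len
    }
    out[, c8] <- det
  }
  out
}

#' Element volumes (corner-quadrature of the trilinear Jacobian)
#' @param mesh A `hex_mesh`.
#' @return Numeric vector of element volumes, mm^3.
#' @export
element_volumes <- function(mesh) {
  rowMeans(corner_jacobians(mesh, scaled = FALSE))
}

#' Taubin smoothing restricted to the model surface and CSF/cortex interface
#'
#' Each iteration performs a Laplacian shrink pass (step `relaxation` toward
#' the centroid of edge-connected neighbours within the same node set)
#' followed by a Taubin inflate pass (step `relaxation / (0.1 * relaxation -
#' 1)`), which keeps the enclosed volume nearly constant while still removing
#' the voxel staircase.  Interior nodes are untouched.  If any corner
#' Jacobian becomes non-positive the operation aborts identifying the
#' offending element.
#'
#' @param mesh A `hex_mesh` with populated `outer_surface` and
#'   `csf_cortex_interface` node sets.
#' @param iterations Number of passes (0 returns the input unchanged).
#' @param relaxation Step fraction in (0, 1].
#' @return The smoothed `hex_mesh`.
#' @export
smooth_surface <- function(mesh, iterations = 5, relaxation = 0.5) {
  stopifnot(iterations >= 0, relaxation > 0, relaxation <= 1)
  if (iterations == 0) return(mesh)
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                      c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                      c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  all_edges <- do.call(rbind, lapply(seq_len(nrow(edge_pairs)), function(e) {
    cbind(mesh$hexes[, edge_pairs[e, 1]], mesh$hexes[, edge_pairs[e, 2]])
  }))
  all_edges <- rbind(all_edges, all_edges[, 2:1])
  sets <- list(mesh$node_sets$outer_surface, mesh$node_sets$csf_cortex_interface)
  sets[[2]] <- setdiff(sets[[2]], sets[[1]])   # surface membership wins
  X <- mesh$nodes
  for (s in sets) {
    if (length(s) < 2) next
    in_set <- logical(nrow(X)); in_set[s] <- TRUE
    keep <- in_set[all_edges[, 1]] & in_set[all_edges[, 2]]
    ed <- unique(all_edges[keep, , drop = FALSE])
    mu <- relaxation / (0.1 * relaxation - 1)   # Taubin pass-band inflate step
    for (it in seq_len(iterations)) {
      for (step in c(relaxation, mu)) {
        sums <- rowsum(X[ed[, 2], , drop = FALSE], ed[, 1])
        cnt <- as.vector(rowsum(rep(1, nrow(ed)), ed[, 1]))
        ids <- as.integer(rownames(sums))
        centroid <- sums / cnt
        X[ids, ] <- X[ids, ] + step * (centroid - X[ids, , drop = FALSE])
      }
    }
  }
  out <- mesh; out$nodes <- X
  jac <- corner_jacobians(out)
  bad <- which(apply(jac, 1, min) <= 0)
  if (length(bad) > 0) {
    stop("surface smoothing inverted element(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Mesh quality report
#' @param mesh A nonempty `hex_mesh`.
#' @return List: node/element/shell counts, min scaled corner Jacobian,
#'   element volume range and total volume (mm^3).
#' @export
mesh_quality <- function(mesh) {
  stopifnot(nrow(mesh$hexes) > 0)
  jac <- corner_jacobians(mesh, scaled = TRUE)
  vols <- element_volumes(mesh)
  list(n_nodes = nrow(mesh$nodes), n_hexes = nrow(mesh$hexes),
       n_shells = if (is.null(mesh$shells)) 0L else nrow(mesh$shells),
       min_scaled_jacobian = min(jac),
       volume_range = range(vols), total_volume = sum(vols))
}

#' Boundary faces of the mesh (faces used by exactly one hex)
#' @param mesh A `hex_mesh`.
#' @return B x 4 integer matrix of node quadruples.
#' @export
boundary_faces <- function(mesh) {
  fc <- list(c(1L, 4L, 8L, 5L), c(2L, 3L, 7L, 6L), c(1L, 2L, 6L, 5L),
             c(4L, 3L, 7L, 8L), c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L))
  faces <- do.call(rbind, lapply(fc, function(q) mesh$hexes[, q, drop = FALSE]))
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Write / read a mesh as legacy ASCII VTK unstructured grid
#'
#' Hexes (VTK cell type 12) and shells (type 9) with tissue tags as cell data;
#' node sets and shell metadata go to a JSON sidecar `<path>.json`.
#'
#' @param mesh A `hex_mesh`.
#' @param path Output `.vtk` path.
#' @return `read_mesh_vtk()` returns a `hex_mesh`; the writer returns `path`.
#' @export
write_mesh_vtk <- function(mesh, path) {
  n_hex <- nrow(mesh$hexes)
  n_sh <- if (is.null(mesh$shells)) 0L else nrow(mesh$shells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ccistrain mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  utils::write.table(format(mesh$nodes, digits = 12, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  cells <- cbind(8L, mesh$hexes - 1L)
  writeLines(paste("CELLS", n_hex + n_sh,
                   9L * n_hex + 5L * n_sh), con)
  utils::write.table(cells, con, row.names = FALSE, col.names = FALSE)
  if (n_sh > 0) {
    utils::write.table(cbind(4L, mesh$shells - 1L), con,
                       row.names = FALSE, col.names = FALSE)
  }
  writeLines(paste("CELL_TYPES", n_hex + n_sh), con)
  writeLines(as.character(c(rep(12L, n_hex), rep(9L, n_sh))), con)
  writeLines(c(paste("CELL_DATA", n_hex + n_sh),
               "SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  tiss_levels <- c("grey", "white", "csf", "ventricle", "dura", "skull")
  codes <- c(match(mesh$hex_tissue, tiss_levels),
             if (n_sh > 0) match(mesh$shell_tissue, tiss_levels))
  writeLines(as.character(codes), con)
  jsonlite::write_json(list(node_sets = mesh$node_sets,
                            hex_voxel = mesh$hex_voxel,
                            shell_thickness = mesh$shell_thickness,
                            grid_dim = mesh$grid_dim),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  np <- as.integer(strsplit(lines[grep("^POINTS", lines)], " ")[[1]][2])
  p0 <- grep("^POINTS", lines)
  nodes <- matrix(scan(text = lines[(p0 + 1):(p0 + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  c0 <- grep("^CELLS", lines)
  nc <- as.integer(strsplit(lines[c0], " ")[[1]][2])
  cell_lines <- lines[(c0 + 1):(c0 + nc)]
  sizes <- as.integer(vapply(strsplit(cell_lines, " +"), `[[`, "", 1))
  hex_rows <- which(sizes == 8L); quad_rows <- which(sizes == 4L)
  parse_rows <- function(rows, k) {
    if (length(rows) == 0) return(NULL)
    m <- matrix(scan(text = cell_lines[rows], quiet = TRUE),
                ncol = k + 1, byrow = TRUE)[, -1, drop = FALSE] + 1L
    storage.mode(m) <- "integer"
    m
  }
  hexes <- parse_rows(hex_rows, 8)
  shells <- parse_rows(quad_rows, 4)
  d0 <- grep("^LOOKUP_TABLE", lines)[1]
  codes <- as.integer(lines[(d0 + 1):(d0 + nc)])
  tiss_levels <- c("grey", "white", "csf", "ventricle", "dura", "skull")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hex_mesh(nodes, hexes, tiss_levels[codes[hex_rows]],
           as.integer(meta$hex_voxel),
           shells = shells,
           shell_thickness = as.numeric(meta$shell_thickness),
           shell_tissue = tiss_levels[codes[quad_rows]],
           node_sets = lapply(meta$node_sets, as.integer),
           grid_dim = as.integer(meta$grid_dim))
}
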