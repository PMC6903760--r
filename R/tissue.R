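#' @useDynLib pcpsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm uniroot sd
NULL

# ---- periodic-geometry helpers ------------------------------------------

wrap_coords <- function(xy, box) {
  xy[, 1] <- xy[, 1] - box[1] * floor(xy[, 1] / box[1])
  xy[, 2] <- xy[, 2] - box[2] * floor(xy[, 2] / box[2])
  xy
}

# minimum-image displacement from points `a` to points `b` (n x 2 each)
min_image <- function(d, box) {
  d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
  d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
  d
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

polygon_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# ---- tissue construction from polygon loops -----------------------------

# Build the half-edge tissue structure from per-cell vertex loops given in
# *unwrapped* coordinates (each loop locally continuous; any orientation).
# Vertices are identified across cells by quantizing wrapped coordinates on
# a grid of size `tol`, checking the 3x3 neighbourhood of bins (modulo the
# box) so points straddling a bin boundary still merge.
tissue_from_polygons <- function(polys, box, l0 = 1, tol = NULL) {
  if (is.null(tol)) tol <- 1e-6 * l0
  nb <- c(max(3L, ceiling(box[1] / tol)), max(3L, ceiling(box[2] / tol)))
  venv <- new.env(hash = TRUE, parent = emptyenv())
  vx <- numeric(0); vy <- numeric(0)
  nv <- 0L

  vertex_id <- function(x, y) {
    wx <- x - box[1] * floor(x / box[1])
    wy <- y - box[2] * floor(y / box[2])
    ix <- floor(wx / tol); iy <- floor(wy / tol)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste((ix + dx) %% nb[1], (iy + dy) %% nb[2])
      ids <- venv[[key]]
      if (!is.null(ids)) {
        ddx <- abs(vx[ids] - wx); ddx <- pmin(ddx, box[1] - ddx)
        ddy <- abs(vy[ids] - wy); ddy <- pmin(ddy, box[2] - ddy)
        hit <- which(ddx < tol & ddy < tol)
        if (length(hit)) return(ids[hit[1]])
      }
    }
    nv <<- nv + 1L
    vx[nv] <<- wx; vy[nv] <<- wy
    key <- paste(ix %% nb[1], iy %% nb[2])
    venv[[key]] <- c(venv[[key]], nv)
    nv
  }

  n_cells <- length(polys)
  cell_poly <- vector("list", n_cells)
  cell_vids <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    p <- polys[[ci]]
    # drop consecutive (near-)duplicate vertices, then enforce CCW
    n <- nrow(p)
    keep <- rep(TRUE, n)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (max(abs(p[k, ] - p[k2, ])) < tol) keep[k2] <- FALSE
    }
    p <- p[keep, , drop = FALSE]
    if (nrow(p) < 3L) stop("degenerate polygon for cell ", ci)
    if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    cell_poly[[ci]] <- p
    cell_vids[[ci]] <- vapply(seq_len(nrow(p)),
                              function(k) vertex_id(p[k, 1], p[k, 2]), 0L)
    if (anyDuplicated(cell_vids[[ci]]))
      stop("self-intersecting or pinched polygon for cell ", ci)
  }

  # edges: keyed by unordered vertex pair
  eenv <- new.env(hash = TRUE, parent = emptyenv())
  ev <- matrix(0L, 0, 2); ecl <- matrix(NA_integer_, 0, 2)
  n_edges <- 0L
  he_edge <- integer(0); he_cell <- integer(0); he_seg <- integer(0)
  cell_he <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    vid <- cell_vids[[ci]]
    m <- length(vid)
    hes <- integer(m)
    for (k in seq_len(m)) {
      a <- vid[k]; b <- vid[if (k == m) 1L else k + 1L]
      key <- paste(min(a, b), max(a, b))
      eid <- eenv[[key]]
      if (is.null(eid)) {
        n_edges <- n_edges + 1L
        eid <- n_edges
        eenv[[key]] <- eid
        ev <- rbind(ev, c(a, b))
        ecl <- rbind(ecl, c(ci, NA_integer_))   # CCW: owner on the left
      } else {
        if (!is.na(ecl[eid, 2]))
          stop("edge shared by more than two cells (vertices ", a, ",", b, ")")
        if (ev[eid, 1] == a)
          stop("inconsistent edge orientation between cells ",
               ecl[eid, 1], " and ", ci)
        ecl[eid, 2] <- ci
      }
      he_edge <- c(he_edge, eid); he_cell <- c(he_cell, ci); he_seg <- c(he_seg, k)
      hes[k] <- length(he_edge)
    }
    cell_he[[ci]] <- hes
  }
  if (anyNA(ecl[, 2]))
    stop("tissue is not periodically closed: ", sum(is.na(ecl[, 2])),
         " edge(s) border only one cell")

  # opposite half-edges: the two half-edges of each edge
  he_of_edge <- split(seq_along(he_edge), he_edge)
  he_opp <- integer(length(he_edge))
  for (e in seq_len(n_edges)) {
    pr <- he_of_edge[[as.character(e)]]
    he_opp[pr[1]] <- pr[2]; he_opp[pr[2]] <- pr[1]
  }

  # geometry from the unwrapped per-cell loops
  n_he <- length(he_edge)
  he_len <- numeric(n_he); he_mid <- matrix(0, n_he, 2); he_nhat <- matrix(0, n_he, 2)
  area <- numeric(n_cells); centroid <- matrix(0, n_cells, 2)
  for (ci in seq_len(n_cells)) {
    p <- cell_poly[[ci]]
    m <- nrow(p)
    area[ci] <- polygon_area(p)
    centroid[ci, ] <- polygon_centroid(p)
    for (k in seq_len(m)) {
      h <- cell_he[[ci]][k]
      a <- p[k, ]; b <- p[if (k == m) 1L else k + 1L, ]
      he_len[h] <- sqrt(sum((b - a)^2))
      he_mid[h, ] <- (a + b) / 2
      dn <- he_mid[h, ] - centroid[ci, ]
      he_nhat[h, ] <- dn / sqrt(sum(dn^2))
    }
  }
  if (any(area <= 0)) stop("cell ", which(area <= 0)[1], " has non-positive area")

  e_len <- he_len[vapply(he_of_edge, `[`, 0L, 1)[order(as.integer(names(he_of_edge)))]]
  t <- structure(list(
    box = box, l0 = l0, tol = tol,
    vertices = cbind(vx[seq_len(nv)], vy[seq_len(nv)]),
    edge_vertices = ev, edge_cells = ecl, edge_length = e_len,
    he_edge = he_edge, he_cell = he_cell, he_opp = he_opp,
    he_length = he_len, he_mid = he_mid, he_nhat = he_nhat,
    cell_he = cell_he, cell_poly = cell_poly,
    area = area, centroid = centroid,
    n_cells = n_cells, n_edges = n_edges, n_vertices = nv, n_he = n_he
  ), class = "pcp_tissue")
  t
}

#' Validate the structural invariants of a tissue
#'
#' Checks that every edge borders exactly two distinct cells, that all edge
#' lengths and cell areas are positive, that areas tile the periodic box,
#' and that the Euler characteristic of the torus (V - E + F = 0) holds.
#'
#' @param tissue a `pcp_tissue` object.
#' @param tol relative tolerance for the area-tiling check.
#' @return `tissue`, invisibly; errors describe the violated invariant.
#' @export
validate_tissue <- function(tissue, tol = 1e-8) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  with(tissue, {
    if (n_vertices - n_edges + n_cells != 0L)
      stop("Euler characteristic V - E + F = ",
           n_vertices - n_edges + n_cells, " (expected 0 on the torus)")
    if (any(edge_cells[, 1] == edge_cells[, 2]))
      stop("edge bordered twice by the same cell")
    if (any(edge_length <= 0)) stop("non-positive edge length")
    if (any(area <= 0)) stop("non-positive cell area")
    if (abs(sum(area) - box[1] * box[2]) > tol * box[1] * box[2])
      stop("cell areas do not tile the box: sum = ", sum(area),
           ", box area = ", box[1] * box[2])
    # the two half-edges of an edge must agree on its length
    if (max(abs(he_length - he_length[he_opp])) > 1e-9 * l0)
      stop("half-edge length mismatch across an edge")
  })
  invisible(tissue)
}

#' @export
print.pcp_tissue <- function(x, ...) {
  cat(sprintf(paste0(
    "Periodic tissue: %d cells, %d edges, %d vertices\n",
    "  box %.4g x %.4g, mean edge length %.4g (target l0 = %g)\n"),
    x$n_cells, x$n_edges, x$n_vertices,
    x$box[1], x$box[2], mean(x$edge_length), x$l0))
  invisible(x)
}

# ---- serialization -------------------------------------------------------

#' Write a tissue to a versioned JSON file
#'
#' The schema stores the box, vertex positions, per-cell ordered vertex
#' loops, and the nominal junction length `l0`; everything else (edges,
#' half-edges, areas) is re-derived on load, so a round trip reproduces the
#' tissue exactly.
#'
#' @param tissue a `pcp_tissue`.
#' @param path output file path.
#' @export
write_tissue_json <- function(tissue, path) {
  vids <- lapply(seq_len(tissue$n_cells), function(ci) {
    he <- tissue$cell_he[[ci]]
    # first vertex of each half-edge segment, in loop order
    vapply(seq_along(he), function(k) {
      e <- tissue$he_edge[he[k]]
      # orientation: owner cell is on the left, so the half-edge of the
      # first-registered cell runs v1 -> v2
      if (tissue$edge_cells[e, 1] == ci) tissue$edge_vertices[e, 1]
      else tissue$edge_vertices[e, 2]
    }, 0L)
  })
  obj <- list(
    format = "pcpsim-tissue", version = 1L,
    box = tissue$box, l0 = tissue$l0,
    vertices = tissue$vertices,
    cells = vids
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a tissue written by [write_tissue_json()]
#'
#' @param path JSON file path.
#' @return a `pcp_tissue`.
#' @export
read_tissue_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pcpsim-tissue"))
    stop("not a pcpsim tissue file: ", path)
  box <- as.numeric(obj$box)
  verts <- as.matrix(obj$vertices)
  cells <- obj$cells
  if (is.matrix(cells))   # equal-size cells simplify to a matrix on read
    cells <- lapply(seq_len(nrow(cells)), function(i) cells[i, ])
  polys <- lapply(cells, function(vid) {
    p <- verts[as.integer(vid), , drop = FALSE]
    # unwrap the loop: successive vertices are nearest images of each other
    for (k in 2:nrow(p)) {
      d <- min_image(matrix(p[k, ] - p[k - 1, ], 1), box)
      p[k, ] <- p[k - 1, ] + d
    }
    p
  })
  validate_tissue(tissue_from_polygons(polys, box, l0 = obj$l0))
}
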