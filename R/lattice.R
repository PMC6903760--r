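# Tissue generators and geometric transforms.
#
# All tissues live on a torus: rectangular box, periodic in x and y.
# Disordered tissues are periodic Voronoi tessellations of displaced
# triangular-lattice seeds, built by half-plane clipping (each cell is the
# intersection of bisector half-planes against nearby seed images), which
# is exact for point seeds and needs no external geometry library.

#' Build a regular hexagonal tissue on a torus
#'
#' Cells are regular hexagons with edge length `l0` ("pointy-top"
#' orientation), arranged as `nx` columns by `ny` rows of cells with
#' periodic boundaries along both axes.  `ny` must be even for the row
#' offset to close periodically.
#'
#' @param nx,ny number of cells along x and y; `nx >= 2`, `ny >= 2` and even.
#' @param l0 junction (hexagon edge) length; the mean junction length of the
#'   tissue equals `l0` exactly.
#' @return a `pcp_tissue` with `nx * ny` cells, every vertex of degree 3.
#' @examples
#' t <- build_hexagonal(4, 4)
#' range(t$edge_length)   # all exactly 1
#' @export
build_hexagonal <- function(nx, ny, l0 = 1) {
  if (nx < 2 || ny < 2) stop("nx and ny must both be at least 2")
  if (ny %% 2 != 0)
    stop("ny must be even: odd row counts cannot close periodically ",
         "(alternate rows are offset by half a cell)")
  if (l0 <= 0) stop("l0 must be positive")
  a <- sqrt(3) * l0                      # center-to-center spacing
  box <- c(nx * a, ny * 1.5 * l0)
  ang <- pi / 6 + (0:5) * pi / 3         # vertex angles: 30, 90, ..., 330 deg
  hexv <- l0 * cbind(cos(ang), sin(ang))
  polys <- vector("list", nx * ny)
  k <- 0L
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    k <- k + 1L
    cx <- (i + 0.5 * (j %% 2)) * a
    cy <- j * 1.5 * l0
    polys[[k]] <- cbind(hexv[, 1] + cx, hexv[, 2] + cy)
  }
  validate_tissue(tissue_from_polygons(polys, box, l0 = l0))
}

# periodic Voronoi cell of seed `i` by half-plane clipping; returns the
# polygon in coordinates relative to the seed
voronoi_cell <- function(i, seeds, box, rcut) {
  p <- rbind(c(-rcut, -rcut), c(rcut, -rcut), c(rcut, rcut), c(-rcut, rcut))
  nimg <- c(ceiling(rcut / box[1]), ceiling(rcut / box[2]))
  for (j in seq_len(nrow(seeds))) {
    d0 <- seeds[j, ] - seeds[i, ]
    for (kx in -nimg[1]:nimg[1]) for (ky in -nimg[2]:nimg[2]) {
      if (j == i && kx == 0 && ky == 0) next
      d <- d0 + c(kx * box[1], ky * box[2])
      r2 <- sum(d^2)
      if (r2 >= (2 * rcut)^2) next
      # keep x . d <= |d|^2 / 2  (Sutherland-Hodgman clip)
      s <- p %*% d - r2 / 2
      if (all(s <= 0)) next
      n <- nrow(p)
      out <- matrix(0, 0, 2)
      for (k in seq_len(n)) {
        k2 <- if (k == n) 1L else k + 1L
        in1 <- s[k] <= 0; in2 <- s[k2] <= 0
        if (in1) out <- rbind(out, p[k, ])
        if (xor(in1, in2)) {
          tt <- s[k] / (s[k] - s[k2])
          out <- rbind(out, p[k, ] + tt * (p[k2, ] - p[k, ]))
        }
      }
      p <- out
      if (nrow(p) < 3L) stop("empty Voronoi cell for seed ", i)
    }
  }
  p
}

# Voronoi tissue from seed points in the periodic box
voronoi_tissue <- function(seeds, box, l0) {
  seeds <- wrap_coords(seeds, box)
  rcut <- 4.5 * l0
  repeat {
    polys <- lapply(seq_len(nrow(seeds)), function(i) {
      p <- voronoi_cell(i, seeds, box, rcut)
      cbind(p[, 1] + seeds[i, 1], p[, 2] + seeds[i, 2])
    })
    reach <- max(vapply(seq_along(polys), function(i) {
      max(abs(cbind(polys[[i]][, 1] - seeds[i, 1],
                    polys[[i]][, 2] - seeds[i, 2])))
    }, 0))
    if (reach < rcut / 2) break
    rcut <- 2 * rcut                     # cell touched the clip window: redo
  }
  t <- validate_tissue(tissue_from_polygons(polys, box, l0 = l0))
  t$seeds <- seeds                       # generating points, kept so later
  t                                      # transforms can act on them exactly
}

#' Apply geometric disorder to a tissue
#'
#' Displaces the cell centers (seeds of a triangular lattice for hexagonal
#' input) by i.i.d. random vectors of magnitude `epsilon0 * l0 * U[0, 1]`
#' and uniform angle, and rebuilds the tissue as the periodic Voronoi
#' tessellation of the displaced seeds.  `epsilon0 = 0` returns the input
#' unchanged; `epsilon0` around 0.6 gives strongly disordered tissues with
#' a broad distribution of neighbour counts and junction lengths.
#'
#' @param tissue a `pcp_tissue` (typically from [build_hexagonal()]).
#' @param epsilon0 disorder magnitude in `[0, 1]`.
#' @param seed integer seed; the construction is deterministic given it.
#' @return a `pcp_tissue` with the same number of cells and the same box.
#' @export
apply_disorder <- function(tissue, epsilon0, seed) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  if (epsilon0 < 0 || epsilon0 > 1)
    stop("epsilon0 must lie in [0, 1], got ", epsilon0)
  if (epsilon0 == 0) return(tissue)
  n <- tissue$n_cells
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- epsilon0 * tissue$l0 * runif(n)
  th <- runif(n, 0, 2 * pi)
  seeds <- tissue$centroid + cbind(r * cos(th), r * sin(th))
  voronoi_tissue(seeds, tissue$box, tissue$l0)
}

# second-moment (shape) tensor of a polygon about its centroid, divided by
# area; returns c(Sxx, Syy, Sxy)
polygon_shape_tensor <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (a < 0) {
    p <- p[rev(seq_len(n)), , drop = FALSE]
    cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
    a <- sum(cr) / 2
  }
  cx <- sum((p[, 1] + p[j, 1]) * cr) / (6 * a)
  cy <- sum((p[, 2] + p[j, 2]) * cr) / (6 * a)
  sxx <- sum(cr * (p[, 1]^2 + p[, 1] * p[j, 1] + p[j, 1]^2)) / 12
  syy <- sum(cr * (p[, 2]^2 + p[, 2] * p[j, 2] + p[j, 2]^2)) / 12
  sxy <- sum(cr * (p[, 1] * p[j, 2] + 2 * p[, 1] * p[, 2] +
                   2 * p[j, 1] * p[j, 2] + p[j, 1] * p[, 2])) / 24
  c(sxx / a - cx^2, syy / a - cy^2, sxy / a - cx * cy)
}

shape_from_tensor <- function(sxx, syy, sxy) {
  tr <- sxx + syy
  disc <- sqrt(pmax(0, (sxx - syy)^2 + 4 * sxy^2))
  ei <- disc / tr
  phi <- (atan2(2 * sxy, sxx - syy) / 2) * 180 / pi
  phi <- phi %% 180
  list(E = ei, phi = phi)
}

#' Per-cell and tissue-level shape statistics
#'
#' The elongation of each cell is measured from the area-normalized second
#' moment tensor of its polygon: with eigenvalues `a >= b`, the elongation
#' index is `Ei = (a - b)/(a + b)` (0 for any regular polygon) and the
#' elongation angle `phi_e` is the direction of the leading eigenvector,
#' in degrees from the x axis, in `[0, 180)`.  Tissue-level `E` and
#' `phi_e` are computed from the area-weighted mean of the per-cell
#' normalized tensors.
#'
#' @param tissue a `pcp_tissue`.
#' @return a list with `cells` (data.frame: `area`, `Ei`, `phi_ie`) and
#'   tissue aggregates `E`, `phi_e`.
#' @export
cell_shape_stats <- function(tissue) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  if (any(tissue$area <= 0))
    stop("degenerate cell (non-positive area): cell ",
         which(tissue$area <= 0)[1])
  tens <- t(vapply(tissue$cell_poly, polygon_shape_tensor, numeric(3)))
  per <- shape_from_tensor(tens[, 1], tens[, 2], tens[, 3])
  per$phi[per$E < 1e-12] <- NA_real_
  w <- tissue$area / sum(tissue$area)
  # normalize each cell tensor to unit trace before averaging so large
  # cells do not dominate through sheer size
  trc <- tens[, 1] + tens[, 2]
  mt <- colSums(w * tens / trc)
  tis <- shape_from_tensor(mt[1], mt[2], mt[3])
  list(cells = data.frame(area = tissue$area, Ei = per$E, phi_ie = per$phi),
       E = tis$E, phi_e = tis$phi)
}

#' Elongate a tissue by an area-preserving affine map
#'
#' Stretches along the requested axis and compresses along the
#' perpendicular axis with determinant 1, so the total area is unchanged.
#' The stretch factor is calibrated so that the *measured* tissue
#' elongation index (see [cell_shape_stats()]) equals the requested `E`.
#' Only axis-aligned elongation (`phi_e` a multiple of 90 degrees) is
#' supported, because an oblique stretch would shear the rectangular
#' periodic box.
#'
#' @param tissue a `pcp_tissue`.
#' @param E target tissue elongation index, `>= 0`; `E = 0` is the identity.
#' @param phi_e elongation axis in degrees from the x-axis (0 or 90, modulo
#'   180).
#' @return the transformed `pcp_tissue`.
#' @export
apply_elongation <- function(tissue, E, phi_e = 90) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  if (E < 0) stop("E must be non-negative")
  if (E == 0) return(tissue)
  if (E >= 1) stop("E must be below 1")
  phi <- phi_e %% 180
  if (!(abs(phi) < 1e-9 || abs(phi - 90) < 1e-9))
    stop("only axis-aligned elongation is supported (phi_e = 0 or 90)")
  along_y <- abs(phi - 90) < 1e-9

  stretch <- function(s) {
    sc <- if (along_y) c(1 / s, s) else c(s, 1 / s)
    polys <- lapply(tissue$cell_poly, function(p)
      cbind(p[, 1] * sc[1], p[, 2] * sc[2]))
    box <- tissue$box * sc
    tissue_from_polygons(polys, box, l0 = tissue$l0)
  }
  measured <- function(s) cell_shape_stats(stretch(s))$E - E
  s0 <- ((1 + E) / (1 - E))^(1 / 4)      # exact for an isotropic tissue
  lo <- 1 + 1e-9; hi <- s0 * 1.5
  while (measured(hi) < 0) hi <- hi * 1.5
  s <- uniroot(measured, c(lo, hi), tol = 1e-6)$root
  validate_tissue(stretch(s))
}

#' Specification of a geometric mutant clone
#'
#' @param center numeric length-2: clone center in box coordinates.
#' @param radius clone radius in length units (use multiples of the cell
#'   diameter `sqrt(3) * l0` for a cell-count-like radius).
#' @param eps_patch extra disorder magnitude inside the patch, in `[0, 1]`.
#' @param shrink cell area shrink factor inside the patch, in `(0, 1]`.
#' @param transition width of the linear ramp from full clone effect to
#'   background, in length units.
#' @return an object of class `pcp_clone_geometry`.
#' @export
geometric_clone_spec <- function(center, radius, eps_patch = 0.6,
                                 shrink = 0.6, transition = 2) {
  if (radius <= 0) stop("radius must be positive")
  if (shrink <= 0 || shrink > 1) stop("shrink must lie in (0, 1]")
  if (eps_patch < 0 || eps_patch > 1) stop("eps_patch must lie in [0, 1]")
  if (transition < 0) stop("transition must be non-negative")
  structure(list(center = as.numeric(center), radius = radius,
                 eps_patch = eps_patch, shrink = shrink,
                 transition = transition),
            class = "pcp_clone_geometry")
}

#' Carve a geometrically disordered, shrunken-cell clone into a tissue
#'
#' Inside the clone radius, cell seeds are contracted towards the clone
#' center (shrinking cell areas by roughly the `shrink` factor) and given
#' additional random displacement of magnitude `eps_patch * l0`; both
#' effects ramp linearly to zero over the transition width, so the patch
#' dissolves smoothly into the background.  The tissue is rebuilt as a
#' periodic Voronoi tessellation, which keeps the topology valid by
#' construction.
#'
#' @param tissue a `pcp_tissue` (background, possibly already disordered).
#' @param spec a [geometric_clone_spec()].
#' @param seed integer seed for the patch displacements.
#' @return a `pcp_tissue`.
#' @export
carve_geometric_clone <- function(tissue, spec, seed) {
  stopifnot(inherits(tissue, "pcp_tissue"),
            inherits(spec, "pcp_clone_geometry"))
  if (2 * (spec$radius + spec$transition) > min(tissue$box))
    stop("clone (radius + transition = ", spec$radius + spec$transition,
         ") does not fit inside the box")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- tissue$n_cells
  base <- if (!is.null(tissue$seeds)) tissue$seeds else tissue$centroid
  d <- min_image(sweep(base, 2, spec$center), tissue$box)
  rho <- sqrt(rowSums(d^2))
  w <- pmin(1, pmax(0, (spec$radius + spec$transition - rho) /
                      max(spec$transition, 1e-12)))
  # contract radially: linear shrink sqrt(shrink) in each direction gives
  # area factor ~ shrink at full weight
  contr <- 1 - (1 - sqrt(spec$shrink)) * w
  r <- spec$eps_patch * tissue$l0 * runif(n) * w
  th <- runif(n, 0, 2 * pi)
  seeds <- sweep(d * contr, 2, spec$center, "+") +
    cbind(r * cos(th), r * sin(th))
  voronoi_tissue(seeds, tissue$box, tissue$l0)
}
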