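# Intracellular interaction operators.
#
# Complexes on junction nu of a cell modulate the kinetics on junction mu
# of the same cell through diffusing cytoplasmic messengers whose
# steady-state concentration decays as exp(-r/lambda) from the source.
# With protein uniformly distributed along junctions, the coupling of two
# junctions is the kernel integrated along both segments.  Distances are
# straight chords through the cell interior (cytosolic diffusion), not arc
# length along the membrane.

gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (e$values[ord] + 1) / 2, w = (2 * e$vectors[1, ord]^2) / 2)
}

# 2-panel 8-point Gauss-Legendre nodes on [0,1]; 16 nodes per segment
.kernel_quad <- local({
  g <- gauss_legendre(8)
  list(x = c(g$x / 2, 0.5 + g$x / 2), w = c(g$w, g$w) / 2)
})

# closed form of the length-normalized self integral
# (1/l^2) int_0^l int_0^l exp(-|s-s'|/lambda) ds ds'
kernel_self <- function(l, lambda) {
  2 * lambda * (l - lambda * (1 - exp(-l / lambda))) / l^2
}

#' Raw pairwise junction kernel of one cell
#'
#' Entry (mu, nu) is the exponential kernel averaged over both junction
#' segments, `(1/(l_mu l_nu)) int_mu int_nu exp(-|r - r'|/lambda) ds ds'`,
#' with straight-line (chord) distances.  Cross terms use fixed-order
#' Gauss-Legendre quadrature (two 8-point panels per segment); the
#' diagonal uses the exact closed form of the collinear double integral.
#' In the limit of short segments the entry tends to `exp(-d/lambda)` for
#' midpoint distance `d`.
#'
#' @param tissue a `pcp_tissue`.
#' @param cell cell index.
#' @param lambda interaction length scale, `> 0`.
#' @return a symmetric `m x m` matrix over the cell's half-edges (in
#'   `tissue$cell_he[[cell]]` order).
#' @export
pairwise_edge_kernel <- function(tissue, cell, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  p <- tissue$cell_poly[[cell]]
  lens <- tissue$he_length[tissue$cell_he[[cell]]]
  polygon_kernel(p, lens, lambda)
}

# raw kernel matrix for an explicit polygon (rows of p = vertices, CCW)
polygon_kernel <- function(p, lens, lambda) {
  m <- nrow(p)
  nxt <- c(2:m, 1)
  qx <- .kernel_quad$x; qw <- .kernel_quad$w
  # quadrature points along each segment: list of (16 x 2)
  pts <- lapply(seq_len(m), function(k) {
    a <- p[k, ]; b <- p[nxt[k], ]
    cbind(a[1] + qx * (b[1] - a[1]), a[2] + qx * (b[2] - a[2]))
  })
  K <- matrix(0, m, m)
  for (mu in seq_len(m)) {
    K[mu, mu] <- kernel_self(lens[mu], lambda)
    if (mu < m) for (nu in (mu + 1):m) {
      d <- sqrt(outer(pts[[mu]][, 1], pts[[nu]][, 1], "-")^2 +
                outer(pts[[mu]][, 2], pts[[nu]][, 2], "-")^2)
      K[mu, nu] <- K[nu, mu] <- sum((qw %o% qw) * exp(-d / lambda))
    }
  }
  K
}

# total source-length-weighted kernel input received by one junction of a
# regular hexagon with edge l0: the per-lambda normalization constant
hex_reference_weight <- function(lambda, l0 = 1) {
  ang <- pi / 6 + (0:5) * pi / 3
  p <- l0 * cbind(cos(ang), sin(ang))
  K <- polygon_kernel(p, rep(l0, 6), lambda)
  sum(K[1, ] * l0 * l0)
}

#' Assemble the intracellular interaction operator
#'
#' For each cell, builds the upregulation matrix `W_up` (length scale
#' `lambda_u`) and downregulation matrix `W_down` (`lambda_d`) over the
#' cell's half-edges.  Entry (mu, nu) is the exponential kernel integrated
#' along both junction segments (the emitted signal scales with the
#' protein a junction carries, and the received signal accumulates along
#' the target junction), divided by a single per-lambda constant: the
#' total weight received by a junction of the regular reference hexagon
#' (edge `l0`).  On the ordered lattice every row therefore sums to
#' exactly 1 whatever `lambda`, making the junctional polarizability
#' threshold and the interaction range independent controls, with the
#' strictly local limit pure same-junction cooperativity.  On irregular
#' cells the weights track the local geometry — in particular the
#' cooperative input of a junction grows with its length (nearly
#' linearly below the saturation scale), which is the geometric readout
#' that orients polarity perpendicular to tissue elongation.  For very
#' large `lambda`, weights become proportional to the product of the two
#' junction lengths.
#'
#' @param tissue a `pcp_tissue`.
#' @param lambda_u,lambda_d interaction lengths for up- and downregulation.
#' @return object of class `pcp_operator`: lists `W_up`, `W_down` of
#'   per-cell matrices, plus the length scales.
#' @export
assemble_operator <- function(tissue, lambda_u, lambda_d = lambda_u) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  if (lambda_u <= 0 || lambda_d <= 0) stop("lambda must be positive")
  one <- function(lambda) {
    sref <- hex_reference_weight(lambda, tissue$l0)
    lapply(seq_len(tissue$n_cells), function(ci) {
      K <- pairwise_edge_kernel(tissue, ci, lambda)
      len <- tissue$he_length[tissue$cell_he[[ci]]]
      (K * outer(len, len)) / sref
    })
  }
  structure(list(W_up = one(lambda_u),
                 W_down = if (lambda_d == lambda_u) NULL else one(lambda_d),
                 lambda_u = lambda_u, lambda_d = lambda_d,
                 n_he = tissue$n_he, n_cells = tissue$n_cells),
            class = "pcp_operator")
}

#' @export
print.pcp_operator <- function(x, ...) {
  cat(sprintf("Interaction operator: %d cells, lambda_u = %g, lambda_d = %g\n",
              x$n_cells, x$lambda_u, x$lambda_d))
  invisible(x)
}

# per-cell W_down list (shared with W_up when lambda_d == lambda_u)
op_wdown <- function(op) if (is.null(op$W_down)) op$W_up else op$W_down
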