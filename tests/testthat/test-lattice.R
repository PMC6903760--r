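test_that("hexagonal lattices satisfy torus topology and exact geometry", {
  t <- build_hexagonal(2, 2)
  expect_equal(t$n_cells, 4)
  expect_equal(t$n_edges, 12)
  expect_equal(t$n_vertices, 8)
  expect_equal(t$n_vertices - t$n_edges + t$n_cells, 0)

  t2 <- build_hexagonal(4, 4, 2)
  expect_true(all(abs(t2$edge_length - 2) < 1e-12))
  expect_equal(sum(t2$area), prod(t2$box), tolerance = 1e-12)

  big <- build_hexagonal(10, 10, 1)
  expect_equal(big$n_cells, 100)
  expect_true(all(abs(big$edge_length - 1) < 1e-12))
  expect_true(all(vapply(big$cell_he, length, 0L) == 6))
  expect_tissue_valid(big)
})

test_that("incompatible lattice sizes are rejected with a clear message", {
  expect_error(build_hexagonal(4, 3), "even")
  expect_error(build_hexagonal(1, 4), "at least 2")
  expect_error(build_hexagonal(4, 4, 0), "positive")
})

test_that("geometric disorder preserves topology, count and area", {
  base <- build_hexagonal(10, 10)
  expect_identical(apply_disorder(base, 0, seed = 3), base)
  d <- disordered(10, 10, 0.45, 7)
  expect_equal(d$n_cells, base$n_cells)
  expect_equal(sum(d$area), prod(d$box), tolerance = 1e-8)
  expect_equal(d$n_vertices - d$n_edges + d$n_cells, 0)
  expect_error(apply_disorder(base, 1.2, 1), "\\[0, 1\\]")
})

test_that("disorder is reproducible and edge-length spread grows with eps0", {
  base <- build_hexagonal(8, 8)
  d1 <- apply_disorder(base, 0.5, seed = 11)
  d2 <- apply_disorder(base, 0.5, seed = 11)
  expect_identical(d1$vertices, d2$vertices)
  cv <- function(x) sd(x) / mean(x)
  cvs <- vapply(1:8, function(s) {
    c(cv(apply_disorder(base, 0.3, s)$edge_length),
      cv(apply_disorder(base, 0.6, s)$edge_length))
  }, numeric(2))
  expect_gt(mean(cvs[2, ]), mean(cvs[1, ]))
})

test_that("elongation is an area-preserving calibrated map", {
  base <- build_hexagonal(8, 8)
  expect_identical(apply_elongation(base, 0, 90), base)
  e <- apply_elongation(base, 0.4, 90)
  expect_equal(sum(e$area), prod(e$box), tolerance = 1e-9)
  expect_equal(prod(e$box), prod(base$box), tolerance = 1e-9)
  st <- cell_shape_stats(e)
  expect_equal(st$E, 0.4, tolerance = 1e-4)
  expect_equal(st$phi_e, 90, tolerance = 2)

  d <- disordered(10, 10, 0.45, 7)
  ed <- apply_elongation(d, 0.1, 90)
  stm <- cell_shape_stats(ed)$E
  expect_true(stm > 0.095 && stm < 0.105)
  expect_error(apply_elongation(base, 0.2, 45), "axis-aligned")
})

test_that("shape statistics match closed forms and symmetries", {
  hexstats <- cell_shape_stats(hex44)
  expect_lt(max(hexstats$cells$Ei), 1e-10)

  # a regular hexagon stretched by s along y (det-1 map) has shape-tensor
  # eigenvalues scaled by s^2 and 1/s^2: Ei = (s^4 - 1)/(s^4 + 1)
  s <- 1.3
  p <- cbind(cos(pi / 6 + (0:5) * pi / 3) / s, sin(pi / 6 + (0:5) * pi / 3) * s)
  tens <- pcpsim:::polygon_shape_tensor(p)
  sh <- pcpsim:::shape_from_tensor(tens[1], tens[2], tens[3])
  expect_equal(sh$E, (s^4 - 1) / (s^4 + 1), tolerance = 1e-10)
  expect_equal(sh$phi, 90, tolerance = 1e-8)

  # translation invariance and rotation equivariance of the cell tensor
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- p %*% t(R)
  tr <- pcpsim:::polygon_shape_tensor(pr + matrix(c(3, -2), 6, 2, byrow = TRUE))
  shr <- pcpsim:::shape_from_tensor(tr[1], tr[2], tr[3])
  expect_equal(shr$E, sh$E, tolerance = 1e-10)
  expect_equal((shr$phi - sh$phi) %% 180, (th * 180 / pi) %% 180,
               tolerance = 1e-6)
})

test_that("tissue-level shape stats are equivariant under quarter turns", {
  d <- disordered(8, 8, 0.4, 5)
  s1 <- cell_shape_stats(d)
  s2 <- cell_shape_stats(rotate_tissue_90(d))
  expect_equal(s2$E, s1$E, tolerance = 1e-9)
  expect_equal(s2$phi_e %% 180, (s1$phi_e + 90) %% 180, tolerance = 1e-6)
})

test_that("geometric clones shrink cells locally and keep the tissue valid", {
  base <- disordered(10, 10, 0.1, 3)
  spec <- geometric_clone_spec(center = base$box / 2, radius = 3,
                               eps_patch = 0.6, shrink = 0.5, transition = 2)
  ct <- carve_geometric_clone(base, spec, seed = 9)
  expect_tissue_valid(ct)
  expect_equal(ct$n_cells, base$n_cells)
  d <- pcpsim:::min_image(sweep(ct$centroid, 2, spec$center), ct$box)
  rho <- sqrt(rowSums(d^2))
  expect_lt(mean(ct$area[rho < spec$radius]),
            mean(ct$area[rho > spec$radius + spec$transition]))
  # reproducibility
  ct2 <- carve_geometric_clone(base, spec, seed = 9)
  expect_identical(ct$vertices, ct2$vertices)
  expect_error(geometric_clone_spec(base$box / 2, 3, shrink = 0),
               "shrink")
  expect_error(carve_geometric_clone(base, geometric_clone_spec(
    base$box / 2, radius = 20, transition = 2), 1), "fit")
})

test_that("a no-op clone is statistically indistinguishable from disorder", {
  base <- build_hexagonal(10, 10)
  bg <- apply_disorder(base, 0.3, seed = 21)
  spec <- geometric_clone_spec(center = base$box / 2, radius = 3,
                               eps_patch = 0, shrink = 1, transition = 1)
  ct <- carve_geometric_clone(bg, spec, seed = 22)
  # no shrink and no extra jitter: same geometry as the background
  expect_equal(sort(ct$area), sort(bg$area), tolerance = 1e-9)
})

test_that("tissue JSON serialization round-trips exactly", {
  d <- disordered(6, 6, 0.5, 13)
  path <- tempfile(fileext = ".json")
  write_tissue_json(d, path)
  r <- read_tissue_json(path)
  expect_equal(r$box, d$box)
  expect_equal(r$n_cells, d$n_cells)
  expect_equal(r$n_edges, d$n_edges)
  expect_equal(sort(r$edge_length), sort(d$edge_length), tolerance = 1e-12)
  # match cells by centroid with minimum-image distances (cell order and
  # the branch of a wrapped polygon are not part of the schema)
  map <- vapply(seq_len(d$n_cells), function(ci) {
    dd <- pcpsim:::min_image(sweep(r$centroid, 2, d$centroid[ci, ]), d$box)
    which.min(rowSums(dd^2))
  }, 0L)
  expect_equal(r$area[map], d$area, tolerance = 1e-12)
  unlink(path)
  expect_error(suppressWarnings(read_tissue_json(tempfile())), ".")
})
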