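# shared small fixtures; built once per test run
hex44 <- build_hexagonal(4, 4)
hex66 <- build_hexagonal(6, 6)
dis_cache <- new.env(parent = emptyenv())

disordered <- function(nx = 10, ny = 10, eps0 = 0.45, seed = 7) {
  key <- paste(nx, ny, eps0, seed)
  if (is.null(dis_cache[[key]]))
    dis_cache[[key]] <- apply_disorder(build_hexagonal(nx, ny), eps0, seed)
  dis_cache[[key]]
}

# rotate a tissue by a quarter turn (the only rotation compatible with a
# rectangular periodic box): (x, y) -> (-y, x), then shift into the box
rotate_tissue_90 <- function(t) {
  polys <- lapply(t$cell_poly, function(p) cbind(-p[, 2] + t$box[2], p[, 1]))
  pcpsim:::tissue_from_polygons(polys, c(t$box[2], t$box[1]), l0 = t$l0)
}

expect_tissue_valid <- function(t) expect_silent(validate_tissue(t))
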