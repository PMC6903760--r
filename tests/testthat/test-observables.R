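mkstate <- function(tissue, u) structure(list(u = u, time = 0),
                                         class = "pcp_state")

test_that("cell dipoles follow the junctional differences", {
  t <- hex44
  n <- t$n_he
  # symmetric state: u = v everywhere
  u <- rep(0.3, n)
  d <- cell_dipoles(mkstate(t, u), t)
  expect_lt(max(d$mag), 1e-12)
  expect_true(all(is.na(d$phi_ip)))

  # u = c on the +x edge of cell 1, v = c on the -x edge: dipole 2c along +x
  he <- t$cell_he[[1]]
  ang <- atan2(t$he_nhat[he, 2], t$he_nhat[he, 1]) * 180 / pi
  plus_x <- he[which.min(abs(ang))]
  minus_x <- he[which.min(abs(abs(ang) - 180))]
  cc <- 0.25
  u <- rep(0, n)
  u[plus_x] <- cc                       # u on +x junction
  u[t$he_opp[minus_x]] <- cc            # v on -x junction
  d <- cell_dipoles(mkstate(t, u), t)
  expect_equal(d$mag[1], 2 * cc, tolerance = 1e-12)
  expect_equal(d$phi_ip[1] %% 360, 0, tolerance = 1e-9)
})

test_that("dipole angles are equivariant under a quarter turn", {
  d <- disordered(6, 6, 0.3, 4)
  set.seed(5)
  u <- runif(d$n_he, 0, 0.4)
  dip <- cell_dipoles(mkstate(d, u), d)
  r <- rotate_tissue_90(d)
  # map half-edges by midpoint position
  tgt <- cbind(-d$he_mid[, 2] + d$box[2], d$he_mid[, 1])
  map <- vapply(seq_len(d$n_he), function(h) {
    dd <- sweep(r$he_mid, 2, tgt[h, ])
    dd[, 1] <- dd[, 1] - r$box[1] * round(dd[, 1] / r$box[1])
    dd[, 2] <- dd[, 2] - r$box[2] * round(dd[, 2] / r$box[2])
    cand <- which(rowSums(dd^2) < 1e-12)
    # two half-edges share a midpoint: pick the one with rotated normal
    nh <- c(-d$he_nhat[h, 2], d$he_nhat[h, 1])
    cand[which.max(r$he_nhat[cand, ] %*% nh)]
  }, 0L)
  ur <- numeric(r$n_he); ur[map] <- u
  dipr <- cell_dipoles(mkstate(r, ur), r)
  cmap <- vapply(seq_len(d$n_cells), function(ci) {
    tc <- c(-d$centroid[ci, 2] + d$box[2], d$centroid[ci, 1])
    dd <- sweep(r$centroid, 2, tc)
    dd[, 1] <- dd[, 1] - r$box[1] * round(dd[, 1] / r$box[1])
    dd[, 2] <- dd[, 2] - r$box[2] * round(dd[, 2] / r$box[2])
    which.min(rowSums(dd^2))
  }, 0L)
  expect_equal(dipr$mag[cmap], dip$mag, tolerance = 1e-9)
  expect_equal((dipr$phi_ip[cmap] - dip$phi_ip) %% 360,
               rep(90, d$n_cells), tolerance = 1e-6)
})

test_that("order parameters satisfy their defining limits", {
  # identical dipoles
  d <- data.frame(Px = rep(1.2, 50), Py = rep(0.5, 50))
  d$mag <- sqrt(d$Px^2 + d$Py^2)
  d$phi_ip <- (atan2(d$Py, d$Px) * 180 / pi) %% 360
  class(d) <- c("pcp_dipoles", "data.frame")
  o <- order_parameters(d)
  expect_equal(o$O, 1, tolerance = 1e-12)
  expect_equal(o$Qbar, o$Pbar, tolerance = 1e-12)

  # two antiparallel dipoles cancel
  d2 <- data.frame(Px = c(1, -1), Py = c(0, 0), mag = c(1, 1),
                   phi_ip = c(0, 180))
  class(d2) <- c("pcp_dipoles", "data.frame")
  o2 <- order_parameters(d2)
  expect_equal(o2$Pbar, 0, tolerance = 1e-14)
  expect_equal(o2$O, 0, tolerance = 1e-14)

  # all-zero dipoles: undefined, not 0/0
  d3 <- data.frame(Px = numeric(3), Py = numeric(3), mag = numeric(3),
                   phi_ip = NA_real_)
  class(d3) <- c("pcp_dipoles", "data.frame")
  expect_true(is.na(order_parameters(d3)$O))
})

test_that("random-angle dipoles give the 2D random-walk resultant", {
  # closed form: E|sum of N unit steps| ~ sqrt(pi N)/2, so E[O] ~
  # sqrt(pi)/(2 sqrt(N)); check the estimator against it at N = 400
  N <- 400
  set.seed(42)
  reps <- 300
  Os <- vapply(seq_len(reps), function(r) {
    phi <- runif(N, 0, 2 * pi)
    d <- data.frame(Px = cos(phi), Py = sin(phi), mag = 1,
                    phi_ip = (phi * 180 / pi) %% 360)
    class(d) <- c("pcp_dipoles", "data.frame")
    order_parameters(d)$O
  }, 0)
  expected <- sqrt(pi) / (2 * sqrt(N))
  se <- sd(Os) / sqrt(reps)
  expect_lt(abs(mean(Os) - expected), 3 * se)
})

test_that("correlation length separates aligned from random fields", {
  d <- disordered(12, 12, 0.2, 8)
  # aligned: capped at half the box diagonal
  phi <- rep(30, d$n_cells)
  dd <- data.frame(Px = cos(phi * pi / 180), Py = sin(phi * pi / 180),
                   mag = 1, phi_ip = phi)
  class(dd) <- c("pcp_dipoles", "data.frame")
  cl <- correlation_length(dd, d)
  expect_true(cl$capped)
  expect_equal(cl$xi_length, sqrt(sum(d$box^2)) / 2)

  # i.i.d. random angles decorrelate within ~2 cell diameters
  set.seed(9)
  phi <- runif(d$n_cells, 0, 360)
  dr <- data.frame(Px = cos(phi * pi / 180), Py = sin(phi * pi / 180),
                   mag = 1, phi_ip = phi)
  class(dr) <- c("pcp_dipoles", "data.frame")
  clr <- correlation_length(dr, d)
  expect_lt(clr$xi, 2)
  expect_error(correlation_length(dr, hex44), "100 cells")
})

test_that("threshold estimator agrees with an exponential fit", {
  # synthetic field with imposed exponential-like correlations: smooth
  # i.i.d. unit vectors with an exponential kernel of scale a
  d <- apply_disorder(build_hexagonal(16, 16), 0.2, 31)
  set.seed(13)
  z <- cbind(rnorm(d$n_cells), rnorm(d$n_cells))
  a <- 2.5
  dx <- outer(d$centroid[, 1], d$centroid[, 1], "-")
  dy <- outer(d$centroid[, 2], d$centroid[, 2], "-")
  dx <- dx - d$box[1] * round(dx / d$box[1])
  dy <- dy - d$box[2] * round(dy / d$box[2])
  K <- exp(-sqrt(dx^2 + dy^2) / a)
  v <- K %*% z
  phi <- (atan2(v[, 2], v[, 1]) * 180 / pi) %% 360
  dd <- data.frame(Px = cos(phi * pi / 180), Py = sin(phi * pi / 180),
                   mag = 1, phi_ip = phi)
  class(dd) <- c("pcp_dipoles", "data.frame")
  cl <- correlation_length(dd, d)
  # exponential fit of the measured C(r) over its decay towards the 1/e
  # level (the smoothed field is exponential to leading order there; the
  # far tail decays differently and is not what the estimator measures)
  sel <- cl$C > 0.3 & cl$C < 0.9
  fit <- -1 / coef(lm(log(cl$C[sel]) ~ cl$r[sel]))[2]
  diam <- sqrt(3) * d$l0
  expect_lt(abs(cl$xi - fit / diam) / (fit / diam), 0.2)
})

test_that("angular histogram conserves counts and detects uniformity", {
  set.seed(7)
  phi <- runif(1e4, 0, 360)
  d <- data.frame(Px = cos(phi * pi / 180), Py = sin(phi * pi / 180),
                  mag = 1, phi_ip = phi)
  class(d) <- c("pcp_dipoles", "data.frame")
  h <- angular_histogram(d, 36)
  expect_equal(sum(h$count), 1e4)
  p <- chisq.test(h$count)$p.value
  expect_gt(p, 0.01)
  expect_error(angular_histogram(d, 3), "nbins")
})

test_that("axial folding and scatter tables behave", {
  expect_equal(pcpsim:::fold_axial(10 - 0), pcpsim:::fold_axial(170 - 0))
  expect_equal(pcpsim:::fold_axial(95), 85)
  expect_equal(pcpsim:::fold_axial(-30), 30)

  # dipoles perpendicular to every cell axis give dphi = 90
  st <- list(cells = data.frame(area = 1, Ei = 0.3, phi_ie = c(10, 40, 120)))
  d <- data.frame(Px = 0, Py = 0, mag = c(1, 1, 1),
                  phi_ip = c(100, 130, 210))
  class(d) <- c("pcp_dipoles", "data.frame")
  sc <- elongation_polarity_scatter(d, st)
  expect_equal(sc$table$dphi, rep(90, 3))
})
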