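# Scripted experiment drivers: interaction-length sweeps, stability of
# polarization under noise, cue detection, elongated tissues, and mutant
# clones.  Each driver returns a plain list (class `pcp_experiment`) whose
# scalars are all recomputable from the stored seeds and settings.

#' Mutant clone specification
#'
#' Defines a circular region of cells whose kinetic parameters are
#' replaced: membrane-protein mutants override `f0`/`g0`, cytoplasmic
#' mutants override `alpha`/`beta` (interaction magnitude) or
#' `lambda_u`/`lambda_d` (interaction range).  A geometric component
#' (type-III mutants) is attached as a [geometric_clone_spec()].
#'
#' @param center length-2 clone center (box coordinates).
#' @param radius clone radius in length units.
#' @param overrides named list of replacement values, names among
#'   `f0, g0, alpha, beta, lambda_u, lambda_d`.
#' @param background named list applied to all cells outside the clone
#'   (e.g. a mutant background tissue).
#' @param geometry optional `pcp_clone_geometry` for geometric clones.
#' @return an object of class `pcp_clone`.
#' @export
clone_spec <- function(center, radius, overrides = list(),
                       background = list(), geometry = NULL) {
  ok <- c("f0", "g0", "alpha", "beta", "lambda_u", "lambda_d")
  bad <- setdiff(c(names(overrides), names(background)), ok)
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
  if (radius <= 0) stop("radius must be positive")
  if (any(unlist(overrides) < 0) || any(unlist(background) < 0))
    stop("override values must be >= 0")
  structure(list(center = as.numeric(center), radius = radius,
                 overrides = overrides, background = background,
                 geometry = geometry),
            class = "pcp_clone")
}

#' Apply a mutant clone to parameters (and, for geometric clones, tissue)
#'
#' Cells whose centroid lies within the clone radius (minimum-image
#' distance) receive the override values as per-cell parameters;
#' background overrides apply to all other cells.  When the spec carries
#' a geometric component the tissue is rebuilt via
#' [carve_geometric_clone()] first, and clone membership is decided on
#' the rebuilt tissue.
#'
#' @param params a `pcp_params`.
#' @param tissue a `pcp_tissue`.
#' @param spec a [clone_spec()].
#' @param seed seed for the geometric component (if any).
#' @return list with updated `params` and `tissue`, plus `cells`, the
#'   clone cell indices.
#' @export
apply_clone <- function(params, tissue, spec, seed = 1) {
  stopifnot(inherits(spec, "pcp_clone"))
  if (!is.null(spec$geometry))
    tissue <- carve_geometric_clone(tissue, spec$geometry, seed)
  d <- min_image(sweep(tissue$centroid, 2, spec$center), tissue$box)
  inside <- which(sqrt(rowSums(d^2)) <= spec$radius)
  if (!length(inside)) stop("clone region contains no cells")
  rows <- list()
  for (nm in names(spec$background)) {
    out <- setdiff(seq_len(tissue$n_cells), inside)
    rows[[length(rows) + 1L]] <- data.frame(cell = out, param = nm,
                                            value = spec$background[[nm]])
  }
  for (nm in names(spec$overrides))
    rows[[length(rows) + 1L]] <- data.frame(cell = inside, param = nm,
                                            value = spec$overrides[[nm]])
  if (length(rows)) {
    ov <- do.call(rbind, c(list(params$overrides), rows))
    params$overrides <- ov
  }
  list(params = params, tissue = tissue, cells = inside)
}

# mean dipole vector per snapshot: rows of (U - U_opp) %*% nhat / n_cells
mean_dipole_series <- function(traj) {
  t <- traj$tissue
  D <- traj$U - traj$U[, t$he_opp, drop = FALSE]
  (D %*% t$he_nhat) / t$n_cells
}

# steady-state summary of one run
run_summary <- function(traj, with_xi = TRUE) {
  dip <- cell_dipoles(state_at(traj), traj$tissue)
  ops <- order_parameters(dip)
  xi <- if (with_xi) correlation_length(dip, traj$tissue)$xi else NA_real_
  c(ops, list(xi = xi, circ_sd = circ_sd_deg(dip$phi_ip[!is.na(dip$phi_ip)])))
}

#' Interaction-length sweep
#'
#' Runs seeded simulations from random initial conditions for each value
#' of `lambda/l0` and reports the seed-averaged steady-state correlation
#' length and alignment ratio.  The correlation length is non-monotone
#' in `lambda`: strictly local interactions polarize junctions but not
#' cells, intermediate ranges maximize tissue-scale alignment, and
#' ranges comparable to the cell diameter couple opposite cell sides and
#' destabilize segregation.
#'
#' @param lambda_grid vector of interaction lengths (units of `l0`),
#'   within `(0, 1.2]`.
#' @param tissue a `pcp_tissue`.
#' @param params a `pcp_params` (its `lambda_u/d` are replaced by the
#'   grid values).
#' @param seeds integer vector of at least 3 seeds.
#' @param Tend duration per run.
#' @param ic_amplitude random initial-condition amplitude.
#' @return `pcp_experiment` list: per-lambda table (`lambda`, `xi`, `O`,
#'   `Qbar`), `argmax_lambda` (ties towards the smaller value), and the
#'   per-run results.
#' @export
run_lambda_sweep <- function(lambda_grid, tissue, params = model_params(),
                             seeds = 1:5, Tend = 150, ic_amplitude = 0.5) {
  if (any(lambda_grid <= 0) || any(lambda_grid > 1.2))
    stop("lambda_grid must lie in (0, 1.2]")
  if (length(seeds) < 3) stop("need at least 3 seeds")
  runs <- list()
  for (lam in lambda_grid) {
    p <- params; p$lambda_u <- lam; p$lambda_d <- lam
    op <- assemble_operator(tissue, lam, lam)
    for (sd in seeds) {
      ic <- init_state(tissue, "random", ic_amplitude, seed = sd)
      tr <- simulate(tissue, p, ic, Tend = Tend, seed = sd, op = op)
      runs[[length(runs) + 1L]] <-
        c(list(lambda = lam, seed = sd), run_summary(tr))
    }
  }
  tab <- do.call(rbind, lapply(runs, function(r)
    data.frame(lambda = r$lambda, seed = r$seed, xi = r$xi, O = r$O,
               Qbar = r$Qbar)))
  agg <- aggregate(tab[c("xi", "O", "Qbar")], by = list(lambda = tab$lambda),
                   FUN = mean)
  k <- which(agg$xi == max(agg$xi))[1]   # ties resolved towards smaller lambda
  structure(list(scenario = "lambda_sweep", table = agg, runs = tab,
                 argmax_lambda = agg$lambda[k], seeds = seeds, Tend = Tend),
            class = "pcp_experiment")
}

#' Stability of an imposed polarization under noise
#'
#' Compares local activation + nonlocal inhibition (`"LA-NLI"`,
#' `lambda_u = 0.01`, `lambda_d = 0.5`) against fully nonlocal
#' interactions (`"NLA-NLI"`, `lambda_u = lambda_d = 0.5`) on identical
#' geometry and initial conditions: a polarized initial state evolving
#' under stochastic noise.  In strongly disordered tissues only nonlocal
#' activation preserves the angular coherence of the dipoles.
#'
#' @param eps0 geometric disorder of the tissue.
#' @param mechanism `"LA-NLI"` or `"NLA-NLI"`.
#' @param geometry_seed,ic_seed seeds shared between mechanisms.
#' @param eta0 noise magnitude.
#' @param Tend duration.
#' @param nx,ny lattice size.
#' @param params base `pcp_params`.
#' @return `pcp_experiment` list with final `O`, circular standard
#'   deviation of dipole angles (`circ_sd`, degrees), and the run.
#' @export
run_stability_experiment <- function(eps0, mechanism = c("NLA-NLI", "LA-NLI"),
                                     geometry_seed = 1, ic_seed = 1,
                                     eta0 = 0.1, Tend = 150,
                                     nx = 20, ny = 20,
                                     params = model_params()) {
  mechanism <- match.arg(mechanism)
  lam <- if (mechanism == "LA-NLI") c(0.01, 0.5) else c(0.5, 0.5)
  p <- params
  p$lambda_u <- lam[1]; p$lambda_d <- lam[2]; p$eta0 <- eta0
  tissue <- apply_disorder(build_hexagonal(nx, ny, 1), eps0, geometry_seed)
  ic <- init_state(tissue, "polarized", amplitude = 0.5, direction = c(1, 0))
  tr <- simulate(tissue, p, ic, Tend = Tend, seed = ic_seed)
  sm <- run_summary(tr)
  structure(list(scenario = "stability", mechanism = mechanism, eps0 = eps0,
                 O = sm$O, circ_sd = sm$circ_sd, xi = sm$xi,
                 phi_mean = sm$phi_mean, trajectory = tr),
            class = "pcp_experiment")
}

#' Cue-detection experiment
#'
#' Runs the model under a directional cue and reports the time to
#' alignment (first snapshot with `O > 0.8` and mean dipole within 15
#' degrees of the cue) and the final alignment.  With strictly local
#' interactions cue detection is slow or absent; nonlocal interactions
#' make the tissue sensitive to weak gradients.
#'
#' @param cue a `pcp_cue`.
#' @param regime `"NLCI"` (`lambda = 0.5`) or `"SLCI"` (`lambda = 0.01`).
#' @param tissue a `pcp_tissue`.
#' @param params base parameters.
#' @param seeds seeds for initial conditions and noise.
#' @param Tend duration.
#' @return `pcp_experiment` list with per-seed `t_align` (NA when never
#'   aligned), final `O` and final angle error (degrees).
#' @export
run_cue_experiment <- function(cue, regime = c("NLCI", "SLCI"), tissue,
                               params = model_params(), seeds = 1:3,
                               Tend = 150) {
  regime <- match.arg(regime)
  lam <- if (regime == "SLCI") 0.01 else 0.5
  p <- params; p$lambda_u <- lam; p$lambda_d <- lam
  op <- assemble_operator(tissue, lam, lam)
  cue_ang <- (atan2(cue$direction[2], cue$direction[1]) * 180 / pi) %% 360
  rows <- lapply(seeds, function(sd) {
    ic <- init_state(tissue, "random", 0.5, seed = sd)
    tr <- simulate(tissue, p, ic, cue = cue, Tend = Tend, seed = sd, op = op,
                   check_steady = FALSE)
    md <- mean_dipole_series(tr)
    ang <- (atan2(md[, 2], md[, 1]) * 180 / pi) %% 360
    err <- abs(((ang - cue_ang + 180) %% 360) - 180)
    ok <- tr$O > 0.8 & err < 15
    data.frame(seed = sd,
               t_align = if (any(ok)) tr$times[which(ok)[1]] else NA_real_,
               O_final = tr$O[length(tr$O)],
               angle_err_final = err[length(err)])
  })
  tab <- do.call(rbind, rows)
  structure(list(scenario = "cue", regime = regime, cue = cue, table = tab,
                 seeds = seeds),
            class = "pcp_experiment")
}

#' Polarization of elongated tissues
#'
#' Applies an area-preserving elongation to a (possibly disordered)
#' tissue and measures, per seed, the folded angle between the direction
#' of the mean dipole and the tissue elongation axis at steady state.
#' Nonlocal interactions stabilize complexes on the longer junctions, so
#' the collective polarity locks approximately perpendicular to the
#' elongation axis even at small elongation.
#'
#' @param E target tissue elongation index.
#' @param phi_e elongation axis (degrees; 0 or 90).
#' @param tissue base tissue (before elongation).
#' @param params a `pcp_params`.
#' @param seeds seeds for initial conditions and noise.
#' @param Tend duration.
#' @return `pcp_experiment` list: per-seed table (`Phi_p`, `dPhi`),
#'   `mean_dphi` (mean folded angle between polarity and elongation
#'   axis), the per-cell scatter of the last run, and the elongated
#'   tissue's measured `E` and `phi_e`.
#' @export
run_elongation_experiment <- function(E, phi_e = 90, tissue,
                                      params = model_params(), seeds = 1:5,
                                      Tend = 150) {
  et <- apply_elongation(tissue, E, phi_e)
  st <- cell_shape_stats(et)
  op <- assemble_operator(et, params$lambda_u, params$lambda_d)
  scatter <- NULL
  rows <- lapply(seeds, function(sd) {
    ic <- init_state(et, "random", 0.5, seed = sd)
    tr <- simulate(et, params, ic, Tend = Tend, seed = sd, op = op)
    dip <- cell_dipoles(state_at(tr), et)
    ops <- order_parameters(dip)
    scatter <<- elongation_polarity_scatter(dip, st)
    data.frame(seed = sd, Phi_p = ops$phi_mean, O = ops$O,
               dPhi = fold_axial(ops$phi_mean - st$phi_e))
  })
  tab <- do.call(rbind, rows)
  structure(list(scenario = "elongation", E_target = E,
                 E_measured = st$E, phi_e = st$phi_e,
                 table = tab, mean_dphi = mean(tab$dPhi),
                 scatter = scatter, seeds = seeds),
            class = "pcp_experiment")
}

# discrete winding number of the dipole angle along a cell loop at
# distance ~r from a center point
winding_number <- function(dipoles, tissue, center, r, width = 1.5) {
  d <- min_image(sweep(tissue$centroid, 2, center), tissue$box)
  rho <- sqrt(rowSums(d^2))
  sel <- which(rho > r - width & rho < r + width & !is.na(dipoles$phi_ip))
  if (length(sel) < 6) return(NA_real_)
  ord <- sel[order(atan2(d[sel, 2], d[sel, 1]))]
  phi <- dipoles$phi_ip[ord]
  dphi <- ((diff(c(phi, phi[1])) + 180) %% 360) - 180
  round(sum(dphi) / 360)
}

#' Geometrically disordered mutant clone
#'
#' Embeds a patch of strongly disordered, shrunken cells in an otherwise
#' mildly disordered tissue and simulates with and without a global
#' gradient cue.  Without a cue the patch nucleates swirling dipole
#' patterns and shortens the global correlation length; a gradient cue
#' unwinds the swirls and restores tissue-wide alignment.
#'
#' @param cue_on logical: apply a persistent bulk gradient cue?
#' @param geometry a [geometric_clone_spec()].
#' @param tissue background tissue.
#' @param params a `pcp_params`.
#' @param seeds seeds.
#' @param Tend duration.
#' @param cue_M gradient magnitude when `cue_on`.
#' @return `pcp_experiment` list with per-seed `xi` (clone) vs
#'   `xi_control` (same seed, no clone), winding numbers around the
#'   patch, and final mean-dipole angle error w.r.t. the cue.
#' @export
run_geometric_mutant <- function(cue_on, geometry, tissue,
                                 params = model_params(), seeds = 1:3,
                                 Tend = 150, cue_M = 2) {
  ct <- carve_geometric_clone(tissue, geometry, seed = 1)
  cue <- if (cue_on) cue_schedule("bulk", c(1, 0), M = cue_M, tau_m = Inf)
         else cue_schedule("none")
  opc <- assemble_operator(ct, params$lambda_u, params$lambda_d)
  op0 <- assemble_operator(tissue, params$lambda_u, params$lambda_d)
  rows <- lapply(seeds, function(sd) {
    ic <- init_state(ct, "random", 0.5, seed = sd)
    tr <- simulate(ct, params, ic, cue = cue, Tend = Tend, seed = sd, op = opc)
    dip <- cell_dipoles(state_at(tr), ct)
    xi <- correlation_length(dip, ct)$xi
    w <- winding_number(dip, ct, geometry$center,
                        r = geometry$radius + 1.5 * sqrt(3) * tissue$l0)
    ic0 <- init_state(tissue, "random", 0.5, seed = sd)
    tr0 <- simulate(tissue, params, ic0, cue = cue, Tend = Tend, seed = sd,
                    op = op0)
    dip0 <- cell_dipoles(state_at(tr0), tissue)
    ops <- order_parameters(dip)
    err <- if (cue_on) fold_axial(ops$phi_mean - 0) else NA_real_
    data.frame(seed = sd, xi = xi,
               xi_control = correlation_length(dip0, tissue)$xi,
               winding = w, angle_err = err, O = ops$O)
  })
  tab <- do.call(rbind, rows)
  structure(list(scenario = "geometric_mutant", cue_on = cue_on,
                 geometry = geometry, table = tab, seeds = seeds),
            class = "pcp_experiment")
}

#' Radial non-autonomy profile around a clone
#'
#' Mean deviation of dipole angles from the far-field mean, per
#' concentric ring of cells around the clone center; the non-autonomy
#' extent is the number of consecutive rings (outward from the clone
#' edge) whose mean deviation exceeds 15 degrees.
#'
#' @param dipoles a `pcp_dipoles`.
#' @param tissue the tissue.
#' @param center clone center.
#' @param radius clone radius (length units).
#' @return list with the ring table and `extent` (rings).
#' @export
nonautonomy_profile <- function(dipoles, tissue, center, radius) {
  d <- min_image(sweep(tissue$centroid, 2, center), tissue$box)
  rho <- sqrt(rowSums(d^2))
  diam <- sqrt(3) * tissue$l0
  far <- rho > max(rho) - 2 * diam
  ref <- circ_mean_deg(dipoles$phi_ip[far & !is.na(dipoles$phi_ip)])
  ring <- pmax(0L, as.integer(floor((rho - radius) / diam)) + 1L)
  outside <- ring >= 1L & !is.na(dipoles$phi_ip)
  dev <- abs(((dipoles$phi_ip - ref + 180) %% 360) - 180)
  tab <- aggregate(dev[outside], by = list(ring = ring[outside]), FUN = mean)
  names(tab)[2] <- "deviation"
  ext <- 0L
  for (k in seq_len(nrow(tab))) {
    if (tab$deviation[k] > 15) ext <- k else break
  }
  list(rings = tab, extent = ext, far_field_angle = ref)
}

#' @export
print.pcp_experiment <- function(x, ...) {
  cat("PCP experiment:", x$scenario, "\n")
  if (!is.null(x$table)) print(utils::head(x$table, 12))
  invisible(x)
}
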