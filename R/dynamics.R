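# Stochastic binding/unbinding dynamics of cross-junctional complexes.
#
# Kinetic closure.  Binding on a junction consumes unbound F from the
# owning cell and unbound G from the facing cell (law of mass action) and
# is enhanced by the cooperative upregulation factor (1 + alpha*Ku).
# Unbinding is proportional to the local concentration, enhanced by
# opposite-polarity complexes through (1 + beta*Kv), and suppressed by the
# same upregulating input, (1 + alpha*Ku)^-1: cytoplasmic messengers of
# the same polarity both promote formation and stabilize existing
# complexes.  Ku and Kv average the kernel channels of the two cells
# sharing the junction (both species' messengers regulate it), which
# makes the F-G relabeling an exact symmetry.  Unbound pools are totals
# minus the perimeter-averaged bound concentration, so f0 and u share
# units of concentration per membrane length.  See the methods vignette
# for how this closure reproduces the junctional polarizability
# threshold.

#' Model parameters
#'
#' Default values are the reference parameter set of the model: total
#' concentrations `f0 = g0 = 1`, binding rate `kappa = 10`, unbinding rate
#' `gamma = 1` (which sets the time unit), cooperativity magnitudes
#' `alpha = beta = 5`, noise magnitude `eta0 = 0.1`, interaction lengths
#' `lambda_u = lambda_d = 0.5` (in units of the junction length l0), and
#' integration step `dt = 1e-3` (units of 1/gamma).
#'
#' @param f0,g0 total F and G concentrations (dimensionless, per cell).
#' @param kappa,gamma binding and unbinding rates (1/time).
#' @param alpha,beta cooperative up/downregulation magnitudes.
#' @param eta0 additive noise magnitude.
#' @param lambda_u,lambda_d up/downregulation interaction length scales.
#' @param dt integration time step in units of `1/gamma`.
#' @param overrides optional data.frame of per-cell parameter overrides
#'   with columns `cell`, `param` (one of f0, g0, alpha, beta, lambda_u,
#'   lambda_d) and `value`; used for mutant clones.
#' @return an object of class `pcp_params`.
#' @export
model_params <- function(f0 = 1, g0 = 1, kappa = 10, gamma = 1,
                         alpha = 5, beta = 5, eta0 = 0.1,
                         lambda_u = 0.5, lambda_d = 0.5, dt = 1e-3,
                         overrides = NULL) {
  stopifnot(f0 >= 0, g0 >= 0, kappa > 0, gamma > 0,
            alpha >= 0, beta >= 0, eta0 >= 0,
            lambda_u > 0, lambda_d > 0, dt > 0)
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides),
              all(c("cell", "param", "value") %in% names(overrides)))
    bad <- setdiff(unique(overrides$param),
                   c("f0", "g0", "alpha", "beta", "lambda_u", "lambda_d"))
    if (length(bad)) stop("unknown override parameter(s): ",
                          paste(bad, collapse = ", "))
    if (any(overrides$value < 0)) stop("override values must be >= 0")
  }
  structure(list(f0 = f0, g0 = g0, kappa = kappa, gamma = gamma,
                 alpha = alpha, beta = beta, eta0 = eta0,
                 lambda_u = lambda_u, lambda_d = lambda_d, dt = dt,
                 overrides = overrides),
            class = "pcp_params")
}

# per-cell parameter vectors with clone overrides applied
cell_param_vectors <- function(params, n_cells) {
  v <- list(f0 = rep(params$f0, n_cells), g0 = rep(params$g0, n_cells),
            alpha = rep(params$alpha, n_cells), beta = rep(params$beta, n_cells),
            lambda_u = rep(params$lambda_u, n_cells),
            lambda_d = rep(params$lambda_d, n_cells))
  ov <- params$overrides
  if (!is.null(ov)) for (k in seq_len(nrow(ov))) {
    v[[ov$param[k]]][ov$cell[k]] <- ov$value[k]
  }
  v
}

#' Directional cue schedule
#'
#' Bulk cues add a formation-rate term on each half-edge proportional to
#' the (clipped) projection of the vector from the cell centroid to the
#' edge midpoint onto the cue direction, with overall magnitude
#' `M * exp(-t/tau_m)`.  Boundary cues act on a strip of `depth` cell
#' columns perpendicular to the cue direction: in `"persistent-clamp"`
#' mode the strip is re-polarized every step; in `"initial-only"` mode the
#' strip starts with a strongly polarized state (amplitude factor
#' `boost`) and is then released.
#'
#' @param kind `"none"`, `"bulk"`, or `"boundary"`.
#' @param direction length-2 cue direction (normalized internally).
#' @param M cue magnitude (rate units); must be `>= 0`.
#' @param tau_m decay timescale; `Inf` for persistent cues.
#' @param depth strip depth in cell columns (boundary cues).
#' @param mode `"persistent-clamp"` or `"initial-only"` (boundary cues).
#' @param boost polarization amplitude factor for `"initial-only"`.
#' @return an object of class `pcp_cue`.
#' @export
cue_schedule <- function(kind = c("none", "bulk", "boundary"),
                         direction = c(1, 0), M = 0, tau_m = Inf,
                         depth = 2, mode = c("persistent-clamp", "initial-only"),
                         boost = 3) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (M < 0) stop("M must be non-negative")
  if (!(tau_m > 0)) stop("tau_m must be positive (possibly Inf)")
  if (kind == "boundary" && depth < 1) stop("depth must be at least 1")
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  structure(list(kind = kind, direction = d, M = M, tau_m = tau_m,
                 depth = depth, mode = mode, boost = boost),
            class = "pcp_cue")
}

#' Initial state of the junctional concentrations
#'
#' @param tissue a `pcp_tissue`.
#' @param mode `"random"`: i.i.d. uniform `u` in `[0, amplitude]`;
#'   `"polarized"`: `u` loaded on half-edges whose outward normal aligns
#'   with `direction`; `"alternating"`: adjacent junctions of every cell
#'   carry opposite polarity, so junctions are polarized but all cell
#'   dipoles vanish (only meaningful on the ordered hexagonal lattice).
#' @param amplitude concentration scale of the loading.
#' @param direction length-2 vector for `"polarized"` mode.
#' @param seed integer seed (`"random"` mode).
#' @return an object of class `pcp_state` (fields `u`, `time`).
#' @export
init_state <- function(tissue, mode = c("random", "polarized", "alternating"),
                       amplitude = 0.5, direction = c(1, 0), seed = 1) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be non-negative")
  n <- tissue$n_he
  u <- switch(mode,
    random = {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      runif(n, 0, amplitude)
    },
    polarized = {
      d <- direction / sqrt(sum(direction^2))
      amplitude * pmax(0, as.vector(tissue$he_nhat %*% d))
    },
    alternating = {
      ang <- atan2(tissue$he_nhat[, 2], tissue$he_nhat[, 1])
      cls <- round(ang / (pi / 3)) %% 6
      amplitude * (1 + (cls %% 2 == 0) - (cls %% 2 == 1)) / 2 * 2
    })
  s <- structure(list(u = u, time = 0), class = "pcp_state")
  chk <- unbound_pools(s, tissue, model_params())
  if (any(chk$f_ubd <= 0) || any(chk$g_ubd <= 0))
    stop("initial amplitude overdraws the protein pools")
  s
}

#' Unbound protein pools per cell
#'
#' The unbound concentration is the total minus the perimeter-averaged
#' bound concentration: `f_ubd(i) = f0(i) - sum(u l) / sum(l)` over the
#' cell perimeter, and `g_ubd(i)` likewise with the opposite-polarity
#' concentrations.  Values that undershoot zero by more than `1e-9` (a
#' consequence of the additive noise) trigger a warning; all values are
#' clipped at zero.
#'
#' @param state a `pcp_state`.
#' @param tissue the `pcp_tissue` the state lives on.
#' @param params a `pcp_params`.
#' @return list with per-cell vectors `f_ubd` and `g_ubd`.
#' @export
unbound_pools <- function(state, tissue, params) {
  u <- state$u
  cp <- cell_param_vectors(params, tissue$n_cells)
  len <- tissue$he_length
  own <- tissue$he_cell
  P <- vapply(seq_len(tissue$n_cells),
              function(ci) sum(len[tissue$cell_he[[ci]]]), 0)
  f <- cp$f0 - as.vector(rowsum(u * len, own)) / P
  g <- cp$g0 - as.vector(rowsum(u[tissue$he_opp] * len, own)) / P
  if (any(f < -1e-9) || any(g < -1e-9))
    warning("unbound pool undershoot beyond 1e-9 (max ",
            format(-min(f, g)), "); clipping at zero")
  list(f_ubd = pmax(0, f), g_ubd = pmax(0, g))
}

#' Deterministic drift of the junctional dynamics
#'
#' Reference (R-level) evaluation of the right-hand side; the compiled
#' integrator used by [simulate()] implements the same expression.  For
#' half-edge `mu` owned by cell `i` facing cell `j`:
#' `du/dt = kappa f_i g_j (1 + alpha Ku) - gamma u (1 + beta Kv)/(1 + alpha Ku)
#'  + cue`, with `Ku`, `Kv` the cooperative inputs averaged over the two
#' cells sharing the junction.
#'
#' @param state a `pcp_state`.
#' @param tissue the tissue.
#' @param op interaction operator from [assemble_operator()] on the same
#'   tissue.
#' @param params a `pcp_params`.
#' @param cue a `pcp_cue` (default none).
#' @param time evaluation time (cue decay).
#' @return numeric vector `du/dt` over half-edges.
#' @export
drift <- function(state, tissue, op, params, cue = cue_schedule("none"),
                  time = state$time) {
  stopifnot(inherits(op, "pcp_operator"))
  if (op$n_he != tissue$n_he)
    stop("operator was assembled on a different tissue (", op$n_he,
         " half-edges vs ", tissue$n_he, ")")
  u <- state$u
  pools <- unbound_pools(state, tissue, params)
  cp <- cell_param_vectors(params, tissue$n_cells)
  own <- tissue$he_cell
  opp <- tissue$he_opp
  neigh <- own[opp]
  wd <- op_wdown(op)
  # per-cell kernel inputs from the state and from the opposite-polarity
  # state; both the F-side and the G-side cell regulate a shared junction
  # (the two protein species enter on an equal footing), so the effective
  # cooperative inputs average the two cells' channels
  bu_u <- numeric(tissue$n_he); bu_v <- numeric(tissue$n_he)
  bd_u <- numeric(tissue$n_he); bd_v <- numeric(tissue$n_he)
  for (ci in seq_len(tissue$n_cells)) {
    he <- tissue$cell_he[[ci]]
    bu_u[he] <- op$W_up[[ci]] %*% u[he]
    bu_v[he] <- op$W_up[[ci]] %*% u[opp[he]]
    bd_u[he] <- wd[[ci]] %*% u[he]
    bd_v[he] <- wd[[ci]] %*% u[opp[he]]
  }
  al <- cp$alpha; be <- cp$beta
  up <- 1 + 0.5 * (al[own] * bu_u + al[neigh] * bu_v[opp])
  dn <- 1 + 0.5 * (be[own] * bd_v + be[neigh] * bd_u[opp])
  du <- params$kappa * pools$f_ubd[own] * pools$g_ubd[neigh] * up -
    params$gamma * u * dn / up
  if (cue$kind == "bulk" && cue$M > 0) {
    amp <- if (is.finite(cue$tau_m)) cue$M * exp(-time / cue$tau_m) else cue$M
    du <- du + amp * cue_spatial(tissue, cue)
  }
  du
}

# static spatial profile of a bulk cue: clipped projection of the
# centroid-to-edge-midpoint vector on the cue direction
cue_spatial <- function(tissue, cue) {
  if (cue$kind != "bulk") return(numeric(tissue$n_he))
  rel <- tissue$he_mid - tissue$centroid[tissue$he_cell, ]
  pmax(0, as.vector(rel %*% cue$direction))
}

# half-edges belonging to the boundary-cue strip, and their clamp values
boundary_clamp <- function(tissue, cue, amplitude = 0.5) {
  d <- cue$direction
  proj <- as.vector(tissue$centroid %*% d)
  width <- cue$depth * sqrt(3) * tissue$l0
  sel <- proj - min(proj) < width
  cells <- which(sel)
  he <- unlist(tissue$cell_he[cells])
  val <- amplitude * pmax(0, as.vector(tissue$he_nhat[he, , drop = FALSE] %*% d))
  list(he = he, value = val, cells = cells)
}

#' One integration step (reference implementation)
#'
#' A single RK4 step of the drift followed by an additive Gaussian noise
#' increment `eta0 * sqrt(dt) * z` per half-edge and clipping of negative
#' concentrations at zero.  Uses R's RNG stream for the noise; seed it
#' with [set.seed()] for reproducibility.  [simulate()] performs the same
#' update in compiled code.
#'
#' @inheritParams drift
#' @param dt step size; defaults to `params$dt`.
#' @return the advanced `pcp_state`.
#' @export
step <- function(state, tissue, op, params, cue = cue_schedule("none"),
                 dt = params$dt) {
  if (dt <= 0) stop("dt must be positive")
  u <- state$u
  st <- function(u2, tm) drift(structure(list(u = u2, time = tm),
                                         class = "pcp_state"),
                               tissue, op, params, cue, time = tm)
  t0 <- state$time
  k1 <- st(u, t0)
  k2 <- st(u + dt / 2 * k1, t0 + dt / 2)
  k3 <- st(u + dt / 2 * k2, t0 + dt / 2)
  k4 <- st(u + dt * k3, t0 + dt)
  u2 <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (params$eta0 > 0)
    u2 <- u2 + params$eta0 * sqrt(dt) * rnorm(length(u2))
  u2 <- pmax(0, u2)
  if (any(!is.finite(u2)))
    stop("non-finite state at t = ", t0 + dt)
  structure(list(u = u2, time = t0 + dt), class = "pcp_state")
}

# flatten the per-cell operator blocks for the compiled core;
# reassembles per-cell kernels when lambda overrides are present
flatten_operator <- function(tissue, op, cp) {
  m <- lengths(tissue$cell_he)
  # half-edge ids must be contiguous per cell (construction guarantees it)
  stopifnot(all(unlist(tissue$cell_he) == seq_len(tissue$n_he)))
  Wu <- op$W_up
  Wd <- op_wdown(op)
  lu <- cp$lambda_u; ld <- cp$lambda_d
  for (ci in which(lu != op$lambda_u)) {
    K <- pairwise_edge_kernel(tissue, ci, lu[ci])
    len <- tissue$he_length[tissue$cell_he[[ci]]]
    W <- K * rep(len, each = nrow(K))
    Wu[[ci]] <- W / rowSums(W)
  }
  for (ci in which(ld != op$lambda_d)) {
    K <- pairwise_edge_kernel(tissue, ci, ld[ci])
    len <- tissue$he_length[tissue$cell_he[[ci]]]
    W <- K * rep(len, each = nrow(K))
    Wd[[ci]] <- W / rowSums(W)
  }
  wu_flat <- unlist(lapply(Wu, t))
  # sharing the same vector lets the integrator use its fused fast path
  wd_flat <- if (is.null(op$W_down) && all(ld == op$lambda_d) &&
                 all(lu == op$lambda_u)) wu_flat else unlist(lapply(Wd, t))
  list(cell_start = c(0L, cumsum(m)),
       woff = c(0L, cumsum(m^2))[seq_along(m)],
       Wup = wu_flat, Wdn = wd_flat)
}

#' Simulate the stochastic junctional dynamics
#'
#' Integrates the model with classical RK4 (step `params$dt`) plus
#' additive Gaussian noise, recording snapshots every `record_every` time
#' units.  The run is flagged steady and stopped early when the largest
#' record-to-record change of the order parameters Q-bar and O over a
#' sliding window of `10/gamma` falls below `steady_tol`.
#'
#' @param tissue a `pcp_tissue`.
#' @param params a `pcp_params` (per-cell overrides honoured).
#' @param ic initial `pcp_state`, e.g. from [init_state()].
#' @param cue a `pcp_cue`.
#' @param Tend duration in units of `1/gamma`.
#' @param seed integer seed for the noise stream (internal generator,
#'   independent of R's RNG).
#' @param record_every snapshot cadence in time units.
#' @param check_steady stop early at the detected steady state?
#' @param steady_tol threshold for the stopping rule.
#' @param op optional pre-assembled `pcp_operator` (reused across runs).
#' @return object of class `pcp_trajectory`: `times`, state matrix `U`
#'   (snapshots in rows), order-parameter series `Qbar`, `O`, `steady`,
#'   `t_steady`, and the inputs needed to interpret them.
#' @export
simulate <- function(tissue, params, ic, cue = cue_schedule("none"),
                     Tend = 200, seed = 1, record_every = 0.5,
                     check_steady = TRUE, steady_tol = 1e-3, op = NULL) {
  stopifnot(inherits(tissue, "pcp_tissue"), inherits(params, "pcp_params"),
            inherits(ic, "pcp_state"), inherits(cue, "pcp_cue"))
  cp <- cell_param_vectors(params, tissue$n_cells)
  if (is.null(op)) op <- assemble_operator(tissue, params$lambda_u, params$lambda_d)
  fl <- flatten_operator(tissue, op, cp)
  u0 <- ic$u
  clamp_idx <- integer(0); clamp_val <- numeric(0)
  if (cue$kind == "boundary") {
    bc <- boundary_clamp(tissue, cue, amplitude = 0.5 * min(params$f0, params$g0))
    if (cue$mode == "persistent-clamp") {
      clamp_idx <- bc$he - 1L
      clamp_val <- bc$value
    } else {
      u0[bc$he] <- cue$boost * bc$value
    }
  }
  cs <- cue_spatial(tissue, cue)
  nsteps <- max(1L, as.integer(round(Tend / params$dt)))
  stride <- max(1L, as.integer(round(record_every / params$dt)))
  res <- .simulate_core(
    u0,
    tissue$he_cell - 1L, tissue$he_opp - 1L, tissue$he_cell[tissue$he_opp] - 1L,
    tissue$he_length, as.integer(fl$cell_start),
    fl$Wup, fl$Wdn, as.integer(fl$woff),
    vapply(seq_len(tissue$n_cells),
           function(ci) sum(tissue$he_length[tissue$cell_he[[ci]]]), 0),
    cp$f0, cp$g0, cp$alpha, cp$beta,
    params$kappa, params$gamma, params$eta0, params$dt, ic$time,
    nsteps, stride,
    cs, if (cue$kind == "bulk") cue$M else 0,
    cue$tau_m,
    clamp_idx, clamp_val,
    tissue$he_nhat, integer(0),
    as.numeric(seed),
    check_steady, 10 / params$gamma, steady_tol)
  structure(list(times = res$times, U = res$U,
                 Qbar = res$Qbar, O = res$O,
                 steady = res$steady, t_steady = res$t_steady,
                 tissue = tissue, params = params, cue = cue, seed = seed),
            class = "pcp_trajectory")
}

#' @export
print.pcp_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(paste0(
    "Trajectory: %d snapshots, t in [%g, %g]%s\n",
    "  final Qbar = %.4f, O = %.4f\n"),
    n, x$times[1], x$times[n],
    if (isTRUE(x$steady)) sprintf(" (steady at t = %g)", x$t_steady) else "",
    x$Qbar[n], x$O[n]))
  invisible(x)
}

#' Extract the state at a snapshot
#'
#' @param traj a `pcp_trajectory`.
#' @param i snapshot index (default: last).
#' @return a `pcp_state`.
#' @export
state_at <- function(traj, i = length(traj$times)) {
  structure(list(u = traj$U[i, ], time = traj$times[i]), class = "pcp_state")
}
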