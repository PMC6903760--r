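# Threshold analyses: junctional polarizability on the ordered lattice
# (linear stability of the uniform symmetric state) and the 1D cell-chain
# reduction.

# uniform symmetric fixed point on the ordered lattice: with all
# junctions equal, the kernel rows sum to one (reference normalization)
# so the cooperative inputs reduce to u itself, and the
# perimeter-averaged pools to f0 - u, g0 - u;
# the cooperative factors of the closure cancel at the symmetric point
# when alpha = beta, but the general balance is solved numerically.
uniform_fixed_point <- function(params) {
  with(params, {
    fn <- function(u) {
      up <- 1 + alpha * u
      kappa * (f0 - u) * (g0 - u) * up - gamma * u * (1 + beta * u) / up
    }
    upper <- min(f0, g0)
    uniroot(fn, c(0, upper * (1 - 1e-12)), tol = 1e-14)$root
  })
}

# leading eigenvalue of the drift Jacobian at the uniform state,
# restricted to junction-antisymmetric perturbations (u and v displaced
# in opposite directions on every junction)
antisym_eigenvalue <- function(tissue, op, params) {
  us <- uniform_fixed_point(params)
  n <- tissue$n_he
  u0 <- rep(us, n)
  base_par <- params
  base_par$eta0 <- 0
  dfun <- function(u) drift(structure(list(u = u, time = 0), class = "pcp_state"),
                            tissue, op, base_par)
  h <- 1e-7 * max(1, us)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    up <- u0; up[k] <- up[k] + h
    um <- u0; um[k] <- um[k] - h
    J[, k] <- (dfun(up) - dfun(um)) / (2 * h)
  }
  opp <- tissue$he_opp
  S <- matrix(0, n, tissue$n_edges)
  done <- logical(n); e <- 0L
  for (mu in seq_len(n)) if (!done[mu]) {
    e <- e + 1L
    S[mu, e] <- 1 / sqrt(2)
    S[opp[mu], e] <- -1 / sqrt(2)
    done[mu] <- TRUE; done[opp[mu]] <- TRUE
  }
  max(Re(eigen(crossprod(S, J %*% S), only.values = TRUE)$values))
}

#' Junctional polarizability threshold
#'
#' On the ordered periodic hexagonal lattice with noise off, individual
#' junctions polarize spontaneously once the total G concentration
#' exceeds a critical value `g*`: the uniform symmetric state loses
#' linear stability to junction-antisymmetric perturbations.  This
#' function locates `g*` by bisecting the sign change of the leading
#' eigenvalue of the drift Jacobian restricted to the antisymmetric
#' sector.  The threshold is deterministic; it decreases as the
#' cooperativity magnitudes grow and depends on the interaction length
#' through the kernel spectrum (the reference value is taken at
#' `lambda/l0 = 0.5`).
#'
#' @param params a `pcp_params`; `g0` is ignored (it is the bisection
#'   variable).
#' @param tol bisection tolerance on `g0`.
#' @param g_range search interval for `g0`.
#' @param nx,ny lattice size used for the Jacobian (the threshold is a
#'   local property; a small periodic lattice already contains all
#'   relevant modes).
#' @return object of class `pcp_threshold`: `g_star`, `bracket`,
#'   `eigen_bracket` (leading eigenvalues at the bracket ends), and the
#'   lattice size used.  Errors with "no threshold found" when the
#'   eigenvalue does not change sign over `g_range`.
#' @export
junctional_threshold <- function(params = model_params(), tol = 0.005,
                                 g_range = c(0.02, 10), nx = 4, ny = 4) {
  if (tol <= 0) stop("tol must be positive")
  tissue <- build_hexagonal(nx, ny, 1)
  op <- assemble_operator(tissue, params$lambda_u, params$lambda_d)
  ev_at <- function(g0) {
    p <- params; p$g0 <- g0
    antisym_eigenvalue(tissue, op, p)
  }
  lo <- g_range[1]; hi <- g_range[2]
  ev_lo <- ev_at(lo)
  if (ev_lo > 0)
    stop("no threshold found: uniform state already unstable at g0 = ", lo)
  # coarse scan upward for a sign change (eigenvalue increases with g0)
  gs <- exp(seq(log(lo), log(hi), length.out = 24))
  ev_hi <- NA; hi_found <- NA
  prev_g <- lo; prev_ev <- ev_lo
  for (g in gs[-1]) {
    e <- ev_at(g)
    if (e > 0) { hi_found <- g; ev_hi <- e; lo <- prev_g; ev_lo <- prev_ev; break }
    prev_g <- g; prev_ev <- e
  }
  if (is.na(hi_found))
    stop("no threshold found in g0 range [", g_range[1], ", ", g_range[2],
         "]: leading antisymmetric eigenvalue stays negative")
  hi <- hi_found
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    e <- ev_at(mid)
    if (e > 0) { hi <- mid; ev_hi <- e } else { lo <- mid; ev_lo <- e }
  }
  structure(list(g_star = (lo + hi) / 2, bracket = c(lo, hi),
                 eigen_bracket = c(ev_lo, ev_hi), nx = nx, ny = ny,
                 lambda_u = params$lambda_u, lambda_d = params$lambda_d),
            class = "pcp_threshold")
}

#' @export
print.pcp_threshold <- function(x, ...) {
  cat(sprintf("Junctional threshold g* = %.4f (bracket [%.4f, %.4f])\n",
              x$g_star, x$bracket[1], x$bracket[2]))
  invisible(x)
}

# ---- one-dimensional chain reduction ------------------------------------

# build the arrays describing a periodic 1D chain of N cells, each with a
# left and right interface; intracellular coupling between the two
# interfaces decays with the cell length
chain_arrays <- function(lengths, lambda_u, lambda_d) {
  N <- length(lengths)
  n <- 2L * N
  own <- rep(seq_len(N), each = 2)
  opp <- integer(n)
  for (i in seq_len(N)) {
    ip <- if (i == N) 1L else i + 1L
    opp[2L * i] <- 2L * ip - 1L
    opp[2L * ip - 1L] <- 2L * i
  }
  wblock <- function(lam) {
    eref <- exp(-1 / lam)   # reference cell of unit length
    lapply(seq_len(N), function(i) {
      e <- exp(-lengths[i] / lam)
      matrix(c(1, e, e, 1) / (1 + eref), 2, 2)
    })
  }
  list(N = N, n = n, own = own, opp = opp,
       Wup = wblock(lambda_u), Wdn = wblock(lambda_d),
       nhat = matrix(rep(c(-1, 0, 1, 0), N), ncol = 2, byrow = TRUE))
}

#' Simulate a periodic 1D chain of cells
#'
#' The one-dimensional reduction: each cell has two interfaces carrying
#' `u` (and the neighbour's `v`); the two interfaces of a cell interact
#' through a weight `exp(-l_i/lambda)` set by the cell length, with the
#' same reference normalization and kinetics as in two dimensions.  Cell
#' lengths are i.i.d. uniform in `l0 * [1 - eps0, 1 + eps0]` (quenched
#' disorder).  The signed cell polarity is the difference of junctional
#' polarities at the two interfaces; the function returns the
#' steady-state average of its magnitude.
#'
#' @param N number of cells (`>= 10`).
#' @param eps0 length disorder magnitude in `[0, 1)`.
#' @param params a `pcp_params`; `f0` and `g0` set the F and G totals.
#' @param ratio optional `G0/F0` ratio; when given, `g0 = ratio * f0`.
#' @param seed integer seed (quenched disorder, initial condition, noise).
#' @param Tend duration.
#' @param dt integration step (defaults to `params$dt`).
#' @return list with `avg_polarization` (mean of |cell polarity| averaged
#'   over the final fifth of the run), `polarity` (final signed per-cell
#'   polarities), and the quenched `lengths`.
#' @export
simulate_chain_1d <- function(N = 200, eps0 = 0, params = model_params(),
                              ratio = NULL, seed = 1, Tend = 60,
                              dt = params$dt) {
  if (N < 10) stop("N must be at least 10")
  if (eps0 < 0 || eps0 >= 1) stop("eps0 must lie in [0, 1)")
  if (!is.null(ratio)) params$g0 <- ratio * params$f0
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lens <- runif(N, 1 - eps0, 1 + eps0)
  ch <- chain_arrays(lens, params$lambda_u, params$lambda_d)
  u0 <- runif(ch$n, 0, 0.5 * min(params$f0, params$g0))
  nsteps <- max(1L, as.integer(round(Tend / dt)))
  stride <- max(1L, as.integer(round(0.5 / dt)))
  wu_flat <- unlist(lapply(ch$Wup, t))
  wd_flat <- if (params$lambda_d == params$lambda_u) wu_flat
             else unlist(lapply(ch$Wdn, t))
  res <- .simulate_core(
    u0, ch$own - 1L, ch$opp - 1L, ch$own[ch$opp] - 1L,
    rep(1, ch$n), as.integer(seq(0L, ch$n, by = 2L)),
    wu_flat, wd_flat,
    as.integer(seq(0L, by = 4L, length.out = ch$N)),
    rep(2, ch$N),
    rep(params$f0, ch$N), rep(params$g0, ch$N),
    rep(params$alpha, ch$N), rep(params$beta, ch$N),
    params$kappa, params$gamma, params$eta0, dt, 0,
    nsteps, stride,
    numeric(ch$n), 0, Inf, integer(0), numeric(0),
    ch$nhat, integer(0), as.numeric(seed),
    TRUE, 10 / params$gamma, 1e-3)
  nr <- length(res$times)
  tail_idx <- seq.int(max(1L, nr - max(4L, nr %/% 5)), nr)
  uF <- res$U[nr, ]
  pol <- uF[seq(2, ch$n, by = 2)] - uF[ch$opp[seq(2, ch$n, by = 2)]] -
    (uF[seq(1, ch$n, by = 2)] - uF[ch$opp[seq(1, ch$n, by = 2)]])
  list(avg_polarization = mean(res$Qbar[tail_idx]),
       polarity = pol, lengths = lens, times = res$times, Qbar = res$Qbar)
}

#' Critical G0/F0 ratio of the 1D chain
#'
#' Sweeps the `G0/F0` ratio, running an ensemble of chains per grid point
#' and averaging the steady-state polarization; the critical ratio is
#' estimated as the midpoint of the steepest rise of the resulting curve
#' (finite-size and noise smearing make a hard zero crossing
#' ill-defined).
#'
#' @param grid sorted vector of `G0/F0` ratios.
#' @param N cells per chain.
#' @param realizations ensemble size per ratio (`>= 10`).
#' @param eps0 length disorder.
#' @param seed integer base seed.
#' @param params a `pcp_params`.
#' @param Tend duration per run.
#' @param min_rise minimum total rise of the curve for a threshold to be
#'   declared present.
#' @return object of class `pcp_chain_result`: `grid`, mean `polarization`
#'   per ratio, `critical` (estimated ratio or `NA`), `absent` flag.
#' @export
threshold_1d <- function(grid = seq(0.05, 0.6, by = 0.02), N = 200,
                         realizations = 100, eps0 = 0, seed = 1,
                         params = model_params(), Tend = 60,
                         min_rise = 0.05) {
  if (is.unsorted(grid)) stop("grid must be sorted increasingly")
  if (realizations < 10) stop("need at least 10 realizations")
  pol <- vapply(seq_along(grid), function(gi) {
    mean(vapply(seq_len(realizations), function(r) {
      simulate_chain_1d(N, eps0, params, ratio = grid[gi],
                        seed = seed * 1e5 + gi * 1e3 + r, Tend = Tend)$avg_polarization
    }, 0))
  }, 0)
  rise <- diff(pol)
  absent <- (max(pol) - min(pol)) < min_rise
  critical <- if (absent) NA_real_ else {
    k <- which.max(rise)
    (grid[k] + grid[k + 1]) / 2
  }
  if (!absent && any(rise < -3 * sd(rise[rise > 0]) / sqrt(realizations)))
    warning("polarization curve is non-monotone beyond noise")
  structure(list(grid = grid, polarization = pol, critical = critical,
                 absent = absent, eps0 = eps0, N = N,
                 realizations = realizations),
            class = "pcp_chain_result")
}

#' @export
print.pcp_chain_result <- function(x, ...) {
  cat(sprintf(paste0("1D chain threshold scan: N = %d, %d realizations, ",
                     "eps0 = %g\n  critical G0/F0 = %s\n"),
              x$N, x$realizations, x$eps0,
              if (x$absent) "not found (curve flat)" else sprintf("%.3f", x$critical)))
  invisible(x)
}
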