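# Polarity observables: cell dipoles, global order parameters, angular
# statistics and the orientational correlation length.

#' Cell polarity dipoles
#'
#' Each junction contributes a vector pointing from the cell centroid
#' towards the junction midpoint, weighted by the junctional polarity
#' `u - v` (the difference between same- and opposite-polarity complex
#' concentrations).  The cell dipole is the vector sum over the cell's
#' junctions; junction lengths do not enter, so the dipole measures
#' protein segregation, not geometry.
#'
#' @param state a `pcp_state`.
#' @param tissue the tissue the state lives on.
#' @return object of class `pcp_dipoles`: data.frame with per-cell `Px`,
#'   `Py`, magnitude `mag` and angle `phi_ip` (degrees in `[0, 360)`;
#'   `NA` for magnitudes below `1e-8`).
#' @export
cell_dipoles <- function(state, tissue) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  u <- state$u
  d <- (u - u[tissue$he_opp]) * tissue$he_nhat
  P <- rowsum(d, tissue$he_cell)
  mag <- sqrt(rowSums(P^2))
  phi <- (atan2(P[, 2], P[, 1]) * 180 / pi) %% 360
  phi[mag < 1e-8] <- NA_real_
  structure(data.frame(Px = P[, 1], Py = P[, 2], mag = mag, phi_ip = phi),
            class = c("pcp_dipoles", "data.frame"))
}

#' Global polarity order parameters
#'
#' `Pbar` is the magnitude of the mean dipole vector, `Qbar` the mean of
#' the dipole magnitudes, and `O = Pbar/Qbar` their ratio: 1 for
#' identical aligned dipoles, near 0 for randomly oriented ones.  By
#' construction `Qbar >= Pbar`, so `O` lies in `[0, 1]`.  When all
#' dipoles vanish, `O` is undefined and reported as `NA`.
#'
#' @param dipoles a `pcp_dipoles` from [cell_dipoles()].
#' @return list with `Pbar`, `Qbar`, `O`, and `phi_mean` (direction of
#'   the mean dipole, degrees).
#' @export
order_parameters <- function(dipoles) {
  mx <- mean(dipoles$Px); my <- mean(dipoles$Py)
  Pbar <- sqrt(mx^2 + my^2)
  Qbar <- mean(dipoles$mag)
  O <- if (Qbar > 1e-14) Pbar / Qbar else NA_real_
  list(Pbar = Pbar, Qbar = Qbar, O = O,
       phi_mean = if (Pbar > 1e-14) (atan2(my, mx) * 180 / pi) %% 360
                  else NA_real_)
}

#' Orientational correlation length of the dipole field
#'
#' Computes the pair correlation `C(r) = <cos(phi_i - phi_j)>` of dipole
#' angles over cell pairs binned by minimum-image centroid distance (bin
#' width `l0`), and returns the smallest `r` at which `C(r)` falls below
#' `1/e`, linearly interpolated between bins and capped at half the box
#' diagonal.  Cells with undefined dipole angle are excluded.
#'
#' @param dipoles a `pcp_dipoles`.
#' @param tissue the matching `pcp_tissue` (needs `>= 100` cells).
#' @return list with `xi` (in units of the cell diameter `sqrt(3) l0`),
#'   `xi_length` (same, in length units), `capped` (logical: correlation
#'   never decayed below `1/e`), and the binned correlation `r`, `C`.
#' @export
correlation_length <- function(dipoles, tissue) {
  stopifnot(inherits(tissue, "pcp_tissue"))
  if (tissue$n_cells < 100)
    stop("correlation length needs at least 100 cells, got ", tissue$n_cells)
  ok <- which(!is.na(dipoles$phi_ip))
  if (length(ok) < 100)
    stop("fewer than 100 cells with defined dipole angle")
  cx <- tissue$centroid[ok, 1]; cy <- tissue$centroid[ok, 2]
  a <- dipoles$phi_ip[ok] * pi / 180
  n <- length(ok)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  dx <- cx[jj] - cx[ii]; dy <- cy[jj] - cy[ii]
  dx <- dx - tissue$box[1] * round(dx / tissue$box[1])
  dy <- dy - tissue$box[2] * round(dy / tissue$box[2])
  r <- sqrt(dx^2 + dy^2)
  cc <- cos(a[jj] - a[ii])
  bw <- tissue$l0
  bin <- pmax(1L, as.integer(ceiling(r / bw)))
  Cr <- vapply(split(cc, bin), mean, 0)
  rb <- (as.integer(names(Cr)) - 0.5) * bw
  o <- order(rb); rb <- rb[o]; Cr <- unname(Cr[o])
  cap <- sqrt(sum(tissue$box^2)) / 2
  thr <- exp(-1)
  below <- which(Cr < thr)
  if (!length(below)) {
    xi <- cap; capped <- TRUE
  } else {
    k <- below[1]
    if (k == 1) {
      xi <- rb[1]
    } else {
      xi <- rb[k - 1] + (rb[k] - rb[k - 1]) * (Cr[k - 1] - thr) / (Cr[k - 1] - Cr[k])
    }
    xi <- min(xi, cap); capped <- FALSE
  }
  diam <- sqrt(3) * tissue$l0
  list(xi = xi / diam, xi_length = xi, capped = capped, r = rb, C = Cr)
}

#' Angular histogram (rose plot data) of dipole angles
#'
#' @param dipoles a `pcp_dipoles`.
#' @param nbins number of equal bins over `[0, 360)` degrees, `>= 4`.
#' @return data.frame with bin `mid` (degrees) and `count`; counts sum to
#'   the number of cells with defined dipole angle, and `n_undefined`
#'   (attribute) reports the excluded cells.
#' @export
angular_histogram <- function(dipoles, nbins = 36) {
  if (nbins < 4) stop("nbins must be at least 4")
  phi <- dipoles$phi_ip[!is.na(dipoles$phi_ip)]
  bin <- pmin(nbins, floor(phi / (360 / nbins)) + 1L)
  cnt <- tabulate(bin, nbins)
  out <- data.frame(mid = (seq_len(nbins) - 0.5) * 360 / nbins, count = cnt)
  attr(out, "n_undefined") <- sum(is.na(dipoles$phi_ip))
  out
}

#' Dipole-versus-elongation scatter tables
#'
#' Cell-by-cell comparison of polarity and shape: dipole magnitude
#' against elongation index, and the absolute angle between the dipole
#' and the cell's elongation axis (folded into `[0, 90]` degrees, since
#' the elongation axis is undirected).
#'
#' @param dipoles a `pcp_dipoles`.
#' @param stats shape statistics from [cell_shape_stats()] on the same
#'   tissue.
#' @return list with `table` (per-cell `mag`, `Ei`, `dphi`, `phi_ie`) and
#'   `cor_mag_E`, the Pearson correlation of dipole magnitude with cell
#'   elongation (NA if degenerate).
#' @export
elongation_polarity_scatter <- function(dipoles, stats) {
  cs <- stats$cells
  if (nrow(cs) != nrow(dipoles)) stop("tissue mismatch")
  dphi <- fold_axial(dipoles$phi_ip - cs$phi_ie)
  ok <- stats::complete.cases(dipoles$mag, cs$Ei)
  r <- if (sum(ok) > 2 && sd(dipoles$mag[ok]) > 0 && sd(cs$Ei[ok]) > 0)
    stats::cor(dipoles$mag[ok], cs$Ei[ok]) else NA_real_
  list(table = data.frame(mag = dipoles$mag, Ei = cs$Ei,
                          dphi = dphi, phi_ie = cs$phi_ie),
       cor_mag_E = r)
}

# fold an angle difference (degrees) into [0, 90]: axes are undirected
fold_axial <- function(dphi) {
  d <- abs(dphi) %% 180
  pmin(d, 180 - d)
}

# circular mean (degrees) of directed angles
circ_mean_deg <- function(phi) {
  (atan2(mean(sin(phi * pi / 180)), mean(cos(phi * pi / 180))) * 180 / pi) %% 360
}

# circular standard deviation (degrees)
circ_sd_deg <- function(phi) {
  R <- sqrt(mean(cos(phi * pi / 180))^2 + mean(sin(phi * pi / 180))^2)
  sqrt(-2 * log(max(R, 1e-300))) * 180 / pi
}

#' Tidy order-parameter time series of a trajectory
#'
#' @param traj a `pcp_trajectory`.
#' @return data.frame with `time`, `Pbar`, `Qbar`, `O`, and `xi` columns
#'   (`xi` only when `with_xi = TRUE`).
#' @param with_xi also compute the correlation length at each snapshot
#'   (quadratic in cell number; off by default).
#' @export
order_series <- function(traj, with_xi = FALSE) {
  n <- length(traj$times)
  out <- data.frame(time = traj$times, Pbar = traj$Qbar * traj$O,
                    Qbar = traj$Qbar, O = traj$O)
  if (with_xi) {
    out$xi <- vapply(seq_len(n), function(i) {
      correlation_length(cell_dipoles(state_at(traj, i), traj$tissue),
                         traj$tissue)$xi
    }, 0)
  }
  out
}
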