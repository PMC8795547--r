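# Species-symmetric rate-equation model for the 1D ring. In the large-N
# limit the species identities are dynamically irrelevant for the
# simultaneous-supply scenarios, so the state reduces to the per-species
# free-monomer concentration m, the size-resolved cluster concentrations
# c_k (k = 2..S-1, all species compositions pooled) and the concentration y
# of completed rings. Never applicable to just-in-sequence supply, where
# species identity is the whole point.

#' Right-hand side of the size-distribution rate equations
#'
#' Fluxes for the 1D ring under the species-symmetric reduction:
#' nucleation `J = P * mu * m^2` into `c_2` (with `P = S` compatible pairs,
#' `P = 1` for the degenerate `S = 2` ring); growth `a_k = 2 * nu * m * c_k`
#' (two chain ends, each requiring one specific species at concentration
#' `m`); shrinkage `b_k = 2 * delta * c_k` for `k >= 3`; dimer breakup
#' `2 * delta * c_2` returning two monomers; completion of `c_{S-1}` into
#' `y` at the growth rate of the single ring-closing vacancy (`2 * nu * m`
#' per bond, `nu * m` under the per-vacancy convention). Mass
#' `S*m + sum(k * c_k) + S*y` is conserved identically.
#'
#' @param t Time (unused; the system is autonomous except for influx).
#' @param y_ State vector `c(m, c_2, ..., c_{S-1}, y)`.
#' @param parms List with `S`, `mu`, `nu`, `delta`, `C`, optional `alpha`
#'   (activation influx `C * alpha` while `t < 1/alpha`) and `per_bond`.
#' @return `list(derivatives)` in the [deSolve::ode()] convention.
#' @export
bd_rhs <- function(t, y_, parms) {
  S <- parms$S
  mu <- parms$mu
  nu <- parms$nu
  delta <- parms$delta
  per_bond <- isTRUE(parms$per_bond) || is.null(parms$per_bond)
  m <- max(y_[1L], 0)   # clamp roundoff-level negatives
  P <- if (S == 2L) 1 else S
  nucl <- P * mu * m * m

  if (S == 2L) {
    dm <- -2 * nucl / S
    dy <- nucl
    dc <- numeric(0)
  } else {
    ck <- pmax(y_[2L:(S - 1L)], 0)   # c_2 .. c_{S-1}
    K <- length(ck)
    grow <- 2 * nu * m * ck          # a_k, k = 2..S-1
    grow[K] <- (if (per_bond) 2 else 1) * nu * m * ck[K]  # ring closure
    shrink <- 2 * delta * ck         # b_k (k >= 3); for k = 2: dimer breakup
    dc <- numeric(K)
    # gain from growth of k-1, loss by own growth; gain from shrink of k+1
    dc <- -grow - shrink
    dc[1L] <- dc[1L] + nucl
    if (K > 1L) {
      dc[2L:K] <- dc[2L:K] + grow[1L:(K - 1L)]
      dc[1L:(K - 1L)] <- dc[1L:(K - 1L)] + shrink[2L:K]
    }
    dy <- grow[K]
    monomer_gain <- sum(shrink[-1L]) + 2 * shrink[1L]  # dimer breakup frees 2
    dm <- -2 * nucl / S - sum(grow) / S + monomer_gain / S
  }
  if (!is.null(parms$alpha) && is.finite(parms$alpha) &&
      t < 1 / parms$alpha) {
    dm <- dm + parms$C * parms$alpha
  }
  list(c(dm, dc, dy))
}

#' Integrate the mean-field size distribution
#'
#' Stiff-capable adaptive integration (lsoda) of [bd_rhs()] from
#' `m(0) = C`, `c_k(0) = 0` (or `m(0) = 0` with an influx source when
#' `alpha` is finite). `T90` is the first time the yield `y / C` reaches
#' `target_yield`, interpolated between output points on a dense grid.
#'
#' @param S Ring size (number of species, `>= 2`).
#' @param mu,nu,delta Rate constants (see [bd_rhs()]).
#' @param C Concentration per species.
#' @param t_end End of the integration horizon.
#' @param alpha Optional finite influx rate (activation cross-checks).
#' @param per_bond Ring-closure convention, see [bd_rhs()].
#' @param target_yield Yield level defining `T90`.
#' @param n_out Output grid size.
#' @param rtol,atol Integrator tolerances.
#' @return List with `trajectory` (data frame `t`, `m`, `yield`, `mass`),
#'   `t90` (`NA` if the target is not reached), `final_yield` and
#'   `conservation_drift` (max relative mass error).
#' @export
bd_integrate <- function(S, mu = 1, nu = 1, delta = 0, C = 1, t_end,
                         alpha = Inf, per_bond = TRUE, target_yield = 0.9,
                         n_out = 2000L, rtol = 1e-9, atol = 1e-12) {
  if (t_end <= 0) stop("`t_end` must be positive")
  if (S < 2) stop("`S` must be at least 2")
  S <- as.integer(S)
  nstate <- if (S == 2L) 2L else S
  y0 <- numeric(nstate)
  y0[1L] <- if (is.finite(alpha)) 0 else C
  parms <- list(S = S, mu = mu, nu = nu, delta = delta, C = C,
                alpha = alpha, per_bond = per_bond)
  times <- unique(c(0, exp(seq(log(t_end / 1e4), log(t_end), length.out = n_out))))
  # bdf: stiff-capable and robust to the underflow-level negative states
  # that the late trap regime produces (lsoda's method switching is not)
  sol <- deSolve::ode(y = y0, times = times, func = bd_rhs, parms = parms,
                      method = "bdf", rtol = rtol, atol = atol)
  m <- sol[, 2L]
  ycomp <- sol[, nstate + 1L]
  mass <- if (S == 2L) S * m + S * ycomp else
    S * m + as.vector(sol[, 3L:nstate, drop = FALSE] %*% (2:(S - 1L))) + S * ycomp
  drift <- max(abs(mass - S * C)) / (S * C)
  yield <- ycomp / C
  t90 <- NA_real_
  ix <- which(yield >= target_yield)
  if (length(ix)) {
    i <- ix[1L]
    if (i == 1L) t90 <- sol[1L, 1L]
    else t90 <- approx(yield[(i - 1L):i], sol[(i - 1L):i, 1L],
                       xout = target_yield)$y
  }
  list(trajectory = data.frame(t = sol[, 1L], m = m, yield = yield,
                               mass = mass),
       t90 = t90, final_yield = yield[length(yield)],
       conservation_drift = drift)
}
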