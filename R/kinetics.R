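#' Rate constants of the assembly reaction network
#'
#' Collects the physical constants in nondimensional reactive units: with
#' the defaults `C = 1` and `nu = 1`, times are measured in units of
#' `(C*nu)^-1`. The detachment preexponential factor follows
#' `A = 1e18 * C * nu` whenever binding is reversible (finite `E_B`);
#' `E_B = Inf` encodes irreversible binding (`delta_n == 0`).
#'
#' @param N Copies per species.
#' @param C Concentration per species (`N / V`).
#' @param nu Attachment rate constant per binding site.
#' @param mu Dimerization rate constant (defaults to `nu`).
#' @param E_B Binding energy per bond in units of `k_B T`; `Inf` for
#'   irreversible binding.
#' @param alpha Influx rate parameter; `Inf` for instantaneous supply.
#' @return A list of class `"rate_constants"` with fields `N`, `C`, `V`,
#'   `mu`, `nu`, `E_B`, `A`, `alpha`.
#' @export
rate_constants <- function(N, C = 1, nu = 1, mu = nu, E_B = Inf, alpha = Inf) {
  if (N < 1 || C <= 0 || nu < 0 || mu < 0) stop("invalid rate constants")
  if (!is.infinite(E_B) && E_B <= 0) stop("`E_B` must be positive (or Inf)")
  if (alpha <= 0) stop("`alpha` must be positive (or Inf)")
  structure(list(N = N, C = C, V = N / C, mu = mu, nu = nu, E_B = E_B,
                 A = if (is.finite(E_B)) 1e18 * C * nu else 0, alpha = alpha),
            class = "rate_constants")
}

#' Arrhenius detachment rate for a monomer bound by n bonds
#'
#' `delta_n = A * exp(-n * E_B)`; zero when `E_B = Inf` (irreversible
#' binding).
#'
#' @param n Number of bonds to break (integer >= 1).
#' @param rates A [rate_constants()] object (fields `A`, `E_B`).
#' @return Nonnegative rate.
#' @export
detachment_rate <- function(n, rates) {
  if (any(n < 1) || any(n != as.integer(n)))
    stop("`n` must be an integer number of bonds >= 1")
  if (is.infinite(rates$E_B)) return(rep(0, length(n)))
  rates$A * exp(-n * rates$E_B)
}

#' Reaction propensities of a state
#'
#' Enumerates every currently feasible reaction with its propensity:
#' dimerization of a compatible free pair `(i, j)` at `mu * a_i * a_j / V`;
#' attachment of species `s` at a frontier vacancy with bond count `b` at
#' `b * nu * a_s / V` (or `nu * a_s / V` under the per-vacancy convention);
#' detachment of a removable member with `n` bonds at `delta_n`; influx of
#' species `s` at `copies * alpha` while its supply window is open and
#' monomers remain undelivered. A zero total signals an absorbing state.
#'
#' @param state An [new_assembly_state()] object.
#' @param rates A [rate_constants()] object.
#' @param supply Optional supply schedule data frame (columns `time`,
#'   `species`, `copies`, `alpha`) for influx propensities, evaluated at
#'   `state$t`.
#' @param per_bond Attachment convention: `TRUE` weights a vacancy by its
#'   bond count.
#' @return A list with data frames `dimerization`, `attachment`,
#'   `detachment`, `influx` and the scalar `total`.
#' @export
compute_propensities <- function(state, rates, supply = NULL, per_bond = TRUE) {
  stopifnot(inherits(state, "assembly_state"))
  g <- state$geometry
  a <- state$active

  bonds <- g$bonds
  dimer <- data.frame(i = bonds[, 1L], j = bonds[, 2L],
                      propensity = rates$mu * a[bonds[, 1L]] * a[bonds[, 2L]] / rates$V)
  dimer <- dimer[dimer$propensity > 0, , drop = FALSE]

  att <- det <- list()
  for (k in seq_along(state$clusters)) {
    members <- state$clusters[[k]]$members
    fr <- cluster_frontier(g, members)
    fr <- fr[a[fr$site] > 0L, , drop = FALSE]   # feasible entries only
    if (nrow(fr)) {
      w <- if (per_bond) fr$b else 1
      att[[length(att) + 1L]] <- data.frame(
        cluster = k, site = fr$site, b = fr$b, species = fr$site,
        propensity = w * rates$nu * a[fr$site] / rates$V)
    }
    if (is.finite(rates$E_B)) {
      rm_ <- removable_members(g, members)
      det[[length(det) + 1L]] <- data.frame(
        cluster = k, site = rm_$site, n = rm_$n,
        propensity = detachment_rate(rm_$n, rates))
    }
  }
  attachment <- if (length(att)) do.call(rbind, att) else
    data.frame(cluster = integer(0), site = integer(0), b = integer(0),
               species = integer(0), propensity = numeric(0))
  detachment <- if (length(det)) do.call(rbind, det) else
    data.frame(cluster = integer(0), site = integer(0), n = integer(0),
               propensity = numeric(0))

  if (!is.null(supply) && nrow(supply)) {
    open <- is.finite(supply$alpha) & state$t >= supply$time &
      state$unsupplied[supply$species] > 0L
    influx <- data.frame(species = supply$species[open],
                         propensity = supply$copies[open] * supply$alpha[open])
  } else {
    influx <- data.frame(species = integer(0), propensity = numeric(0))
  }

  total <- sum(dimer$propensity) + sum(attachment$propensity) +
    sum(detachment$propensity) + sum(influx$propensity)
  list(dimerization = dimer, attachment = attachment, detachment = detachment,
       influx = influx, total = total)
}

#' Draw one exact-SSA step from a propensity table
#'
#' Samples an exponential waiting time at the total propensity and an event
#' proportional to its entry. If the next supply boundary falls inside the
#' waiting time, the step truncates at the boundary and returns no event
#' (the caller advances the clock and recomputes propensities — the standard
#' handling of stepwise-constant time dependence).
#'
#' @param state An [new_assembly_state()] object.
#' @param table Result of [compute_propensities()] with `total > 0`.
#' @param next_boundary Time of the next supply-schedule discontinuity.
#' @return A list with `event` (an event list, or `NULL` on truncation) and
#'   `tau` (time increment). Uses R's RNG.
#' @export
ssa_step <- function(state, table, next_boundary = Inf) {
  if (table$total <= 0) stop("absorbing state: total propensity is zero")
  tau <- rexp(1, table$total)
  if (state$t + tau >= next_boundary)
    return(list(event = NULL, tau = next_boundary - state$t))
  props <- c(table$dimerization$propensity, table$attachment$propensity,
             table$detachment$propensity, table$influx$propensity)
  idx <- sample.int(length(props), 1L, prob = props)
  nd <- nrow(table$dimerization)
  na <- nrow(table$attachment)
  nt <- nrow(table$detachment)
  event <-
    if (idx <= nd) ev_dimerize(table$dimerization$i[idx], table$dimerization$j[idx])
    else if (idx <= nd + na) {
      r <- table$attachment[idx - nd, ]
      ev_attach(r$cluster, r$site)
    } else if (idx <= nd + na + nt) {
      r <- table$detachment[idx - nd - na, ]
      ev_detach(r$cluster, r$site)
    } else {
      ev_influx(table$influx$species[idx - nd - na - nt])
    }
  list(event = event, tau = tau)
}

#' Run a stochastic assembly simulation
#'
#' Simulates a scenario configuration with the compiled exact-SSA engine
#' (direct method; integer bookkeeping of the dimerization and attachment
#' propensity sums). The run stops at an absorbing state, at `max_time`, at
#' `max_events`, or — if `stop_on_target` — as soon as the yield first
#' reaches `target_yield` (that first-crossing time is `T90` for the default
#' target of 0.9).
#'
#' @param config A scenario configuration from [make_dimerization()],
#'   [make_reversible()], [make_activation()] or [make_jis()].
#' @param target_yield Yield whose first-crossing time is recorded.
#' @param max_time,max_events Stop caps; runs that hit a cap before the
#'   target are flagged censored, not errors.
#' @param seed Integer seed (reproducible: same seed, same trajectory).
#' @param checkpoint_every Record a trajectory row every this many events
#'   (plus at every completion event). Default: `n_expected / 1e4`.
#' @param stop_on_target Stop at the first target crossing.
#' @return An object of class `"assembly_trajectory"`: list with `t90`,
#'   `final_yield`, `final_time`, `censored`, `events` (named counts),
#'   `trajectory` (data frame `t`, `yield`, `n_clusters`,
#'   `free_monomers_total`, `completed`), `initial_propensity`, `seed` and
#'   the `config`.
#' @export
run_simulation <- function(config, target_yield = 0.9, max_time = Inf,
                           max_events = Inf, seed = 1L,
                           checkpoint_every = NULL, stop_on_target = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$geometry
  csr <- geometry_csr(g)
  sup <- config$supply
  if (is.null(checkpoint_every)) {
    expected <- 2.5 * sum(as.numeric(sup$copies))
    checkpoint_every <- max(1, floor(expected / 1e4))
  }
  res <- .ssa_run(
    S = g$S, d = g$d, adj = csr$adj, adj_ptr = csr$ptr,
    bond_i = csr$bond_i, bond_j = csr$bond_j,
    sup_time = as.numeric(sup$time), sup_species = as.integer(sup$species - 1L),
    sup_copies = as.integer(sup$copies), sup_alpha = as.numeric(sup$alpha),
    mu = config$mu, nu = config$nu, EB = config$E_B, Afac = config$A,
    V = config$V, per_bond = config$per_bond,
    target_yield = target_yield, reference_count = config$reference_count,
    max_time = if (is.finite(max_time)) max_time else 1e300,
    max_events = if (is.finite(max_events)) max_events else 1e300,
    stop_on_target = stop_on_target,
    checkpoint_every = checkpoint_every,
    seed = as.numeric(seed))
  res$censored <- res$censored_time || res$censored_events
  res$seed <- seed
  res$config <- config
  class(res) <- "assembly_trajectory"
  res
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  cat(sprintf("assembly trajectory: %s scenario, S = %d, N = %g\n",
              x$config$scenario, x$config$geometry$S, x$config$N))
  cat(sprintf("  final yield %.3f at t = %.4g (%.0f events)\n",
              x$final_yield, x$final_time, x$n_events))
  if (!is.na(x$t90)) cat(sprintf("  T90 = %.6g\n", x$t90))
  else cat(sprintf("  target yield not reached%s\n",
                   if (x$censored) " (censored)" else ""))
  invisible(x)
}
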