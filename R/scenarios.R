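# shared constructor: every non-controlled parameter keeps the default values
# T_i = 0, alpha = Inf, mu = nu, E_B = Inf (delta_n = 0)
new_scenario_config <- function(geometry, scenario, control, rates, supply,
                                per_bond = TRUE,
                                yield_reference = c("min_supplied", "nominal")) {
  yield_reference <- match.arg(yield_reference)
  supplied <- vapply(seq_len(geometry$S), function(s)
    sum(supply$copies[supply$species == s]), numeric(1))
  if (any(supplied <= 0))
    stop("supply schedule misses species: ",
         paste(which(supplied <= 0), collapse = ", "))
  reference_count <- if (yield_reference == "min_supplied")
    as.integer(min(supplied)) else as.integer(rates$N)
  structure(
    list(geometry = geometry, scenario = scenario, control = control,
         N = rates$N, C = rates$C, V = rates$V, mu = rates$mu, nu = rates$nu,
         E_B = rates$E_B, A = rates$A, alpha = rates$alpha,
         supply = supply, per_bond = per_bond,
         yield_reference = yield_reference,
         reference_count = reference_count),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario config: %s, d = %d, S = %d, N = %g\n",
              x$scenario, x$geometry$d, x$geometry$S, x$N))
  cat(sprintf("  control: %s = %g\n", names(x$control)[1], x$control[[1]]))
  cat(sprintf("  mu = %g, nu = %g, E_B = %g, alpha = %g, %d supply entries\n",
              x$mu, x$nu, x$E_B, x$alpha, nrow(x$supply)))
  invisible(x)
}

bulk_supply <- function(S, N) {
  data.frame(time = 0, species = seq_len(S), copies = as.integer(round(N)),
             alpha = Inf)
}

#' Reversible-binding scenario
#'
#' All monomers are supplied at `t = 0`; binding is reversible with per-bond
#' energy `E_B`, so a monomer bound by `n` bonds detaches at
#' `delta_n = A * exp(-n * E_B)` with `A = 1e18 * C * nu`. The binding
#' energy is the control parameter.
#'
#' @param geometry An [build_geometry()] object.
#' @param E_B Finite positive binding energy (units of `k_B T`).
#' @param N Copies per species.
#' @param C Concentration per species.
#' @param nu Attachment rate constant.
#' @param per_bond Attachment convention (see [compute_propensities()]).
#' @return A `"scenario_config"`.
#' @export
make_reversible <- function(geometry, E_B, N, C = 1, nu = 1, per_bond = TRUE) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  if (!is.finite(E_B) || E_B <= 0)
    stop("`E_B` must be finite and positive; E_B = Inf is the irreversible default, not this scenario")
  rates <- rate_constants(N, C, nu, mu = nu, E_B = E_B, alpha = Inf)
  new_scenario_config(geometry, "reversible", list(E_B = E_B), rates,
                      bulk_supply(geometry$S, N), per_bond = per_bond)
}

#' Dimerization-controlled scenario
#'
#' All monomers at `t = 0`, irreversible binding; the nucleation barrier
#' `mu / nu < 1` is the control parameter.
#'
#' @inheritParams make_reversible
#' @param mu_over_nu Dimerization rate relative to the attachment rate.
#' @return A `"scenario_config"`.
#' @export
make_dimerization <- function(geometry, mu_over_nu, N, C = 1, nu = 1,
                              per_bond = TRUE) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  if (!is.finite(mu_over_nu) || mu_over_nu <= 0)
    stop("`mu_over_nu` must be positive")
  rates <- rate_constants(N, C, nu, mu = mu_over_nu * nu, E_B = Inf, alpha = Inf)
  new_scenario_config(geometry, "dimerization", list(mu_over_nu = mu_over_nu),
                      rates, bulk_supply(geometry$S, N), per_bond = per_bond)
}

#' Activation (influx-controlled) scenario
#'
#' Every species is supplied by a constant stochastic influx at rate
#' `N * alpha` starting at `t = 0` over a window of nominal length
#' `1 / alpha`, which throttles the momentary free-monomer concentration and
#' with it the effective dimerization rate. The influx stays open until the
#' species' allotment of `N` copies has been delivered (the expected overrun
#' beyond `1 / alpha` is a relative `O(N^-1/2)`).
#'
#' @inheritParams make_reversible
#' @param alpha Positive finite influx rate parameter.
#' @return A `"scenario_config"`.
#' @export
make_activation <- function(geometry, alpha, N, C = 1, nu = 1, per_bond = TRUE) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be finite and positive")
  rates <- rate_constants(N, C, nu, mu = nu, E_B = Inf, alpha = alpha)
  supply <- data.frame(time = 0, species = seq_len(geometry$S),
                       copies = as.integer(round(N)), alpha = alpha)
  new_scenario_config(geometry, "activation", list(alpha = alpha), rates,
                      supply, per_bond = per_bond)
}

#' Just-in-sequence (JIS) supply scenario
#'
#' Species are supplied in the ordered batches of [onion_shells()] at
#' equidistant times `T_k = (k - 1) * delta_T`, instantaneously
#' (`alpha = Inf`). Under the linear nonstoichiometric ramp, the species
#' with supply rank `r` (position in the flattened batch order) receives
#' `round(N * (0.9 + 0.2 * (r - 1) / (S - 1)))` copies, i.e. `0.9 N` for the
#' first species rising linearly to `1.1 N` for the last; under
#' stoichiometric supply every species receives `N` copies. The yield
#' reference defaults to the minimum supplied copy number over species, so a
#' ramped run can reach yield 1.
#'
#' @inheritParams make_reversible
#' @param delta_T Positive spacing between supply batches.
#' @param ramp `"stoichiometric"` or `"linear"` (the 0.9N -> 1.1N ramp).
#' @param yield_reference `"min_supplied"` (default) or `"nominal"` (plain N).
#' @return A `"scenario_config"`.
#' @export
make_jis <- function(geometry, delta_T, N, ramp = c("stoichiometric", "linear"),
                     C = 1, nu = 1, per_bond = TRUE,
                     yield_reference = c("min_supplied", "nominal")) {
  stopifnot(inherits(geometry, "assembly_geometry"))
  if (!is.finite(delta_T) || delta_T <= 0) stop("`delta_T` must be positive")
  ramp <- match.arg(ramp)
  S <- geometry$S
  batches <- onion_shells(geometry)
  order_flat <- unlist(batches)
  copies <- if (ramp == "linear" && S > 1L) {
    rank <- match(seq_len(S), order_flat)
    as.integer(round(N * (0.9 + 0.2 * (rank - 1) / (S - 1))))
  } else {
    rep(as.integer(round(N)), S)
  }
  supply <- do.call(rbind, lapply(seq_along(batches), function(k) {
    sp <- batches[[k]]
    data.frame(time = (k - 1) * delta_T, species = sp, copies = copies[sp],
               alpha = Inf)
  }))
  rownames(supply) <- NULL
  rates <- rate_constants(N, C, nu, mu = nu, E_B = Inf, alpha = Inf)
  cfg <- new_scenario_config(geometry, "jis", list(delta_T = delta_T), rates,
                             supply, per_bond = per_bond,
                             yield_reference = match.arg(yield_reference))
  cfg$ramp <- ramp
  cfg
}

#' Perturb a supply schedule with extrinsic noise
#'
#' Multiplies each species' copy number by an independent factor
#' `1 + epsilon`, `epsilon ~ Normal(0, cv)`, rounding to the nearest
#' nonnegative integer. Models batch-to-batch pipetting/concentration noise
#' with a given coefficient of variation.
#'
#' @param schedule A supply schedule data frame (columns `time`, `species`,
#'   `copies`, `alpha`) or a `"scenario_config"` (perturbed in place,
#'   including its yield reference).
#' @param cv Coefficient of variation (`>= 0`); `cv = 0` returns the input
#'   unchanged.
#' @return The perturbed schedule or config. Uses R's RNG.
#' @export
apply_supply_noise <- function(schedule, cv) {
  if (length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("`cv` must be a nonnegative coefficient of variation")
  is_config <- inherits(schedule, "scenario_config")
  sup <- if (is_config) schedule$supply else schedule
  if (cv > 0) {
    species <- sort(unique(sup$species))
    fac <- setNames(1 + rnorm(length(species), 0, cv), species)
    sup$copies <- as.integer(pmax(0, round(sup$copies * fac[as.character(sup$species)])))
  }
  if (!is_config) return(sup)
  schedule$supply <- sup
  if (schedule$yield_reference == "min_supplied") {
    supplied <- vapply(seq_len(schedule$geometry$S), function(s)
      sum(sup$copies[sup$species == s]), numeric(1))
    schedule$reference_count <- as.integer(max(1, min(supplied)))
  }
  schedule
}

#' Ordered supply batches of a config
#'
#' @param config A `"scenario_config"`.
#' @return A data frame `batch`, `time`, `species`, `copies`.
#' @export
supply_batches <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sup <- config$supply[order(config$supply$time, config$supply$species), ]
  times <- sort(unique(sup$time))
  data.frame(batch = match(sup$time, times), time = sup$time,
             species = sup$species, copies = sup$copies, row.names = NULL)
}
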