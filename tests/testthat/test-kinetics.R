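test_that("propensity tables match the stated rate expressions", {
  # S = 2, active = (N, N), V = N/C: one compatible pair, total = mu * N * C
  g2 <- geo1d(2)
  st <- new_assembly_state(g2, active = 100L)
  r <- rate_constants(N = 100, C = 2, mu = 0.5)
  tab <- compute_propensities(st, r)
  expect_equal(nrow(tab$dimerization), 1)
  expect_equal(tab$total, 0.5 * 100 * 2)

  # a 1D cluster (not ring-closing) grows at exactly its two ends, b = 1
  g <- geo1d(5)
  st5 <- new_assembly_state(g, active = 3L)
  st5 <- apply_event(st5, ev_dimerize(2, 3))
  tab5 <- compute_propensities(st5, rate_constants(N = 3))
  expect_equal(nrow(tab5$attachment), 2)
  expect_equal(sort(tab5$attachment$site), c(1, 4))
  expect_true(all(tab5$attachment$b == 1))

  # ring-closing vacancy has b = 2: per-bond weight 2, per-vacancy weight 1
  st5 <- apply_event(st5, ev_attach(1, 4))
  st5 <- apply_event(st5, ev_attach(1, 5))
  tabb <- compute_propensities(st5, rate_constants(N = 3))
  tabv <- compute_propensities(st5, rate_constants(N = 3), per_bond = FALSE)
  closing_b <- tabb$attachment[tabb$attachment$site == 1, ]
  closing_v <- tabv$attachment[tabv$attachment$site == 1, ]
  expect_equal(closing_b$propensity / closing_v$propensity, 2)

  # empty pools and no clusters: absorbing state, total = 0
  st0 <- new_assembly_state(g, active = 0L)
  expect_equal(compute_propensities(st0, rate_constants(N = 1))$total, 0)

  # detachment entries all zero when E_B = Inf, Arrhenius otherwise
  str_ <- new_assembly_state(g, active = 2L)
  str_ <- apply_event(str_, ev_dimerize(1, 2))
  tabr <- compute_propensities(str_, rate_constants(N = 2, E_B = 5))
  expect_equal(sum(tabr$detachment$propensity), 2 * 1e18 * exp(-5))
  tabi <- compute_propensities(str_, rate_constants(N = 2))
  expect_equal(nrow(tabi$detachment), 0)
})

test_that("propensity totals agree with brute-force event enumeration", {
  # oracle: enumerate every feasible event directly from the definitions
  brute_total <- function(state, rates) {
    g <- state$geometry
    a <- state$active
    tot <- 0
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      tot <- tot + rates$mu * a[i] * a[j] / rates$V
    }
    for (cl in state$clusters) {
      vac <- setdiff(seq_len(g$S), cl$members)
      for (s in vac) {
        b <- sum(neighbors(g, s) %in% cl$members)
        if (b > 0) tot <- tot + b * rates$nu * a[s] / rates$V
      }
      if (is.finite(rates$E_B)) {
        rm_ <- removable_members(g, cl$members)
        tot <- tot + sum(rates$A * exp(-rm_$n * rates$E_B))
      }
    }
    tot
  }
  set.seed(99)
  g <- geo2d(3)
  rates <- rate_constants(N = 5, C = 1, mu = 0.7, E_B = 3)
  st <- new_assembly_state(g, active = 2L)
  for (step in 1:40) {
    tab <- compute_propensities(st, rates)
    expect_equal(tab$total, brute_total(st, rates), tolerance = 1e-12)
    ev <- random_feasible_event(st, rates)
    if (is.null(ev)) break
    st <- apply_event(st, ev)
  }
})

test_that("compiled engine and reference implementation agree on initial propensities", {
  for (cfg in list(make_dimerization(geo1d(8), 0.3, N = 50),
                   make_reversible(geo2d(3), 6, N = 20),
                   make_activation(geo1d(8), 0.1, N = 40))) {
    res <- run_simulation(cfg, seed = 1, max_events = 0)
    rates <- rate_constants(cfg$N, cfg$C, cfg$nu, cfg$mu, cfg$E_B, cfg$alpha)
    active0 <- if (cfg$scenario == "activation") 0L else as.integer(cfg$N)
    st <- new_assembly_state(cfg$geometry, active = active0,
                             unsupplied = if (cfg$scenario == "activation")
                               as.integer(cfg$N) else 0L)
    tab <- compute_propensities(st, rates, supply = cfg$supply)
    expect_equal(sum(res$initial_propensity), tab$total, tolerance = 1e-12)
    expect_equal(unname(res$initial_propensity["dimerization"]),
                 sum(tab$dimerization$propensity), tolerance = 1e-12)
    expect_equal(unname(res$initial_propensity["influx"]),
                 sum(tab$influx$propensity), tolerance = 1e-12)
  }
})

test_that("ssa_step samples waiting times and events with the right law", {
  g <- geo1d(3)
  st <- new_assembly_state(g, active = c(1L, 3L, 3L))
  r <- rate_constants(N = 3, C = 1, mu = 1)
  tab <- compute_propensities(st, r)
  # pair propensities a_i * a_j / V: (1,2) -> 3, (2,3) -> 9, (1,3) -> 3
  expect_equal(sort(tab$dimerization$propensity * r$V), c(3, 3, 9))

  set.seed(123)
  n <- 4000
  taus <- numeric(n)
  hit23 <- logical(n)
  for (k in seq_len(n)) {
    s <- ssa_step(st, tab)
    taus[k] <- s$tau
    hit23[k] <- s$event$i == 2 && s$event$j == 3
  }
  # mean waiting time = 1 / total within 5 sigma
  expect_equal(mean(taus), 1 / tab$total,
               tolerance = 5 / sqrt(n))
  # event (2,3) selected with frequency 9/15 within 5 sigma
  p <- 9 / 15
  expect_lt(abs(mean(hit23) - p), 5 * sqrt(p * (1 - p) / n))
})

test_that("ssa_step truncates at a supply boundary without firing an event", {
  g <- geo1d(3)
  st <- new_assembly_state(g, active = 1L)
  tab <- compute_propensities(st, rate_constants(N = 1, mu = 1e-9))
  set.seed(1)
  s <- ssa_step(st, tab, next_boundary = 0.5)
  expect_null(s$event)
  expect_equal(s$tau, 0.5)
  expect_error(ssa_step(st, list(total = 0)), "absorbing")
})

test_that("simulations are reproducible and respect stochastic ordering", {
  cfg <- make_dimerization(geo1d(12), 5e-2, N = 200)
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$t90, b$t90)
  c_ <- run_simulation(cfg, seed = 8)
  expect_false(identical(a$trajectory$t, c_$trajectory$t))

  # irreversible runs: completed count and clusters+completed nondecreasing
  tr <- a$trajectory
  expect_true(all(diff(tr$completed) >= 0))
  expect_true(all(diff(tr$completed + tr$n_clusters) >= -1e-9))
})

test_that("the S = 2 stochastic assembly matches the closed form T90 = 9/(mu C)", {
  cfg <- make_dimerization(geo1d(2), 1, N = 1e4)
  t90 <- mean(sapply(1:3, function(s)
    run_simulation(cfg, seed = s, stop_on_target = TRUE)$t90))
  expect_equal(t90, 9, tolerance = 0.05)
})

test_that("deep kinetic traps censor the run rather than erroring", {
  # mu = nu at S = 64: yield collapses far below 0.9
  cfg <- make_dimerization(geo1d(64), 1, N = 200)
  res <- run_simulation(cfg, seed = 2, stop_on_target = TRUE)
  expect_false(res$reached_target)
  expect_lt(res$final_yield, 0.2)
})

test_that("attach/detach at a single vacancy balances to the expected odds", {
  # cluster = L-tromino on a 3x3 sheet; toggling the corner vacancy between
  # occupied (rate 2 nu a/V) and detached (rate delta_2) is a two-state
  # chain: long-run occupation odds must equal the rate ratio (within 3 sigma)
  g <- geo2d(3)
  EB <- 1.5
  rates <- rate_constants(N = 10, E_B = EB, nu = 1e-18 * exp(-2 * EB) / 2)
  # nu chosen so both rates are comparable: ka = 2 nu a / V, kd = A e^{-2 EB}
  st <- new_assembly_state(g, active = 10L)
  st <- apply_event(st, ev_dimerize(site_at(g, 0, 0), site_at(g, 0, 1)))
  st <- apply_event(st, ev_attach(1, site_at(g, 1, 0)))
  corner <- site_at(g, 1, 1)
  # attach rate from the propensity table of the vacant configuration
  tab_empty <- compute_propensities(st, rates)
  ka <- tab_empty$attachment$propensity[tab_empty$attachment$site == corner]
  expect_equal(ka, 2 * rates$nu * st$active[corner] / rates$V)
  # detach rate from the table of the occupied configuration
  st_occ <- apply_event(st, ev_attach(1, corner))
  tab_occ <- compute_propensities(st_occ, rates)
  kd <- tab_occ$detachment$propensity[tab_occ$detachment$site == corner]
  expect_equal(kd, detachment_rate(2, rates))
  set.seed(31)
  occupied_time <- empty_time <- 0
  occ <- FALSE
  for (k in 1:4000) {
    if (occ) {
      occupied_time <- occupied_time + rexp(1, kd)
      occ <- FALSE
    } else {
      empty_time <- empty_time + rexp(1, ka)
      occ <- TRUE
    }
  }
  odds_sim <- occupied_time / empty_time
  odds_th <- ka / kd
  expect_equal(odds_sim, odds_th, tolerance = 3 * sqrt(2 / 2000))
})
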