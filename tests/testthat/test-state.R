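test_that("bond counts at vacancies", {
  g <- geo2d(3)
  dimer <- c(site_at(g, 0, 0), site_at(g, 0, 1))
  expect_equal(bond_count(g, dimer, site_at(g, 1, 0)), 1)
  tromino <- c(site_at(g, 0, 0), site_at(g, 0, 1), site_at(g, 1, 0))
  expect_equal(bond_count(g, tromino, site_at(g, 1, 1)), 2)
  # 8-cell ring around the centre of a 3x3 sheet: centre vacancy has 4 bonds
  ring8 <- setdiff(seq_len(9), site_at(g, 1, 1))
  expect_equal(bond_count(g, ring8, site_at(g, 1, 1)), 4)
  expect_error(bond_count(g, dimer, site_at(g, 0, 0)), "occupied")
})

test_that("removable members are the non-articulation members", {
  # 1D chain of 5 inside a ring of 8: exactly the two ends, n = 1
  g8 <- geo1d(8)
  rm1 <- removable_members(g8, 2:6)
  expect_equal(rm1$site, c(2, 6))
  expect_equal(rm1$n, c(1, 1))

  g <- geo2d(3)
  # 2x2 block: every corner removable with n = 2
  block <- c(site_at(g, 0, 0), site_at(g, 1, 0), site_at(g, 0, 1), site_at(g, 1, 1))
  rm2 <- removable_members(g, block)
  expect_equal(sort(rm2$site), sort(block))
  expect_true(all(rm2$n == 2))

  # L-tromino: the two arm tips (n = 1); the corner is a cut vertex
  tromino <- c(site_at(g, 0, 0), site_at(g, 0, 1), site_at(g, 1, 0))
  rm3 <- removable_members(g, tromino)
  expect_equal(sort(rm3$site), sort(c(site_at(g, 0, 1), site_at(g, 1, 0))))
  expect_true(all(rm3$n == 1))

  # a dimer: both members, n = 1
  rm4 <- removable_members(g8, c(3, 4))
  expect_equal(rm4$n, c(1, 1))
})

test_that("event application keeps exact books", {
  g <- geo1d(3)
  st <- new_assembly_state(g, active = 10L)

  st <- apply_event(st, ev_dimerize(1, 2))
  expect_equal(st$active, c(9L, 9L, 10L))
  expect_length(st$clusters, 1)
  expect_equal(mass_balance(st), c(0L, 0L, 0L))

  # attach completing the S = 3 ring removes the cluster and counts it
  st <- apply_event(st, ev_attach(1, 3))
  expect_equal(st$completed, 1L)
  expect_length(st$clusters, 0)
  expect_equal(mass_balance(st), c(0L, 0L, 0L))
  expect_equal(yield_of(st, 10), 0.1)

  # detach from a 2-member cluster dissolves it into two free monomers
  st <- apply_event(st, ev_dimerize(2, 3))
  st <- apply_event(st, ev_detach(1, 2))
  expect_length(st$clusters, 0)
  expect_equal(st$active, c(9L, 9L, 9L))

  # a ring-closing attach on S = 4 increments completed
  g4 <- geo1d(4)
  st4 <- new_assembly_state(g4, active = 2L)
  st4 <- apply_event(st4, ev_dimerize(1, 2))
  st4 <- apply_event(st4, ev_attach(1, 3))
  st4 <- apply_event(st4, ev_attach(1, 4))
  expect_equal(st4$completed, 1L)
  expect_length(st4$clusters, 0)

  # dimerization on the degenerate S = 2 ring is immediately complete
  g2 <- geo1d(2)
  st2 <- new_assembly_state(g2, active = 5L)
  st2 <- apply_event(st2, ev_dimerize(1, 2))
  expect_equal(st2$completed, 1L)
  expect_length(st2$clusters, 0)

  # influx moves monomers from the unsupplied to the active pool
  st5 <- new_assembly_state(g, active = 0L, unsupplied = 4L)
  st5 <- apply_event(st5, ev_influx(2, 3))
  expect_equal(st5$active[2], 3L)
  expect_equal(st5$unsupplied[2], 1L)
  expect_equal(mass_balance(st5), c(0L, 0L, 0L))
})

test_that("infeasible events are rejected with the violated precondition", {
  g <- geo1d(6)
  st <- new_assembly_state(g, active = c(1L, 1L, 0L, 1L, 1L, 1L))
  expect_error(apply_event(st, ev_dimerize(1, 3)), "not compatible")
  expect_error(apply_event(st, ev_dimerize(3, 4)), "no free active monomer")
  st <- apply_event(st, ev_dimerize(1, 2))
  expect_error(apply_event(st, ev_attach(1, 4)), "not adjacent")
  expect_error(apply_event(st, ev_attach(1, 2)), "already occupied")
  st <- apply_event(st, ev_attach(1, 6))           # cluster now {6, 1, 2}
  expect_error(apply_event(st, ev_detach(1, 1)), "not a removable member")
  expect_error(apply_event(st, ev_influx(1, 1)), "unsupplied")
  expect_error(apply_event(st, list(type = "merge")), "unknown event type")
})

test_that("yield_of validates its reference", {
  st <- new_assembly_state(geo1d(3), active = 1L)
  expect_equal(yield_of(st, 100), 0)
  expect_error(yield_of(st, 0), "positive")
  expect_error(yield_of(st, -2), "positive")
})

test_that("fuzzed event sequences conserve mass and connectivity exactly", {
  set.seed(42)
  g <- geo2d(3)
  rates <- rate_constants(N = 6, E_B = 2)  # reversible: detach events occur
  supply <- data.frame(time = 0, species = seq_len(g$S), copies = 2L,
                       alpha = 1)
  for (rep in 1:5) {
    st <- new_assembly_state(g, active = 4L, unsupplied = 2L)
    for (step in 1:60) {
      ev <- random_feasible_event(st, rates, supply)
      if (is.null(ev)) break
      n_before <- length(st$clusters)
      st <- apply_event(st, ev)
      # exact per-species balance after every event
      expect_equal(mass_balance(st), rep(0L, g$S))
      # connectivity after every event; a detach never splits a cluster
      for (cl in st$clusters)
        expect_true(cluster_connected(g, cl$members))
      if (ev$type == "detach")
        expect_lte(length(st$clusters), n_before)
    }
  }
})
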