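zero_model <- function() interaction_model(rep(0, 10))

test_that("interfacial cell listing excludes buried cells and materials", {
  lat <- tme_lattice(c(9, 9, 9))
  expect_equal(nrow(identify_interfacial_cells(lat)), 0L)

  # solid 3x3x3 cancer block in medium: all but the center are interfacial
  block <- as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5))
  lat <- lattice_set(lat, block, 3)
  set.seed(1)
  cells <- identify_interfacial_cells(lat)
  expect_equal(nrow(cells), 26L)
  expect_false(any(cells$x == 4 & cells$y == 4 & cells$z == 4))

  # at seeding density 1e-3 essentially every cell is isolated, so listed
  set.seed(2)
  con <- build_toroidal(scale = 1 / 4)
  listed <- identify_interfacial_cells(con)
  expect_gte(nrow(listed), 0.99 * sum(con$types %in% 2:3))
})

test_that("proliferation copies the mother into a uniformly chosen free neighbor", {
  lat <- tme_lattice(c(7, 7, 7), fill = 1)
  lat <- lattice_set(lat, c(3, 3, 3), 2)
  set.seed(4)
  out <- attempt_proliferation(lat, c(3, 3, 3))
  expect_equal(out$outcome$kind, "proliferation")
  d <- c(out$outcome$partner_x, out$outcome$partner_y, out$outcome$partner_z)
  expect_equal(max(abs(d - c(3, 3, 3))), 1)        # daughter is adjacent
  expect_equal(site_type(out$lattice, d), 2L)
  expect_equal(sum(out$lattice$types == 1), 7L^3L - 2L)  # one hydrogel replaced
  expect_equal(sum(out$lattice$types == 2), 2L)
  expect_true(is.na(out$outcome$delta_e))          # no Metropolis test applies

  # a cell walled in by other cells cannot divide
  lat2 <- tme_lattice(c(7, 7, 7), fill = 2)
  lat2 <- lattice_set(lat2, c(3, 3, 3), 3)
  out2 <- attempt_proliferation(lat2, c(3, 3, 3))
  expect_equal(out2$outcome$kind, "skipped")
  expect_identical(out2$lattice$types, lat2$types)

  expect_error(attempt_proliferation(lat, c(0, 0, 0)), "cell")
})

test_that("the daughter site is chosen uniformly among eligible neighbors", {
  # mother with a mixed shell: 13 hydrogel + 13 medium neighbors
  lat <- tme_lattice(c(7, 7, 7), fill = 0)
  off <- neighbor_offsets()
  shell <- sweep(off, 2, c(3L, 3L, 3L), "+")
  lat <- lattice_set(lat, shell[1:13, ], 1)
  lat <- lattice_set(lat, c(3, 3, 3), 3)
  set.seed(9)
  n <- 26000
  tally <- integer(26)
  for (i in seq_len(n)) {
    out <- attempt_proliferation(lat, c(3, 3, 3))
    d <- c(out$outcome$partner_x, out$outcome$partner_y, out$outcome$partner_z)
    k <- which(shell[, 1] == d[1] & shell[, 2] == d[2] & shell[, 3] == d[3])
    tally[k] <- tally[k] + 1L
  }
  p <- 1 / 26
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(tally / n - p) < 4 * se))
})

test_that("trial moves respect partner eligibility and the Metropolis rule", {
  # zero-energy model: every proposal has dE = 0 and is always accepted
  lat <- tme_lattice(c(7, 7, 7), fill = 1)
  lat <- lattice_set(lat, c(3, 3, 3), 3)
  set.seed(14)
  for (i in 1:20) {
    out <- attempt_move(lat, c(3, 3, 3), zero_model())
    expect_equal(out$outcome$kind, "move-accepted")
    expect_equal(out$outcome$delta_e, 0)
  }

  # peritumoral cell whose only different-type neighbors are cancer: stuck
  lat2 <- tme_lattice(c(7, 7, 7), fill = 2)
  lat2 <- lattice_set(lat2, neighbor_offsets() + 3L, 3)
  lat2 <- lattice_set(lat2, c(3, 3, 3), 2)
  out2 <- attempt_move(lat2, c(3, 3, 3), zero_model())
  expect_equal(out2$outcome$kind, "skipped")

  # a cancer cell in the same geometry may swap with the type-2 shell
  lat3 <- tme_lattice(c(7, 7, 7), fill = 3)
  lat3 <- lattice_set(lat3, neighbor_offsets() + 3L, 2)
  lat3 <- lattice_set(lat3, c(3, 3, 3), 3)
  out3 <- attempt_move(lat3, c(3, 3, 3), zero_model())
  expect_true(out3$outcome$kind %in% c("move-accepted", "move-rejected"))

  expect_error(attempt_move(lat, c(0, 0, 0), zero_model()), "cell")
})

test_that("a two-state cell reaches the Boltzmann occupancy ratio", {
  # mobile peritumoral cell hopping between a site next to a cancer anchor
  # and one farther away; stationary ratio must be exp(-(E2 - E1) / ET)
  m <- interaction_model(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2), ET = 1)  # eps23 = 2
  lat <- tme_lattice(c(9, 9, 9), fill = 1)
  lat <- lattice_set(lat, c(2, 4, 4), 3)       # anchor
  s1 <- c(3, 4, 4)                             # adjacent to the anchor
  s2 <- c(4, 4, 4)
  lat1 <- lattice_set(lat, s1, 2)
  dE12 <- delta_energy_swap(lat1, s1, s2, m)   # E(s2) - E(s1) = eps23 = 2
  expect_equal(dE12, 2)
  set.seed(77)
  cur <- 1L
  occ <- c(0L, 0L)
  latc <- lat1
  for (i in 1:20000) {
    from <- if (cur == 1L) s1 else s2
    to <- if (cur == 1L) s2 else s1
    d <- delta_energy_swap(latc, from, to, m)
    if (metropolis_accept(d, m$ET)) {
      latc <- lattice_set(lattice_set(latc, to, 2), from, 1)
      cur <- 3L - cur
    }
    occ[cur] <- occ[cur] + 1L
  }
  expect_equal(occ[2] / occ[1], exp(-dE12), tolerance = 0.1)
})

test_that("sweeps conserve matter and composition under moves alone", {
  set.seed(21)
  lat <- build_toroidal(scale = 1 / 6, phi = c(tumor = 0.02, peritumoral = 0.02))
  res <- run_mcs(lat, zero_model(),
                 simulation_params(p2 = 0, p3 = 0, metrics_interval = 10),
                 n_mcs = 50)
  tr <- res$trajectory
  expect_true(all(tr$N0 + tr$N1 + tr$N2 + tr$N3 == prod(lat$dims)))
  expect_true(all(tr$N2 == tr$N2[1]))
  expect_true(all(tr$N3 == tr$N3[1]))
  expect_true(all(tr$E_total == 0))            # zero-energy model
  expect_true(all(tr$ev_move_rejected == 0))   # dE = 0 proposals always accepted
})

test_that("proliferation tallies follow the Bernoulli thinning of events", {
  set.seed(33)
  lat <- build_toroidal(scale = 1 / 3)
  p <- 0.01
  res <- run_mcs(lat, set1_model(),
                 simulation_params(p2 = p, p3 = p, metrics_interval = 1,
                                   validate = FALSE),
                 n_mcs = 100)
  tr <- res$trajectory
  ncells <- tr$N2 + tr$N3
  expected <- p * sum(ncells[-length(ncells)])   # listed cells per sweep
  got <- sum(tr$ev_proliferation)
  sdev <- sqrt(p * (1 - p) * sum(ncells[-length(ncells)]))
  expect_lt(abs(got - expected), 4 * sdev)
  # growth conserves sites: cells gained = materials lost
  expect_equal(tr$N2 + tr$N3 - ncells[1],
               (tr$N0[1] + tr$N1[1]) - (tr$N0 + tr$N1))
})

test_that("identical seeds give bit-identical trajectories and lattices", {
  set.seed(55); lat <- build_toroidal(scale = 1 / 6)
  params <- simulation_params(n_mcs = 300, seed = 123, metrics_interval = 50)
  a <- run_simulation(lat, "set1", params)
  b <- run_simulation(lat, "set1", params)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$lattice$types, b$lattice$types)
  expect_identical(a$rng_state, b$rng_state)
})

test_that("a snapshot-resumed run equals the uninterrupted run exactly", {
  set.seed(56); lat <- build_toroidal(scale = 1 / 6)
  full <- run_simulation(lat, "set2",
                         simulation_params(n_mcs = 400, seed = 9,
                                           metrics_interval = 100))

  half <- run_simulation(lat, "set2",
                         simulation_params(n_mcs = 200, seed = 9,
                                           metrics_interval = 100))
  # via an on-disk site-list snapshot carrying the RNG state
  snap <- withr::local_tempfile(fileext = ".txt")
  write_site_list(half$lattice, snap, rng_state = half$rng_state)
  reloaded <- set_region(read_site_list(snap), lat)
  resumed <- run_simulation(reloaded, "set2",
                            simulation_params(n_mcs = 200, seed = NULL,
                                              metrics_interval = 100),
                            rng_state = attr(reloaded, "rng_state"))
  expect_identical(resumed$lattice$types, full$lattice$types)
  expect_equal(resumed$lattice$mcs, 400L)
  merged <- rbind(half$trajectory, resumed$trajectory[-1, ])
  expect_equal(merged, full$trajectory)
})

test_that("running energy bookkeeping matches a fresh recomputation", {
  set.seed(60)
  lat <- build_toroidal(scale = 1 / 6, phi = c(tumor = 0.01, peritumoral = 0.01))
  m <- set1_model()
  sim <- run_simulation(lat, m,
                        simulation_params(n_mcs = 1000, seed = 3,
                                          metrics_interval = 100,
                                          validate = TRUE))
  last <- sim$trajectory[nrow(sim$trajectory), ]
  fresh <- total_energy(sim$lattice, m)
  expect_equal(last$E_total, fresh$E_total, tolerance = 1e-12)
  expect_equal(last$E_interfacial, fresh$E_interfacial, tolerance = 1e-12)
  rel_drift <- abs(last$E_total - fresh$E_total) /
    max(1, abs(fresh$E_total))
  expect_lt(rel_drift, 1e-6)
})

test_that("the engine refuses biomaterial occupants", {
  lat <- lattice_set(tme_lattice(c(6, 6, 6)), c(2, 2, 2), 4)
  expect_error(run_simulation(lat, "set1", simulation_params(n_mcs = 1)),
               "type 4")
})
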