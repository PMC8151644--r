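test_that("sphere rasterization matches the lattice-distance definition", {
  expect_equal(nrow(rasterize_sphere(c(5, 5, 5), 0.5, c(11, 11, 11))), 1L)
  s <- rasterize_sphere(c(5, 5, 5), 1, c(11, 11, 11))
  expect_equal(nrow(s), 7L)  # center + the 6 face neighbors
  expect_true(all(sqrt(rowSums(sweep(s, 2, c(5, 5, 5))^2)) <= 1 + 1e-9))
  expect_error(rasterize_sphere(c(2, 5, 5), 3, c(11, 11, 11)), "bounds")
  expect_error(rasterize_sphere(c(5, 5, 5), 0, c(11, 11, 11)), "positive")
})

test_that("torus rasterization matches brute-force enumeration", {
  dims <- c(13, 13, 7)
  ctr <- c(6, 6, 3)
  tor <- rasterize_torus(ctr, R = 3, r = 1, axis = "z", dims)
  g <- as.matrix(expand.grid(x = 0:12, y = 0:12, z = 0:6))
  d2 <- (sqrt((g[, 1] - 6)^2 + (g[, 2] - 6)^2) - 3)^2 + (g[, 3] - 3)^2
  expect_equal(nrow(tor), sum(d2 <= 1 + 1e-12))

  # a thin loop stays within pipe distance of the centerline circle
  loop <- rasterize_torus(c(8, 8, 3), R = 5, r = 0.5, axis = "z", c(17, 17, 7))
  cd <- sqrt((sqrt((loop[, 1] - 8)^2 + (loop[, 2] - 8)^2) - 5)^2 +
               (loop[, 3] - 3)^2)
  expect_true(all(cd <= 0.5 + 1e-9))

  expect_error(rasterize_torus(ctr, R = 1, r = 2, axis = "z", dims), "R >= r")
  expect_error(rasterize_torus(ctr, R = 6, r = 1, axis = "z", dims), "bounds")
})

test_that("rasterized volumes follow the cubic scaling law", {
  dims <- c(95, 95, 41)
  ctr <- c(47, 47, 20)
  n_half <- nrow(rasterize_sphere(ctr, 15, dims))
  n_sixth <- nrow(rasterize_sphere(ctr, 5, dims))
  expect_lt(abs(n_sixth / n_half - (1 / 3)^3), 0.05 * (1 / 3)^3)

  t_half <- nrow(rasterize_torus(ctr, 30, 15, "z", dims))
  t_sixth <- nrow(rasterize_torus(ctr, 10, 5, "z", dims))
  expect_lt(abs(t_sixth / t_half - (1 / 3)^3), 0.05 * (1 / 3)^3)
})

test_that("the toroidal construct partitions into disjoint labeled zones", {
  set.seed(31)
  lat <- build_toroidal(scale = 1 / 6)
  expect_true(all(lat$region %in% 0:2))
  # construct material is hydrogel-or-cell exactly on the non-medium zones
  expect_equal(lat$types != 0, lat$region != 0)
  # cells sit only in their own zone
  expect_true(all(lat$region[lat$types == 3] == 1))
  expect_true(all(lat$region[lat$types == 2] == 2))
  # the medium margin keeps construct material >= 2 sites off the boundary
  d <- lat$dims
  shell <- lat$types
  shell[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- 0L
  expect_true(all(shell == 0L))
  # zone volumes track the continuum solids at this scale
  expect_lt(abs(sum(lat$region == 1) - 4 / 3 * pi * 5^3), 0.05 * 4 / 3 * pi * 5^3)
  expect_lt(abs(sum(lat$region == 2) - 2 * pi^2 * 10 * 25),
            0.05 * 2 * pi^2 * 10 * 25)
})

test_that("construct building is deterministic given the seed", {
  set.seed(99); a <- build_toroidal(scale = 1 / 6)
  set.seed(99); b <- build_toroidal(scale = 1 / 6)
  expect_identical(a$types, b$types)
  expect_identical(a$region, b$region)
  expect_identical(a$seeded, b$seeded)
})

test_that("Bernoulli seeding has the right edge cases and statistics", {
  set.seed(8)
  lat0 <- build_toroidal(scale = 1 / 4, phi = c(tumor = 0, peritumoral = 0))
  expect_equal(sum(lat0$types %in% 2:3), 0L)
  expect_equal(unname(lat0$seeded), c(0L, 0L))

  full <- seed_cells(lat0, "tumor", 3, 1)
  expect_equal(sum(full$types == 3), sum(full$region == 1))

  expect_error(seed_cells(lat0, "tumor", 3, 1.5), "\\[0, 1\\]")
  expect_error(seed_cells(lat0, "tumor", 1, 0.1), "cell_type")

  # repeated seeding of the tumor zone behaves binomially
  n_zone <- sum(lat0$region == 1)
  phi <- 0.01
  counts <- replicate(200, sum(seed_cells(lat0, "tumor", 3, phi)$types == 3))
  expect_lt(abs(mean(counts) - phi * n_zone),
            3 * sqrt(phi * (1 - phi) * n_zone / 200))
  v <- var(counts)
  expect_gt(v, 0.5 * phi * (1 - phi) * n_zone)
  expect_lt(v, 1.6 * phi * (1 - phi) * n_zone)
})

test_that("triple-layered construct is the union of its tubes minus the sphere", {
  set.seed(12)
  sc <- 1 / 6
  lat <- build_triple_layered(scale = sc, phi = c(tumor = 0, peritumoral = 0))
  d <- lat$dims
  ctr <- (d - 1) / 2
  g <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1)))
  rho <- sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2)
  in_sphere <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2 <=
    (30 * sc)^2 + 1e-12
  tube <- function(R, zoff) {
    (rho - R)^2 + (g[, 3] - ctr[3] - zoff)^2 <= (30 * sc)^2 + 1e-12
  }
  spec <- default_layer_spec(sc)
  in_tube <- tube(60 * sc, 0)
  for (i in seq_len(nrow(spec))) in_tube <- in_tube | tube(spec$R[i], spec$z_offset[i])
  expect_equal(sum(lat$region == 1), sum(in_sphere))
  expect_equal(sum(lat$region == 2), sum(in_tube & !in_sphere))
  expect_equal(sum(lat$types == 1), sum(in_tube | in_sphere))
})

test_that("layer rings that collide with the tumor sphere are rejected", {
  bad <- tibble::tibble(z_offset = 0, R = 30 * (1 / 6))
  expect_error(build_triple_layered(scale = 1 / 6, layer_spec = bad),
               "collides")
})

test_that("builders enforce scale and margin preconditions", {
  expect_error(build_toroidal(scale = 0), "scale")
  expect_error(build_toroidal(scale = 2), "scale")
  expect_error(build_toroidal(scale = 0.5, margin = 1), "margin")
  expect_error(build_toroidal(scale = 0.5, phi = c(bad = 1)), "phi")
})
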