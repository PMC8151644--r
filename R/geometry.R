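#' Rasterize a sphere onto the lattice
#'
#' Returns every integer site whose Euclidean distance from `center` is at
#' most `radius`. At realistic (1:1) scale the tumor spheroid is a sphere of
#' diameter 60 sites (0.6 mm at 10 um per cell diameter).
#'
#' @param center Real coordinate triple (0-based lattice frame).
#' @param radius Sphere radius, > 0 (sites; 1 site = 1 cell diameter).
#' @param dims Lattice dimensions `c(Lx, Ly, Lz)`.
#' @return An `n x 3` integer matrix of 0-based sites.
#' @examples
#' rasterize_sphere(c(5, 5, 5), 1, c(11, 11, 11))  # center + 6 face neighbors
#' @export
rasterize_sphere <- function(center, radius, dims) {
  if (radius <= 0) abort("`radius` must be positive.")
  if (any(center - radius < 0) || any(center + radius > dims - 1)) {
    abort("sphere exceeds the lattice bounds.")
  }
  lo <- floor(center - radius); hi <- ceiling(center + radius)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  sites <- g[d2 <= radius^2 + 1e-12, , drop = FALSE]
  storage.mode(sites) <- "integer"
  dimnames(sites) <- NULL
  sites
}

#' Rasterize a torus onto the lattice
#'
#' Returns the integer sites inside the torus with major radius `R` and pipe
#' radius `r`: in the torus' local frame (symmetry axis = local z),
#' `(sqrt(u^2 + v^2) - R)^2 + w^2 <= r^2`. The bioprinted hydrogel rings are
#' tori whose pipe diameter equals the extruded thread diameter (60 sites at
#' realistic scale).
#'
#' @param center Real coordinate triple of the torus center.
#' @param R Major radius (centerline circle), `R >= r`.
#' @param r Pipe radius, > 0.
#' @param axis Symmetry axis, one of `"x"`, `"y"`, `"z"`.
#' @param dims Lattice dimensions.
#' @return An `n x 3` integer matrix of 0-based sites.
#' @export
rasterize_torus <- function(center, R, r, axis = "z", dims) {
  if (r <= 0 || R < r) abort("need R >= r > 0.")
  axis <- match.arg(axis, c("x", "y", "z"))
  ax <- match(axis, c("x", "y", "z"))
  ip <- setdiff(1:3, ax)  # in-plane axes
  half <- numeric(3); half[ip] <- R + r; half[ax] <- r
  if (any(center - half < 0) || any(center + half > dims - 1)) {
    abort("torus exceeds the lattice bounds.")
  }
  lo <- floor(center - half); hi <- ceiling(center + half)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  u <- g[, ip[1]] - center[ip[1]]
  v <- g[, ip[2]] - center[ip[2]]
  w <- g[, ax] - center[ax]
  d2 <- (sqrt(u^2 + v^2) - R)^2 + w^2
  sites <- g[d2 <= r^2 + 1e-12, , drop = FALSE]
  storage.mode(sites) <- "integer"
  dimnames(sites) <- NULL
  sites
}

#' Seed cells into a hydrogel zone
#'
#' Each hydrogel site of the zone independently becomes a cell of
#' `cell_type` with probability `phi` (Bernoulli seeding; realized counts
#' scatter binomially around `phi * n`). A volume fraction of 1e-3
#' reproduces the experimental density of 1e6 cells/mL: one cell-sized
#' volume element in a thousand. Sites are visited in canonical (z, y, x)
#' order; draws use R's RNG, so results are reproducible under [set.seed()].
#'
#' @param lattice A [tme_lattice()] with region labels.
#' @param zone `"tumor"` or `"peritumoral"` (initial-geometry region).
#' @param cell_type Particle type to seed (3 cancer, 2 peritumoral).
#' @param phi Volume fraction in `[0, 1]`.
#' @return The lattice with cells seeded; the realized count is appended to
#'   `lattice$seeded`.
#' @export
seed_cells <- function(lattice, zone, cell_type, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1) {
    abort("`phi` must be a single volume fraction in [0, 1].")
  }
  code <- switch(match.arg(zone, c("tumor", "peritumoral")),
                 tumor = REGION_TUMOR, peritumoral = REGION_PERITUMORAL)
  cell_type <- as.integer(cell_type)
  if (!cell_type %in% c(TYPE_PERITUMORAL, TYPE_CANCER)) {
    abort("`cell_type` must be 2 (peritumoral) or 3 (cancer).")
  }
  idx <- which(lattice$region == code & lattice$types == TYPE_HYDROGEL)
  hit <- idx[runif(length(idx)) < phi]
  lattice$types[hit] <- cell_type
  lattice$seeded <- c(lattice$seeded,
                      setNames(length(hit), paste0("type", cell_type)))
  lattice
}

toroidal_dims <- function(scale, margin) {
  rs <- 30 * scale; rt <- 30 * scale; R <- 60 * scale
  c(2L * as.integer(ceiling(R + rt)) + 1L + 2L * margin,
    2L * as.integer(ceiling(R + rt)) + 1L + 2L * margin,
    2L * as.integer(ceiling(max(rs, rt))) + 1L + 2L * margin)
}

#' Build and seed the toroidal construct
#'
#' The printed toroidal construct is a tumor spheroid (diameter `60 * scale`
#' sites) tightly embraced by a donut-shaped hydrogel ring of the same thread
#' diameter: pipe radius `r = 30 * scale`, major radius `R = 60 * scale`, so
#' the tube is tangent to the spheroid. The spheroid takes precedence on any
#' shared site. All remaining sites are culture medium; a medium margin of at
#' least 2 sites separates the construct from the lattice boundary. Region
#' labels (tumor zone / peritumoral zone / medium) are frozen before seeding.
#' The tumor zone is then seeded with cancer cells and the ring with
#' peritumoral cells at volume fractions `phi`.
#'
#' @param scale Geometric scale in `(0, 1]`: 1 is the realistic 1:1 model
#'   (about 1.18e6 construct sites), 1/3 the reduced model.
#' @param phi Named vector `c(tumor = , peritumoral = )` of seeding volume
#'   fractions (default 1e-3 each, the experimental cell density).
#' @param margin Medium padding around the construct, >= 2 sites.
#' @return A seeded [tme_lattice()] with region labels and realized cell
#'   counts in `$seeded`.
#' @examples
#' set.seed(1)
#' lat <- build_toroidal(scale = 1 / 6)
#' lat$seeded
#' @export
build_toroidal <- function(scale = 1, phi = c(tumor = 1e-3, peritumoral = 1e-3),
                           margin = 2L) {
  if (scale <= 0 || scale > 1) abort("`scale` must be in (0, 1].")
  margin <- as.integer(margin)
  if (margin < 2L) abort("`margin` must be at least 2 sites.")
  phi <- resolve_phi(phi)
  dims <- toroidal_dims(scale, margin)
  center <- (dims - 1) / 2
  lat <- tme_lattice(dims, fill = TYPE_MEDIUM, scale = scale)

  sph <- rasterize_sphere(center, 30 * scale, dims)
  tor <- rasterize_torus(center, 60 * scale, 30 * scale, "z", dims)
  lat$region[site_index(tor, dims)] <- REGION_PERITUMORAL
  lat$region[site_index(sph, dims)] <- REGION_TUMOR  # sphere wins on overlap
  lat$types[lat$region != REGION_MEDIUM] <- TYPE_HYDROGEL

  lat$seeded <- integer(0)
  lat <- seed_cells(lat, "tumor", TYPE_CANCER, phi[["tumor"]])
  lat <- seed_cells(lat, "peritumoral", TYPE_PERITUMORAL, phi[["peritumoral"]])
  lat
}

resolve_phi <- function(phi) {
  if (length(phi) == 1L && is.null(names(phi))) {
    phi <- c(tumor = unname(phi), peritumoral = unname(phi))
  }
  if (!all(c("tumor", "peritumoral") %in% names(phi))) {
    abort("`phi` must be named c(tumor = , peritumoral = ) or a single value.")
  }
  phi
}

#' Default ring layout of the triple-layered construct
#'
#' The triple-layered construct sandwiches the toroidal construct between two
#' hydrogel layers: a pair of concentric rings at the bottom and one ring at
#' the top, all with pipe radius `30 * scale`. The layout is configurable;
#' the default nests tangent tubes (vertical offsets of about `r * sqrt(3)`,
#' the stable pyramid-like stacking of extruded threads): bottom rings of
#' major radius `30 * scale` and `90 * scale` at `z = -52 * scale`, one top
#' ring of major radius `60 * scale` at `z = +52 * scale`.
#'
#' @param scale Geometric scale.
#' @return A tibble with columns `z_offset` and `R` (one row per extra ring).
#' @export
default_layer_spec <- function(scale = 1) {
  tibble(z_offset = c(-52, -52, 52) * scale, R = c(30, 90, 60) * scale)
}

#' Build and seed the triple-layered construct
#'
#' Middle layer: the toroidal construct of [build_toroidal()]. Bottom and top
#' layers: the rings of `layer_spec` (default [default_layer_spec()]), each a
#' torus of pipe radius `30 * scale` centered on the construct axis. The
#' peritumoral zone is the set union of all tube interiors minus the tumor
#' sphere; rings other than the embracing middle ring must not collide with
#' the tumor sphere.
#'
#' @inheritParams build_toroidal
#' @param layer_spec Tibble with columns `z_offset`, `R` describing the extra
#'   rings (already at the requested scale).
#' @return A seeded [tme_lattice()].
#' @export
build_triple_layered <- function(scale = 1,
                                 layer_spec = default_layer_spec(scale),
                                 phi = c(tumor = 1e-3, peritumoral = 1e-3),
                                 margin = 2L) {
  if (scale <= 0 || scale > 1) abort("`scale` must be in (0, 1].")
  margin <- as.integer(margin)
  if (margin < 2L) abort("`margin` must be at least 2 sites.")
  phi <- resolve_phi(phi)
  rt <- 30 * scale
  half_xy <- max(60 * scale, layer_spec$R) + rt
  half_z <- max(30 * scale, abs(layer_spec$z_offset) + rt)
  dims <- c(rep(2L * as.integer(ceiling(half_xy)) + 1L + 2L * margin, 2),
            2L * as.integer(ceiling(half_z)) + 1L + 2L * margin)
  center <- (dims - 1) / 2
  lat <- tme_lattice(dims, fill = TYPE_MEDIUM, scale = scale)

  sph <- rasterize_sphere(center, 30 * scale, dims)
  sph_idx <- site_index(sph, dims)
  tube_idx <- site_index(rasterize_torus(center, 60 * scale, rt, "z", dims), dims)
  for (i in seq_len(nrow(layer_spec))) {
    ring <- rasterize_torus(center + c(0, 0, layer_spec$z_offset[i]),
                            layer_spec$R[i], rt, "z", dims)
    ridx <- site_index(ring, dims)
    if (any(ridx %in% sph_idx)) {
      abort(sprintf("layer ring %d (R = %g, z_offset = %g) collides with the tumor sphere.",
                    i, layer_spec$R[i], layer_spec$z_offset[i]))
    }
    tube_idx <- union(tube_idx, ridx)
  }
  lat$region[tube_idx] <- REGION_PERITUMORAL
  lat$region[sph_idx] <- REGION_TUMOR  # sphere wins
  lat$types[lat$region != REGION_MEDIUM] <- TYPE_HYDROGEL

  lat$seeded <- integer(0)
  lat <- seed_cells(lat, "tumor", TYPE_CANCER, phi[["tumor"]])
  lat <- seed_cells(lat, "peritumoral", TYPE_PERITUMORAL, phi[["peritumoral"]])
  lat
}
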