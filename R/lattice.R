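#' Create a cubic-lattice construct
#'
#' A `tme_lattice` is a finite 3D cubic lattice in which every site holds one
#' point particle: medium (0), hydrogel (1), a peritumoral cell (2), a cancer
#' cell (3), or biomaterial (4; accepted by I/O but never generated by the
#' simulation engine). The lattice spacing is one cell diameter (about 10 um),
#' coordinates are 0-based integer triples, and there are no periodic
#' boundaries: sites beyond the lattice are virtual medium, the convention for
#' a construct bathed in culture medium.
#'
#' A parallel `region` array records the *initial* geometry (0 medium zone,
#' 1 tumor zone, 2 peritumoral zone). It is frozen at build time and used by
#' the morphometric descriptors, which read the evolving configuration
#' relative to the printed construct.
#'
#' @param dims Integer vector `c(Lx, Ly, Lz)` of positive site counts.
#' @param fill Particle type used for every site (default medium, 0).
#' @param region Optional integer array of region labels with the same
#'   dimensions; defaults to all medium zone.
#' @param scale Geometric scale factor recorded as metadata (1 = realistic).
#' @return An object of class `tme_lattice` with fields `types` (integer
#'   array), `region` (integer array), `dims`, `scale`, and `mcs`.
#' @examples
#' lat <- tme_lattice(c(5, 5, 5), fill = 1)
#' lat
#' @export
tme_lattice <- function(dims, fill = 0L, region = NULL, scale = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    abort("`dims` must be three positive integers (Lx, Ly, Lz).")
  }
  fill <- as.integer(fill)
  if (!fill %in% 0:4) abort("`fill` must be a particle type in 0..4.")
  types <- array(fill, dim = dims)
  if (is.null(region)) {
    region <- array(REGION_MEDIUM, dim = dims)
  } else {
    region <- array(as.integer(region), dim = dims)
    if (!all(region %in% 0:2)) abort("region labels must be in 0..2.")
  }
  structure(
    list(types = types, region = region, dims = dims,
         scale = scale, seed = NA, mcs = 0L),
    class = "tme_lattice"
  )
}

#' @export
print.tme_lattice <- function(x, ...) {
  n <- tabulate(as.vector(x$types) + 1L, nbins = 5L)
  cat(sprintf("<tme_lattice %d x %d x %d, scale %s, mcs %d>\n",
              x$dims[1], x$dims[2], x$dims[3],
              format(x$scale), x$mcs))
  cat(sprintf("  medium %d | hydrogel %d | peritumoral %d | cancer %d | biomaterial %d\n",
              n[1], n[2], n[3], n[4], n[5]))
  invisible(x)
}

in_bounds <- function(sites, dims) {
  sites[, 1] >= 0L & sites[, 1] < dims[1] &
    sites[, 2] >= 0L & sites[, 2] < dims[2] &
    sites[, 3] >= 0L & sites[, 3] < dims[3]
}

site_index <- function(sites, dims) {
  # 0-based (x, y, z) -> 1-based linear index into the types array
  1L + sites[, 1] + dims[1] * (sites[, 2] + dims[2] * sites[, 3])
}

as_site_matrix <- function(site) {
  if (is.matrix(site)) {
    storage.mode(site) <- "integer"
    site
  } else {
    matrix(as.integer(site), ncol = 3)
  }
}

#' Set particle types at sites
#'
#' @param lattice A [tme_lattice()].
#' @param sites An `n x 3` matrix (or length-3 vector) of 0-based coordinates.
#' @param type Particle type(s), recycled to `n`.
#' @return The modified lattice.
#' @export
lattice_set <- function(lattice, sites, type) {
  sites <- as_site_matrix(sites)
  if (!all(in_bounds(sites, lattice$dims))) abort("site out of bounds.")
  type <- as.integer(type)
  if (!all(type %in% 0:4)) abort("particle types must be in 0..4.")
  lattice$types[site_index(sites, lattice$dims)] <- type
  lattice
}

#' Particle type at a site
#'
#' @inheritParams lattice_set
#' @return Integer particle type(s).
#' @export
site_type <- function(lattice, sites) {
  sites <- as_site_matrix(sites)
  if (!all(in_bounds(sites, lattice$dims))) abort("site out of bounds.")
  as.integer(lattice$types[site_index(sites, lattice$dims)])
}

#' Occupied sites as a tibble
#'
#' Lists sites whose particle type is among `types`, in canonical
#' (z, y, x) scan order.
#'
#' @inheritParams lattice_set
#' @param types Particle types to include (default: everything but medium).
#' @return A tibble with columns `x`, `y`, `z`, `type` (0-based coordinates).
#' @export
lattice_sites <- function(lattice, types = 1:4) {
  keep <- which(array(lattice$types %in% types, dim = lattice$dims))
  idx <- keep - 1L
  d <- lattice$dims
  x <- idx %% d[1]
  y <- (idx %/% d[1]) %% d[2]
  z <- idx %/% (d[1] * d[2])
  ord <- order(z, y, x)
  tibble(x = x[ord], y = y[ord], z = z[ord],
         type = as.integer(lattice$types[keep][ord]))
}

#' The 26-site Moore neighborhood offsets
#'
#' The neighborhood of a site comprises its nn = 26 face, edge and corner
#' neighbors — all sites within Chebyshev distance 1. The offset order is
#' fixed (z, then y, then x varying fastest) and the set is closed under
#' negation.
#'
#' @return A `26 x 3` integer matrix of offsets.
#' @export
neighbor_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- list(NULL, c("dx", "dy", "dz"))
  g
}

#' Enumerate the 26 neighbors of a site
#'
#' Returns the Moore neighborhood in the fixed offset order. Out-of-bounds
#' neighbors are returned flagged as `virtual` with type 0 (medium): the
#' construct is bathed in culture medium, so the world beyond the lattice is
#' medium.
#'
#' @inheritParams lattice_set
#' @param site A 0-based coordinate triple; must be in bounds.
#' @return A tibble with columns `x`, `y`, `z`, `type`, `virtual`
#'   (26 rows).
#' @examples
#' lat <- tme_lattice(c(10, 10, 10))
#' nbrs <- neighbors(lat, c(0, 0, 0))
#' sum(nbrs$virtual)  # 19 of the corner's neighbors lie outside the lattice
#' @export
neighbors <- function(lattice, site) {
  site <- as.integer(site)
  if (length(site) != 3L ||
      !all(in_bounds(matrix(site, ncol = 3), lattice$dims))) {
    abort("`site` must be a single in-bounds 0-based coordinate triple.")
  }
  off <- neighbor_offsets()
  pts <- sweep(off, 2, site, "+")
  ok <- in_bounds(pts, lattice$dims)
  type <- rep(TYPE_MEDIUM, 26L)
  type[ok] <- lattice$types[site_index(pts[ok, , drop = FALSE], lattice$dims)]
  tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
         type = as.integer(type), virtual = !ok)
}

#' Count neighbor bonds by particle-type pair
#'
#' Tallies every unordered pair of in-bounds Moore neighbors once, by the
#' type pair (sigma, sigma') of its two ends, along with per-type particle
#' counts. Pairs with a virtual out-of-bounds neighbor (always medium) are
#' tallied separately as boundary pairs so that energy code can include or
#' audit them.
#'
#' @inheritParams lattice_set
#' @return A list with `pairs` (symmetric 5 x 5 matrix of unordered in-bounds
#'   pair counts, dimnames "0".."4"), `types` (named length-5 vector of
#'   particle counts), and `boundary` (length-5 vector: bonds between an
#'   in-bounds site of each type and a virtual medium neighbor).
#' @export
count_bonds <- function(lattice) {
  res <- cpp_count_bonds(as.integer(lattice$types), lattice$dims)
  pairs <- res$pairs
  dimnames(pairs) <- list(0:4, 0:4)
  list(pairs = pairs,
       types = setNames(res$types, 0:4),
       boundary = setNames(res$boundary, 0:4))
}

#' Is a site an interfacial cell?
#'
#' An interfacial cell is a particle of type 2 or 3 with at least one
#' neighbor of a different kind (virtual medium neighbors count). Only
#' interfacial cells receive event opportunities in the simulation;
#' materials (medium, hydrogel) are never active.
#'
#' @inheritParams neighbors
#' @return `TRUE` or `FALSE`.
#' @export
is_interfacial <- function(lattice, site) {
  t0 <- site_type(lattice, site)
  if (!t0 %in% c(TYPE_PERITUMORAL, TYPE_CANCER)) return(FALSE)
  any(neighbors(lattice, site)$type != t0)
}
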