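#' Infiltration of peritumoral cells into the tumor zone
#'
#' Fraction of peritumoral (type 2) cells currently sitting on sites that
#' belonged to the initial tumor spheroid zone. The zone labels are frozen at
#' construct build time, so the index reads the evolving configuration
#' relative to the printed geometry. 0 when there are no peritumoral cells.
#'
#' @param lattice A [tme_lattice()] with region labels.
#' @return A fraction in `[0, 1]`.
#' @export
infiltration_index <- function(lattice) {
  check_region(lattice)
  n2 <- sum(lattice$types == TYPE_PERITUMORAL)
  if (n2 == 0) return(0)
  sum(lattice$types == TYPE_PERITUMORAL & lattice$region == REGION_TUMOR) / n2
}

#' Wrapping of cancer cells by peritumoral cells
#'
#' The fraction of cancer cells' heterotypic bonds that are made with
#' peritumoral cells: `N23 / (N03 + N13 + N23)` over in-bounds neighbor
#' pairs. High values indicate peritumoral cells coating (or mixed through)
#' the cancer-cell population; 0 when cancer cells touch no other type.
#'
#' @param lattice A [tme_lattice()].
#' @return A fraction in `[0, 1]`.
#' @export
wrapping_index <- function(lattice) {
  p <- count_bonds(lattice)$pairs
  het <- p["0", "3"] + p["1", "3"] + p["2", "3"]
  if (het == 0) return(0)
  p["2", "3"] / het
}

#' Escape of cancer cells into the medium zone
#'
#' Fraction of cancer (type 3) cells on sites labeled as initial medium
#' zone, i.e. outside the printed construct. 0 when there are no cancer
#' cells.
#'
#' @inheritParams infiltration_index
#' @return A fraction in `[0, 1]`.
#' @export
escape_fraction <- function(lattice) {
  check_region(lattice)
  n3 <- sum(lattice$types == TYPE_CANCER)
  if (n3 == 0) return(0)
  sum(lattice$types == TYPE_CANCER & lattice$region == REGION_MEDIUM) / n3
}

check_region <- function(lattice) {
  if (is.null(lattice$region)) abort("lattice has no region labels.")
  invisible(lattice)
}

#' Cell cluster statistics
#'
#' Connected components of the cell sites under 26-connectivity (the same
#' Moore neighborhood that defines interactions). Cluster sizes always sum
#' to the number of cells considered.
#'
#' @param lattice A [tme_lattice()].
#' @param types Cell types to cluster jointly (default both cell types).
#' @return A list with `sizes` (decreasing integer vector), `n_clusters`,
#'   `mean_size`, `max_size`.
#' @export
cluster_stats <- function(lattice, types = c(2L, 3L)) {
  sizes <- cpp_cluster_sizes(as.integer(lattice$types), lattice$dims,
                             as.integer(types))
  list(sizes = sizes,
       n_clusters = length(sizes),
       mean_size = if (length(sizes)) mean(sizes) else 0,
       max_size = if (length(sizes)) max(sizes) else 0L)
}

#' All morphometric descriptors of a configuration
#'
#' @inheritParams infiltration_index
#' @return A one-row tibble: `mcs`, type counts, `N23`,
#'   `infiltration_index`, `wrapping_index`, `escape_fraction`,
#'   `n_clusters`, `mean_cluster_size`, `max_cluster_size`.
#' @export
morphometrics <- function(lattice) {
  check_region(lattice)
  bc <- count_bonds(lattice)
  cl <- cluster_stats(lattice)
  tibble(
    mcs = lattice$mcs,
    N0 = unname(bc$types["0"]), N1 = unname(bc$types["1"]),
    N2 = unname(bc$types["2"]), N3 = unname(bc$types["3"]),
    N23 = unname(bc$pairs["2", "3"]),
    infiltration_index = infiltration_index(lattice),
    wrapping_index = wrapping_index(lattice),
    escape_fraction = escape_fraction(lattice),
    n_clusters = cl$n_clusters,
    mean_cluster_size = cl$mean_size,
    max_cluster_size = cl$max_size
  )
}
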