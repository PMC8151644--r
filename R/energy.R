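#' Derive interfacial tensions from works of cohesion and adhesion
#'
#' The work of cohesion eps_ss (diagonal) and work of adhesion eps_ss'
#' (off-diagonal) are the mechanical work needed to break a bond between two
#' adjacent particles. The interfacial tension of the surface separating
#' media s and s' is
#' \deqn{\gamma_{\sigma\sigma'} = (\varepsilon_{\sigma\sigma} +
#'   \varepsilon_{\sigma'\sigma'})/2 - \varepsilon_{\sigma\sigma'}.}
#' Tensions are always derived from eps, never set independently; the
#' diagonal is zero by definition and negative values are permitted (a
#' negative gamma favors the heterotypic contact).
#'
#' @param eps Either a symmetric numeric matrix of works (any size >= 2) or
#'   the length-10 vector for types 0..3 in the canonical order
#'   `e00, e11, e22, e33, e01, e02, e03, e12, e13, e23`.
#' @return A symmetric matrix of interfacial tensions, same shape as the
#'   matrix form of `eps`, units of ET.
#' @examples
#' derive_gamma(tme_preset("set1")$model$eps)
#' @export
derive_gamma <- function(eps) {
  eps <- as_eps_matrix(eps)
  coh <- diag(eps)
  g <- outer(coh, coh, "+") / 2 - eps
  diag(g) <- 0
  dimnames(g) <- dimnames(eps)
  g
}

# Accept the canonical-order length-10 vector or a symmetric matrix.
as_eps_matrix <- function(eps) {
  if (is.matrix(eps)) {
    if (nrow(eps) != ncol(eps) || !is.numeric(eps) || anyNA(eps) ||
        any(!is.finite(eps))) {
      abort("`eps` matrix must be square, numeric and finite.")
    }
    if (!isTRUE(all.equal(eps, t(eps), tolerance = 1e-12))) {
      abort("`eps` must be symmetric: the work to break a bond does not depend on the order of the pair.")
    }
    m <- (eps + t(eps)) / 2
  } else {
    eps <- as.numeric(eps)
    if (length(eps) != 10L || anyNA(eps) || any(!is.finite(eps))) {
      abort("vector `eps` must hold the 10 finite values e00,e11,e22,e33,e01,e02,e03,e12,e13,e23.")
    }
    m <- matrix(0, 4, 4)
    diag(m) <- eps[1:4]
    ut <- cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
    m[ut] <- eps[5:10]
    m[ut[, 2:1]] <- eps[5:10]
  }
  dimnames(m) <- list(seq_len(nrow(m)) - 1L, seq_len(nrow(m)) - 1L)
  m
}

#' Adhesion-energy model
#'
#' Bundles the symmetric works-of-cohesion/adhesion matrix for particle types
#' 0..3, the interfacial tensions derived from it, and the fluctuation energy
#' ET. ET is the biological analog of the thermal fluctuation energy and a
#' surrogate measure of cell motility; works and tensions are expressed in
#' units of ET, so the default is ET = 1.
#'
#' @inheritParams derive_gamma
#' @param ET Fluctuation energy, > 0 (default 1).
#' @return An object of class `tme_model`: list with `eps` (4 x 4), `gamma`
#'   (4 x 4, derived), `ET`.
#' @export
interaction_model <- function(eps, ET = 1) {
  m <- as_eps_matrix(eps)
  if (nrow(m) != 4L) abort("the interaction model covers types 0..3 (4 x 4 `eps`).")
  if (!is.numeric(ET) || length(ET) != 1L || !is.finite(ET) || ET <= 0) {
    abort("`ET` must be a single positive number.")
  }
  structure(list(eps = m, gamma = derive_gamma(m), ET = as.numeric(ET)),
            class = "tme_model")
}

#' @export
print.tme_model <- function(x, ...) {
  cat("<tme_model> works of cohesion/adhesion (units of ET):\n")
  print(x$eps)
  cat("derived interfacial tensions:\n")
  print(round(x$gamma, 6))
  cat(sprintf("ET = %g\n", x$ET))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interaction model
#'
#' One row per unordered type pair with its work of cohesion/adhesion and the
#' derived interfacial tension.
#'
#' @param x A [interaction_model()].
#' @param ... Unused.
#' @return A tibble with columns `type_a`, `type_b`, `eps`, `gamma`.
#' @export
tidy.tme_model <- function(x, ...) {
  idx <- which(upper.tri(x$eps, diag = TRUE), arr.ind = TRUE)
  tibble(type_a = idx[, 1] - 1L, type_b = idx[, 2] - 1L,
         eps = x$eps[idx], gamma = x$gamma[idx]) |>
    dplyr::arrange(.data$type_a, .data$type_b)
}

check_no_biomaterial <- function(lattice) {
  if (any(lattice$types == TYPE_BIOMATERIAL)) {
    abort("biomaterial particles (type 4) are outside the adhesion model: simulations involve types 0..3 only.")
  }
}

#' Total adhesion energy of a configuration
#'
#' Evaluates the lattice energy
#' \deqn{E = \sum_{\sigma<\sigma'} \gamma_{\sigma\sigma'} N_{\sigma\sigma'}
#'  - \tfrac{nn}{2} \sum_{\sigma} \varepsilon_{\sigma\sigma} N_\sigma,}
#' with nn = 26: the first term is the total interfacial energy of adhesion
#' over heterotypic in-bounds bonds, the second the total energy of cohesion
#' (coefficient nn/2 = 13, the choice that makes E identical to the pairwise
#' bond-sum energy on interior configurations; see [bond_sum_energy()]).
#'
#' @param lattice A [tme_lattice()] containing types 0..3 only.
#' @param model A [interaction_model()].
#' @return A one-row tibble with columns `E_total`, `E_interfacial`,
#'   `E_cohesion` (units of ET); `E_total = E_interfacial + E_cohesion`
#'   exactly.
#' @export
total_energy <- function(lattice, model) {
  check_no_biomaterial(lattice)
  bc <- count_bonds(lattice)
  p <- bc$pairs[1:4, 1:4]
  het <- upper.tri(p)
  e_int <- sum(model$gamma[het] * p[het])
  e_coh <- -13 * sum(diag(model$eps) * bc$types[1:4])
  tibble(E_total = e_int + e_coh, E_interfacial = e_int, E_cohesion = e_coh)
}

#' Pairwise bond-sum energy (independent of the gamma decomposition)
#'
#' Since eps is the work needed to break a bond, the configuration energy is
#' minus the sum of eps over every unordered in-bounds neighbor pair
#' (homotypic and heterotypic alike). On configurations whose non-medium
#' material sits at least 2 sites from the lattice boundary, this equals
#' [total_energy()] exactly; it serves as the independent cross-check of the
#' interfacial/cohesion decomposition.
#'
#' @inheritParams total_energy
#' @return A single energy value (units of ET).
#' @export
bond_sum_energy <- function(lattice, model) {
  check_no_biomaterial(lattice)
  p <- count_bonds(lattice)$pairs[1:4, 1:4]
  keep <- upper.tri(p, diag = TRUE)
  -sum(model$eps[keep] * p[keep])
}

#' Energy change of a trial swap
#'
#' Computes E(after) - E(before) for swapping the particles at two Moore
#' neighbor sites of different types, locally from the bonds incident to the
#' two sites only (the shared bond is invariant under the swap). Out-of-bounds
#' virtual neighbors contribute as medium. The lattice is not modified. On
#' interior configurations this equals the difference of [total_energy()]
#' under full recomputation; since a swap leaves all particle counts
#' unchanged, only the interfacial term moves.
#'
#' @inheritParams total_energy
#' @param a,b 0-based coordinates of two Moore-neighbor sites with different
#'   types.
#' @return The energy change (units of ET).
#' @export
delta_energy_swap <- function(lattice, a, b, model) {
  check_no_biomaterial(lattice)
  a <- as.integer(a); b <- as.integer(b)
  if (max(abs(a - b)) != 1L) abort("`a` and `b` must be Moore neighbors.")
  ta <- site_type(lattice, a); tb <- site_type(lattice, b)
  if (ta == tb) abort("`a` and `b` hold the same particle type; a swap is a no-op.")
  cpp_delta_energy_swap(as.integer(lattice$types), lattice$dims,
                        a, b, model$eps)
}

#' Metropolis acceptance rule
#'
#' A trial move is accepted if its energy change is non-positive; otherwise
#' it is accepted with probability exp(-dE / ET). Draws one uniform variate
#' per proposal from R's RNG.
#'
#' @param delta_e Energy change(s) of the proposed move.
#' @param ET Fluctuation energy, > 0.
#' @return Logical vector: accept or reject each proposal.
#' @export
metropolis_accept <- function(delta_e, ET = 1) {
  if (ET <= 0) abort("`ET` must be positive.")
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e / ET)
}
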