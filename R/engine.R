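#' Simulation run controls
#'
#' @param p2,p3 Proliferation probability per eligible peritumoral / cancer
#'   cell per Monte Carlo step (MCS). Defaults are the bundled presets'
#'   values: `p2 = 2e-4`, `p3 = 2.4e-4`.
#' @param ET Fluctuation energy (cell-motility surrogate), > 0.
#' @param n_mcs Number of Monte Carlo steps to run, >= 0.
#' @param seed Optional integer seed; if supplied, [run_simulation()] calls
#'   [set.seed()] before the run so trajectories are bit-reproducible.
#' @param metrics_interval Record a trajectory row (energy, counts, bond
#'   counts, event tallies, morphometrics) every this many MCS; the initial
#'   and final states are always recorded. The full bond-count recomputation
#'   used to audit the running energy bookkeeping happens at the same
#'   checkpoints when `validate = TRUE`.
#' @param validate Cross-check the incremental bond counts against a full
#'   recomputation at every checkpoint (default `TRUE`).
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(p2 = 2e-4, p3 = 2.4e-4, ET = 1, n_mcs = 1000L,
                              seed = NULL, metrics_interval = 100L,
                              validate = TRUE) {
  if (p2 < 0 || p2 > 1 || p3 < 0 || p3 > 1) {
    abort("`p2` and `p3` must be probabilities in [0, 1].")
  }
  if (ET <= 0) abort("`ET` must be positive.")
  if (n_mcs < 0) abort("`n_mcs` must be non-negative.")
  structure(list(p2 = p2, p3 = p3, ET = ET, n_mcs = as.integer(n_mcs),
                 seed = seed, metrics_interval = as.integer(metrics_interval),
                 validate = isTRUE(validate)),
            class = "simulation_params")
}

#' List the interfacial cells of a configuration
#'
#' Interfacial cells — particles of type 2 or 3 with at least one neighbor of
#' a different kind — are the only particles that receive event
#' opportunities. Each type partition is returned in an RNG-shuffled order,
#' cancer cells (type 3) first, mirroring the per-MCS processing order of the
#' engine.
#'
#' @param lattice A [tme_lattice()].
#' @return A tibble with columns `x`, `y`, `z`, `type`.
#' @export
identify_interfacial_cells <- function(lattice) {
  cells <- lattice_sites(lattice, types = c(TYPE_CANCER, TYPE_PERITUMORAL))
  keep <- vapply(seq_len(nrow(cells)), function(i) {
    is_interfacial(lattice, c(cells$x[i], cells$y[i], cells$z[i]))
  }, logical(1))
  cells <- cells[keep, , drop = FALSE]
  parts <- lapply(c(TYPE_CANCER, TYPE_PERITUMORAL), function(t) {
    p <- cells[cells$type == t, , drop = FALSE]
    p[sample.int(nrow(p)), , drop = FALSE]
  })
  dplyr::bind_rows(parts)
}

event_outcome <- function(kind, site, partner = NULL, delta_e = NULL) {
  tibble(kind = kind,
         x = site[1], y = site[2], z = site[3],
         partner_x = if (is.null(partner)) NA_integer_ else partner[1],
         partner_y = if (is.null(partner)) NA_integer_ else partner[2],
         partner_z = if (is.null(partner)) NA_integer_ else partner[3],
         delta_e = if (is.null(delta_e)) NA_real_ else delta_e)
}

#' Attempt a proliferation event
#'
#' If the mother cell has at least one neighbor of type 0 (medium) or 1
#' (hydrogel), one such neighbor is picked uniformly at random and replaced
#' by a daughter cell of the mother's type. No energy test applies to
#' proliferation. A cell with no medium/hydrogel neighbor is buried and the
#' event is skipped: only superficial cells proliferate, a proxy for oxygen
#' and nutrient limitation in the tumor bulk.
#'
#' @param lattice A [tme_lattice()].
#' @param site 0-based coordinates of a cell (type 2 or 3).
#' @return A list with `lattice` (possibly modified) and `outcome` (one-row
#'   tibble: `kind` is `"proliferation"` or `"skipped"`).
#' @export
attempt_proliferation <- function(lattice, site) {
  t0 <- site_type(lattice, site)
  if (!t0 %in% c(TYPE_PERITUMORAL, TYPE_CANCER)) {
    abort("`site` must hold a cell (type 2 or 3).")
  }
  nb <- neighbors(lattice, site)
  elig <- which(!nb$virtual & nb$type <= TYPE_HYDROGEL)
  if (length(elig) == 0L) {
    return(list(lattice = lattice, outcome = event_outcome("skipped", site)))
  }
  pick <- elig[sample.int(length(elig), 1L)]
  d <- c(nb$x[pick], nb$y[pick], nb$z[pick])
  lattice <- lattice_set(lattice, d, t0)
  list(lattice = lattice, outcome = event_outcome("proliferation", site, d))
}

#' Attempt a trial move (swap with a neighbor)
#'
#' Cancer cells (type 3) may swap with any neighbor of a different type;
#' peritumoral cells (type 2) only with medium or hydrogel (type 0/1) —
#' allowing 2-3 swaps as well would merely thrash the cancer-peritumoral
#' interface. One eligible in-bounds partner is chosen uniformly at random;
#' the swap is applied if its energy change is non-positive, otherwise with
#' probability `exp(-dE / ET)`.
#'
#' @inheritParams attempt_proliferation
#' @param model A [interaction_model()]; its `ET` sets the acceptance scale.
#' @return A list with `lattice` and `outcome` (`kind` one of
#'   `"move-accepted"`, `"move-rejected"`, `"skipped"`, with `delta_e` for
#'   the two move outcomes).
#' @export
attempt_move <- function(lattice, site, model) {
  t0 <- site_type(lattice, site)
  if (!t0 %in% c(TYPE_PERITUMORAL, TYPE_CANCER)) {
    abort("`site` must hold a cell (type 2 or 3).")
  }
  nb <- neighbors(lattice, site)
  elig <- if (t0 == TYPE_CANCER) {
    which(!nb$virtual & nb$type != t0)
  } else {
    which(!nb$virtual & nb$type <= TYPE_HYDROGEL)
  }
  if (length(elig) == 0L) {
    return(list(lattice = lattice, outcome = event_outcome("skipped", site)))
  }
  pick <- elig[sample.int(length(elig), 1L)]
  b <- c(nb$x[pick], nb$y[pick], nb$z[pick])
  de <- delta_energy_swap(lattice, site, b, model)
  if (de <= 0 || runif(1) < exp(-de / model$ET)) {
    tb <- site_type(lattice, b)
    lattice <- lattice_set(lattice, b, t0)
    lattice <- lattice_set(lattice, site, tb)
    list(lattice = lattice,
         outcome = event_outcome("move-accepted", site, b, de))
  } else {
    list(lattice = lattice,
         outcome = event_outcome("move-rejected", site, b, de))
  }
}

engine_call <- function(lattice, model, params, n_mcs) {
  res <- cpp_run(as.integer(lattice$types), lattice$dims,
                 as.integer(lattice$region), model$eps, model$gamma,
                 model$ET, params$p2, params$p3, as.integer(n_mcs),
                 params$metrics_interval, as.integer(lattice$mcs),
                 params$validate)
  lattice$types <- array(res$lat, dim = lattice$dims)
  lattice$mcs <- res$final_mcs
  traj <- dplyr::bind_cols(as_tibble(res$trajectory),
                           as_tibble(res$morphometrics))
  list(lattice = lattice, trajectory = traj)
}

#' Advance a configuration by Monte Carlo steps
#'
#' One MCS sweeps the interfacial cells identified at its start: every
#' interfacial cancer cell (in shuffled order) receives one Bernoulli(`p3`)
#' draw deciding proliferation attempt versus trial move, then every
#' interfacial peritumoral cell likewise with `p2`. Cells displaced after
#' listing are skipped on revalidation; daughters act from the next MCS.
#'
#' @inheritParams attempt_move
#' @param params A [simulation_params()] (its `n_mcs` is ignored here).
#' @param n_mcs Number of steps to advance (default 1).
#' @return A list with the advanced `lattice` and the `trajectory` tibble of
#'   recorded checkpoints.
#' @export
run_mcs <- function(lattice, model, params = simulation_params(), n_mcs = 1L) {
  check_no_biomaterial(lattice)
  engine_call(lattice, model, params, n_mcs)
}

#' Run a full simulation
#'
#' Runs `params$n_mcs` Monte Carlo steps of differential-adhesion dynamics
#' with stochastic proliferation, recording energy, composition, bond counts,
#' event tallies and morphometrics every `params$metrics_interval` MCS.
#' Given `params$seed`, trajectories are bit-reproducible; a run can be
#' resumed from its returned state (or a saved site-list snapshot holding an
#' RNG state) and matches the uninterrupted run exactly.
#'
#' @param lattice A seeded construct, e.g. from [build_toroidal()]; may be a
#'   snapshot mid-run (its `mcs` counter continues).
#' @param model A [interaction_model()] or a preset name like `"set1"`.
#' @param params A [simulation_params()].
#' @param rng_state Optional saved `.Random.seed` vector (from a previous
#'   run's `$rng_state` or [read_site_list()]) used to resume the RNG
#'   exactly; ignored when `params$seed` is given.
#' @return An object of class `tme_sim`: list with `lattice` (final state),
#'   `trajectory` (tibble), `model`, `params`, and `rng_state` (the RNG
#'   state after the run, for resuming).
#' @examples
#' set.seed(42)
#' lat <- build_toroidal(scale = 1 / 6)
#' sim <- run_simulation(lat, "set1", simulation_params(n_mcs = 200))
#' glance(sim)
#' @export
run_simulation <- function(lattice, model, params = simulation_params(),
                           rng_state = NULL) {
  if (is.character(model)) model <- tme_preset(model, ET = params$ET)$model
  check_no_biomaterial(lattice)
  if (!is.null(params$seed)) {
    set.seed(params$seed)
  } else if (!is.null(rng_state)) {
    assign(".Random.seed", as.integer(rng_state), envir = globalenv())
  }
  res <- engine_call(lattice, model, params, params$n_mcs)
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  structure(
    list(lattice = res$lattice, trajectory = res$trajectory,
         model = model, params = params,
         rng_state = get(".Random.seed", envir = globalenv())),
    class = "tme_sim"
  )
}

#' @export
print.tme_sim <- function(x, ...) {
  cat(sprintf("<tme_sim> %d MCS, %d trajectory records\n",
              x$lattice$mcs, nrow(x$trajectory)))
  print(x$lattice)
  invisible(x)
}
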