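XYZ_SYMBOLS <- c("1" = "H", "2" = "C", "3" = "O", "4" = "B")

fmt_num <- function(x) {
  # shortest representation that survives a write -> read -> write roundtrip
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a configuration as an XYZ file
#'
#' Standard chemistry XYZ (readable by VMD and most molecular viewers):
#' line 1 the record count, line 2 a comment carrying `mcs=` and `dims=`,
#' then one `SYMBOL x y z` line per non-medium site. The frozen symbol map
#' is hydrogel H, peritumoral cell C, cancer cell O, biomaterial B; medium
#' is always omitted, and with `include_materials = FALSE` hydrogel is
#' omitted too, leaving the cells only.
#'
#' @param lattice A [tme_lattice()].
#' @param path Output file path.
#' @param include_materials Include hydrogel/biomaterial sites (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(lattice, path, include_materials = TRUE) {
  types <- if (include_materials) 1:4 else 2:3
  rec <- lattice_sites(lattice, types = types)
  hdr <- sprintf("tmesim mcs=%d dims=%d %d %d scale=%s",
                 lattice$mcs, lattice$dims[1], lattice$dims[2],
                 lattice$dims[3], fmt_num(lattice$scale))
  lines <- c(as.character(nrow(rec)), hdr,
             sprintf("%s %d %d %d", XYZ_SYMBOLS[as.character(rec$type)],
                     rec$x, rec$y, rec$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file written by [write_xyz()]
#'
#' @param path XYZ file path.
#' @return A [tme_lattice()]; sites not listed are medium. Region labels are
#'   not stored in XYZ and come back as all medium zone.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  m <- regmatches(lines[2],
                  regexec("mcs=(\\d+) dims=(\\d+) (\\d+) (\\d+) scale=([-0-9.eE+naNA]+)",
                          lines[2]))[[1]]
  if (length(m) != 6L) abort("XYZ comment line lacks the mcs=/dims=/scale= fields.")
  dims <- as.integer(m[3:5])
  lat <- tme_lattice(dims, scale = as.numeric(m[6]))
  lat$mcs <- as.integer(m[2])
  if (n > 0) {
    rec <- read.table(text = lines[3:(2 + n)],
                      col.names = c("sym", "x", "y", "z"))
    type <- as.integer(names(XYZ_SYMBOLS))[match(rec$sym, XYZ_SYMBOLS)]
    if (anyNA(type)) abort("unknown atom symbol in XYZ file.")
    lat <- lattice_set(lat, cbind(rec$x, rec$y, rec$z), type)
  }
  lat
}

#' Write a sparse site-list snapshot
#'
#' Bespoke plain-text snapshot: a header `#tmesim v1 Lx Ly Lz scale seed mcs`,
#' an optional `#rng ...` line carrying the RNG state (so a run can be
#' resumed exactly), then one `x y z sigma` line per non-medium site in
#' canonical (z, y, x) order — the format round-trips byte-identically.
#'
#' @param lattice A [tme_lattice()].
#' @param path Output file path.
#' @param rng_state Optional `.Random.seed` vector (e.g. from a
#'   [run_simulation()] result) stored for exact resumption.
#' @return `path`, invisibly.
#' @export
write_site_list <- function(lattice, path, rng_state = NULL) {
  seed <- if (is.null(lattice$seed)) NA else lattice$seed
  hdr <- sprintf("#tmesim v1 %d %d %d %s %s %d",
                 lattice$dims[1], lattice$dims[2], lattice$dims[3],
                 fmt_num(lattice$scale), fmt_num(seed), lattice$mcs)
  lines <- hdr
  if (!is.null(rng_state)) {
    lines <- c(lines, paste("#rng", paste(as.integer(rng_state), collapse = " ")))
  }
  rec <- lattice_sites(lattice, types = 1:4)
  lines <- c(lines, sprintf("%d %d %d %d", rec$x, rec$y, rec$z, rec$type))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sparse site-list snapshot
#'
#' Reconstructs the full lattice (unlisted sites are medium), validating the
#' header dimensions, site bounds, particle types, and duplicate sites (a
#' parse error names the offending line). Region labels are not part of the
#' format; use [set_region()] with the freshly built construct as donor to
#' reattach the frozen initial-geometry labels for morphometrics.
#'
#' @param path Snapshot file path.
#' @return A [tme_lattice()]; if the file stores an RNG state it is attached
#'   as attribute `"rng_state"`.
#' @export
read_site_list <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(hdr) != 8L || hdr[1] != "#tmesim" || hdr[2] != "v1") {
    abort(sprintf("%s:1: malformed site-list header.", path))
  }
  dims <- as.integer(hdr[3:5])
  if (anyNA(dims) || any(dims < 1L)) {
    abort(sprintf("%s:1: invalid dimensions in header.", path))
  }
  lat <- tme_lattice(dims, scale = as.numeric(hdr[6]))
  lat$seed <- suppressWarnings(as.numeric(hdr[7]))
  lat$mcs <- as.integer(hdr[8])
  body_start <- 2L
  rng_state <- NULL
  if (length(lines) >= 2L && startsWith(lines[2], "#rng")) {
    rng_state <- as.integer(strsplit(lines[2], " ", fixed = TRUE)[[1]][-1])
    body_start <- 3L
  }
  seen <- new.env(hash = TRUE)
  if (length(lines) >= body_start) {
    for (i in body_start:length(lines)) {
      f <- suppressWarnings(as.integer(strsplit(lines[i], " ", fixed = TRUE)[[1]]))
      if (length(f) != 4L || anyNA(f)) {
        abort(sprintf("%s:%d: expected 'x y z sigma'.", path, i))
      }
      if (!f[4] %in% 0:4) {
        abort(sprintf("%s:%d: invalid particle type %d.", path, i, f[4]))
      }
      if (any(f[1:3] < 0L) || any(f[1:3] >= dims)) {
        abort(sprintf("%s:%d: site out of bounds.", path, i))
      }
      key <- paste(f[1:3], collapse = ",")
      if (!is.null(seen[[key]])) {
        abort(sprintf("%s:%d: duplicate site.", path, i))
      }
      seen[[key]] <- TRUE
      lat <- lattice_set(lat, f[1:3], f[4])
    }
  }
  if (!is.null(rng_state)) attr(lat, "rng_state") <- rng_state
  lat
}

#' Attach frozen region labels from a donor construct
#'
#' @param lattice A [tme_lattice()] (e.g. read from a snapshot).
#' @param donor A [tme_lattice()] with the same dimensions, or a region
#'   array.
#' @return `lattice` with the donor's region labels.
#' @export
set_region <- function(lattice, donor) {
  reg <- if (inherits(donor, "tme_lattice")) donor$region else donor
  if (!all(dim(reg) == lattice$dims)) abort("region dimensions do not match.")
  lattice$region <- array(as.integer(reg), dim = lattice$dims)
  lattice
}

#' Write the trajectory metrics as CSV
#'
#' One row per recorded MCS with the fixed column set: `mcs`, the energy
#' breakdown, type counts `N0..N3`, the ten unordered bond counts
#' `N00..N33`, the per-interval event tallies, and the morphometric
#' descriptors.
#'
#' @param x A `tme_sim` result or its trajectory tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  traj <- if (inherits(x, "tme_sim")) x$trajectory else x
  readr::write_csv(traj, path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Plain-text YAML configuration with a versioned schema. Recognised keys:
#' `construct` (`type`: `"toroidal"` or `"triple_layered"`, `scale`,
#' `phi_tumor`, `phi_peritumoral`, `margin`), either `preset` (name) or
#' `eps` (the 10 works in canonical order) with `p2`/`p3`, plus `ET`,
#' `n_mcs`, `seed`, `metrics_interval`. Explicit `gamma` entries are
#' rejected — tensions are always derived — but an `expected_gamma` block
#' (the six heterotypic tensions in order g01,g02,g03,g12,g13,g23) may be
#' supplied and is validated against [derive_gamma()].
#'
#' @param path YAML file path.
#' @return A validated config list of class `tme_config`.
#' @export
read_run_config <- function(path) {
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A named list with the keys above.
#' @export
as_run_config <- function(config) {
  if (!is.null(config$gamma)) {
    abort("config must not set `gamma`: interfacial tensions are always derived from `eps` (use `expected_gamma` for validation).")
  }
  defaults <- list(
    construct = list(type = "toroidal", scale = 1 / 3, phi_tumor = 1e-3,
                     phi_peritumoral = 1e-3, margin = 2),
    ET = 1, n_mcs = 1000, seed = NULL, metrics_interval = 100
  )
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  cfg$construct$type <- match.arg(cfg$construct$type,
                                  c("toroidal", "triple_layered"))
  if (!is.null(cfg$preset)) {
    pre <- tme_preset(cfg$preset, ET = cfg$ET)
    cfg$eps <- as.numeric(pre$model$eps[cbind(
      c(1, 2, 3, 4, 1, 1, 1, 2, 2, 3), c(1, 2, 3, 4, 2, 3, 4, 3, 4, 4))])
    if (is.null(cfg$p2)) cfg$p2 <- pre$p2
    if (is.null(cfg$p3)) cfg$p3 <- pre$p3
  }
  if (is.null(cfg$eps)) abort("config needs `preset` or an explicit `eps` list.")
  model <- interaction_model(as.numeric(cfg$eps), ET = cfg$ET)
  if (!is.null(cfg$expected_gamma)) {
    got <- model$gamma[cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))]
    if (max(abs(got - as.numeric(cfg$expected_gamma))) > 1e-6) {
      abort("`expected_gamma` does not match the tensions derived from `eps`.")
    }
  }
  if (is.null(cfg$p2) || is.null(cfg$p3)) {
    abort("config needs `p2` and `p3` (or a `preset` that provides them).")
  }
  cfg$model <- model
  structure(cfg, class = "tme_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$model <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' Builds the configured construct, runs the configured number of MCS, and
#' returns the `tme_sim` result.
#'
#' @param config A `tme_config` (or path to one).
#' @return A `tme_sim`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "tme_config")) config <- as_run_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  phi <- c(tumor = config$construct$phi_tumor,
           peritumoral = config$construct$phi_peritumoral)
  lat <- if (config$construct$type == "toroidal") {
    build_toroidal(scale = config$construct$scale, phi = phi,
                   margin = config$construct$margin)
  } else {
    build_triple_layered(scale = config$construct$scale, phi = phi,
                         margin = config$construct$margin)
  }
  lat$seed <- if (is.null(config$seed)) NA else config$seed
  params <- simulation_params(p2 = config$p2, p3 = config$p3, ET = config$ET,
                              n_mcs = config$n_mcs, seed = NULL,
                              metrics_interval = config$metrics_interval)
  run_simulation(lat, config$model, params)
}
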