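preset_dir <- function() system.file("extdata", "presets", package = "tmesim")

#' Bundled interaction parameter presets
#'
#' Five named parameter sets ship with the package, each pairing a
#' works-of-cohesion/adhesion row (canonical order
#' `e00,e11,e22,e33,e01,e02,e03,e12,e13,e23`, units of ET) with the
#' proliferation probabilities `p2` (peritumoral) and `p3` (cancer) per
#' eligible cell per Monte Carlo step. They span the qualitative outcomes of
#' differential-adhesion self-assembly: infiltration (set1), surface wrapping
#' (set2), plain heterotypic aggregation (set3), no aggregation (set4), and
#' cancer-cell escape (set5).
#'
#' @return A tibble with one row per preset: `name`, `eps` (list column of
#'   length-10 numeric vectors), `p2`, `p3`.
#' @examples
#' tme_presets()
#' @export
tme_presets <- function() {
  files <- sort(list.files(preset_dir(), pattern = "\\.yaml$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    p <- yaml::read_yaml(f)
    tibble(name = p$name, eps = list(as.numeric(p$eps)),
           p2 = as.numeric(p$p2), p3 = as.numeric(p$p3))
  })
  dplyr::bind_rows(rows)
}

#' Load a single preset
#'
#' @param name Preset name, `"set1"` .. `"set5"`.
#' @param ET Fluctuation energy passed to [interaction_model()].
#' @return A list with `name`, `model` (an [interaction_model()]), `p2`, `p3`.
#' @examples
#' tme_preset("set1")$model$gamma
#' @export
tme_preset <- function(name, ET = 1) {
  path <- file.path(preset_dir(), paste0(name, ".yaml"))
  if (length(name) != 1L || !file.exists(path)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(tme_presets()$name, collapse = ", ")))
  }
  p <- yaml::read_yaml(path)
  list(name = p$name, model = interaction_model(as.numeric(p$eps), ET = ET),
       p2 = as.numeric(p$p2), p3 = as.numeric(p$p3))
}
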