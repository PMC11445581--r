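# Flat key = value configuration files with typed validation. Unknown keys
# are errors, so a typo in a threshold cannot silently change an analysis.

.CONFIG_SPEC <- list(
  w_xy_um          = list(type = "num", default = 0.2,
                          check = function(x) x > 0),
  kappa            = list(type = "num", default = 5,
                          check = function(x) x > 1),
  temperature_K    = list(type = "num", default = 310,
                          check = function(x) x > 0),
  viscosity_pa_s   = list(type = "num", default = 1e-3,
                          check = function(x) x > 0),
  points_per_octave = list(type = "int", default = 8L,
                           check = function(x) x >= 1),
  n_segments       = list(type = "int", default = 10L,
                          check = function(x) x >= 2),
  reference_frame  = list(type = "int", default = -20L,
                          check = function(x) TRUE),
  smooth_window    = list(type = "int", default = 4L,
                          check = function(x) x >= 1),
  slope_window     = list(type = "int", default = 5L,
                          check = function(x) x >= 2),
  slope_threshold  = list(type = "num", default = -0.05,
                          check = function(x) is.finite(x)),
  bleach_mode      = list(type = "chr", default = "linear",
                          check = function(x)
                            x %in% c("linear", "control", "none")),
  bleach_fit_window_start = list(type = "int", default = -30L,
                                 check = function(x) TRUE),
  bleach_fit_window_end   = list(type = "int", default = -25L,
                                 check = function(x) TRUE),
  box_multiplier   = list(type = "num", default = 4,
                          check = function(x) x >= 3),
  bin_width_s      = list(type = "num", default = 1e-4,
                          check = function(x) x > 0),
  duration_s       = list(type = "num", default = 30,
                          check = function(x) x > 0),
  timestep_s       = list(type = "num", default = NA_real_,
                          check = function(x) is.na(x) || x > 0),
  seed             = list(type = "int", default = 1L,
                          check = function(x) TRUE),
  # degradation-simulation defaults
  baseline         = list(type = "num", default = 1,
                          check = function(x) x > 0),
  bleach_rate      = list(type = "num", default = 0.002,
                          check = function(x) x >= 0),
  onset_frame      = list(type = "int", default = 3L,
                          check = function(x) TRUE),
  decay_rate       = list(type = "num", default = 0.1,
                          check = function(x) x >= 0),
  noise_sd         = list(type = "num", default = 0.02,
                          check = function(x) x >= 0),
  frame_first      = list(type = "int", default = -40L,
                          check = function(x) TRUE),
  frame_last       = list(type = "int", default = 40L,
                          check = function(x) TRUE),
  frame_interval_s = list(type = "num", default = 30,
                          check = function(x) x > 0),
  # line-profile-simulation defaults
  background       = list(type = "num", default = 0,
                          check = function(x) is.finite(x)),
  image_nx         = list(type = "int", default = 64L,
                          check = function(x) x >= 2),
  image_ny         = list(type = "int", default = 64L,
                          check = function(x) x >= 2)
)

# indexed keys: species<i>_<field> and peak<i>_<field>
.SPECIES_FIELDS <- c(label = "chr", d_um2_s = "num", conc_nm = "num",
                     brightness_g = "num", brightness_r = "num")
.PEAK_FIELDS <- c(x = "num", y = "num", sd_px = "num", amplitude = "num",
                  channel = "chr")

.coerceConfigValue <- function(key, value, type) {
  out <- switch(type,
                num = suppressWarnings(as.numeric(value)),
                int = suppressWarnings(as.integer(value)),
                chr = value)
  if (type != "chr" && is.na(out))
    stop("config key '", key, "': cannot parse '", value, "' as ", type)
  out
}

#' Read a run-configuration file
#'
#' Flat "key = value" text format; '#' starts a comment. Every known key
#' is typed and validated against the owning module's preconditions at
#' load time; unknown keys are errors. Species for the FCS simulator are
#' given as \code{species<i>_label}, \code{species<i>_d_um2_s},
#' \code{species<i>_conc_nm}, \code{species<i>_brightness_g},
#' \code{species<i>_brightness_r}; line-profile peaks as
#' \code{peak<i>_x}, \code{peak<i>_y}, \code{peak<i>_sd_px},
#' \code{peak<i>_amplitude}, \code{peak<i>_channel}.
#'
#' @param path config file path (NULL gives all defaults).
#' @return a named list of validated settings, with \code{species} and
#'   \code{peaks} sub-lists.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- lapply(.CONFIG_SPEC, `[[`, "default")
  species <- list()
  peaks <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (i in seq_along(lines)) {
      kv <- regmatches(lines[i],
                       regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines[i]))[[1L]]
      if (length(kv) != 3L)
        stop("config line ", i, " is not 'key = value': '", lines[i], "'")
      key <- kv[2L]; val <- trimws(kv[3L])
      idx <- regmatches(key,
                        regexec("^(species|peak)([0-9]+)_([a-z0-9_]+)$", key))[[1L]]
      if (length(idx) == 4L) {
        fields <- if (idx[2L] == "species") .SPECIES_FIELDS else .PEAK_FIELDS
        if (!idx[4L] %in% names(fields))
          stop("unknown config key '", key, "'")
        tgt <- if (idx[2L] == "species") "species" else "peaks"
        j <- idx[3L]
        lst <- get(tgt)
        if (is.null(lst[[j]])) lst[[j]] <- list()
        lst[[j]][[idx[4L]]] <- .coerceConfigValue(key, val, fields[[idx[4L]]])
        assign(tgt, lst)
      } else {
        if (!key %in% names(.CONFIG_SPEC))
          stop("unknown config key '", key, "'")
        cfg[[key]] <- .coerceConfigValue(key, val, .CONFIG_SPEC[[key]]$type)
      }
    }
  }
  for (key in names(.CONFIG_SPEC)) {
    if (!is.na(cfg[[key]]) && !.CONFIG_SPEC[[key]]$check(cfg[[key]]))
      stop("config key '", key, "' fails validation (value ", cfg[[key]], ")")
  }
  if (is.na(cfg$timestep_s)) cfg$timestep_s <- cfg$bin_width_s
  cfg$species <- unname(species)
  cfg$peaks <- unname(peaks)
  cfg
}

# assemble domain objects from a validated config
.configVolume <- function(cfg) observationVolume(cfg$w_xy_um, cfg$kappa)

.configSpecies <- function(cfg) {
  if (!length(cfg$species))
    stop("config defines no species (species1_label = ... etc.)")
  lapply(cfg$species, function(sp) {
    need <- c("label", "d_um2_s", "conc_nm")
    if (!all(need %in% names(sp)))
      stop("each species needs at least label, d_um2_s and conc_nm")
    speciesSpec(sp$label, sp$d_um2_s, sp$conc_nm * 1e-9,
                brightnessG = if (is.null(sp$brightness_g)) 0 else sp$brightness_g,
                brightnessR = if (is.null(sp$brightness_r)) 0 else sp$brightness_r)
  })
}

.configPeaks <- function(cfg) {
  lapply(cfg$peaks, function(p) {
    need <- c("x", "y", "sd_px", "amplitude")
    if (!all(need %in% names(p)))
      stop("each peak needs x, y, sd_px and amplitude")
    list(center = c(p$x, p$y), sd = p$sd_px, amplitude = p$amplitude,
         channel = if (is.null(p$channel)) "green" else p$channel)
  })
}
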