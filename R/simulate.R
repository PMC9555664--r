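#' Configuration for the synthetic breeding-investment generator
#'
#' Bundles every parameter of the two-species generator.  The default
#' scenario emulates the study system the package was built around: two
#' sympatric seabirds whose annual mean egg volume tracks a shared winter
#' environmental index, with the gull decoupled ("buffered") from that
#' index before a subsidy-removal (landfill-closure) year and coupled to it
#' afterwards.
#'
#' @param years Study years (default 2002:2019).
#' @param closure_year Regime-change year; the change applies from this year
#'   onward (default 2010).
#' @param species Named list (gull, shearwater) of per-species parameter
#'   lists: `baseline` mean volume (cm^3); `slope_coupled` and
#'   `slope_buffered` (cm^3 per unit of the environmental index);
#'   `resid_sd` annual process noise (cm^3); `buffer_extra_sd` extra
#'   independent noise while buffered (cm^3); `buffered_before_closure`
#'   logical; `n_clutches` per year; `eggs_per_clutch`; `clutch_sd`
#'   between-clutch volume SD (cm^3); `width_mean`, `width_sd` egg width
#'   (mm).
#' @param env List with `mean`, `sd` and AR(1) coefficient `ar` of the
#'   simulated winter index (defaults 0, 1, 0: white noise on the winter
#'   NAO scale).
#' @param seed Master seed; stage-specific substreams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(years = 2002:2019, closure_year = 2010,
                       species = NULL, env = NULL, seed = 1L) {
  default_species <- list(
    gull = list(baseline = 82, slope_coupled = -0.4, slope_buffered = 0,
                resid_sd = 0.06, buffer_extra_sd = 0.6,
                buffered_before_closure = TRUE,
                n_clutches = 30L, eggs_per_clutch = 3L, clutch_sd = 1.5,
                width_mean = 49, width_sd = 1),
    shearwater = list(baseline = 78, slope_coupled = -0.4, slope_buffered = 0,
                      resid_sd = 0.06, buffer_extra_sd = 0,
                      buffered_before_closure = FALSE,
                      n_clutches = 100L, eggs_per_clutch = 1L, clutch_sd = 1.5,
                      width_mean = 46.5, width_sd = 1))
  default_env <- list(mean = 0, sd = 1, ar = 0)
  sp <- default_species
  for (nm in names(species)) sp[[nm]] <- utils::modifyList(sp[[nm]], species[[nm]])
  ev <- utils::modifyList(default_env, as.list(env))
  for (nm in names(sp)) {
    p <- sp[[nm]]
    if (p$resid_sd < 0 || p$buffer_extra_sd < 0 || p$clutch_sd < 0 ||
        p$width_sd < 0)
      stop_eggsync("standard deviations must be >= 0", "eggsync_invalid_config")
    if (p$n_clutches < 1 || p$eggs_per_clutch < 1)
      stop_eggsync("clutch counts must be >= 1", "eggsync_invalid_config")
  }
  if (ev$sd < 0) stop_eggsync("env sd must be >= 0", "eggsync_invalid_config")
  if (abs(ev$ar) >= 1)
    stop_eggsync("AR(1) coefficient must lie in (-1, 1)", "eggsync_invalid_config")
  out <- list(years = as.integer(years), closure_year = as.integer(closure_year),
              species = sp, env = ev, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Simulate the annual environmental index
#'
#' Stationary Gaussian AR(1) series with the configured mean, marginal SD
#' and autocorrelation (default white noise), standing in for a winter
#' climate index such as the December-March NAO.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to a substream of `config$seed`.
#' @return Data frame `year,wnao`.
#' @export
simulate_environment <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$seed, "env")
  set.seed(seed)
  n <- length(config$years)
  ar <- config$env$ar
  z <- numeric(n)
  z[1] <- rnorm(1, 0, config$env$sd)
  if (n > 1) {
    innov_sd <- config$env$sd * sqrt(1 - ar^2)
    for (t in 2:n) z[t] <- ar * z[t - 1] + rnorm(1, 0, innov_sd)
  }
  data.frame(year = config$years, wnao = config$env$mean + z)
}

#' Simulate per-species annual mean-volume series
#'
#' For each species and year, mean volume = baseline + (regime-appropriate
#' slope) x index + Gaussian process noise, plus extra independent noise in
#' buffered years.  A species with `buffered_before_closure = TRUE` uses its
#' buffered slope before `closure_year` and its coupled slope from that year
#' onward.
#'
#' @param config A [sim_config()].
#' @param env Environment series from [simulate_environment()]; must cover
#'   the configured years.
#' @param seed Optional seed; defaults to a substream of `config$seed`.
#' @return An [annual_series()]-classed data frame (with `n_clutches` and
#'   `sd_volume_cm3` set to `NA`: these are latent annual means, not yet
#'   sampled as eggs).
#' @export
simulate_annual_volumes <- function(config, env, seed = NULL) {
  if (!all(config$years %in% env$year))
    stop_eggsync("env series does not cover the configured years",
                 "eggsync_missing_year")
  if (is.null(seed)) seed <- substream_seed(config$seed, "volumes")
  set.seed(seed)
  wnao <- env$wnao[match(config$years, env$year)]
  pieces <- lapply(names(config$species), function(nm) {
    p <- config$species[[nm]]
    buffered <- if (p$buffered_before_closure)
      config$years < config$closure_year else rep(FALSE, length(config$years))
    slope <- ifelse(buffered, p$slope_buffered, p$slope_coupled)
    vol <- p$baseline + slope * wnao +
      rnorm(length(config$years), 0, p$resid_sd) +
      ifelse(buffered, rnorm(length(config$years), 0, p$buffer_extra_sd), 0)
    data.frame(species = nm, year = config$years, mean_volume_cm3 = vol,
               n_clutches = NA_integer_, sd_volume_cm3 = NA_real_)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Realise an annual series as individual egg measurements
#'
#' Per clutch, a clutch-level target volume is drawn around the annual mean
#' (`clutch_sd`); per egg, a width is drawn from the species' width
#' distribution and the length solved from the volume formula,
#' `L = V / (beta W^2)`, so the fixture is exactly consistent with the
#' morphometric model up to measurement rounding (both axes rounded to
#' 0.1 mm).  Draws with solved length <= width are redrawn (capped at 100
#' retries, then an error).
#'
#' @param series An [annual_series()]-style data frame (the generating
#'   means).
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to a substream of `config$seed`.
#' @param constants Volume constants (default [species_constants()]).
#' @return Data frame of egg records
#'   (`species,year,nest_id,length_mm,width_mm`).
#' @export
volumes_to_eggs <- function(series, config, seed = NULL,
                            constants = species_constants()) {
  if (is.null(seed)) seed <- substream_seed(config$seed, "eggs")
  set.seed(seed)
  rows <- list()
  for (nm in unique(series$species)) {
    p <- config$species[[nm]]
    beta <- constants[[nm]]
    sp <- series[series$species == nm, ]
    for (i in seq_len(nrow(sp))) {
      clutch_v <- rnorm(p$n_clutches, sp$mean_volume_cm3[i], p$clutch_sd)
      clutch_v <- pmax(clutch_v, 0.05 * sp$mean_volume_cm3[i])
      for (cl in seq_len(p$n_clutches)) {
        for (egg in seq_len(p$eggs_per_clutch)) {
          ok <- FALSE
          for (try in 1:100) {
            w <- rnorm(1, p$width_mean, p$width_sd)
            if (w <= 0) next
            l <- clutch_v[cl] / (beta * w^2)
            if (l > w) { ok <- TRUE; break }
          }
          if (!ok)
            stop_eggsync(sprintf(
              "could not draw an egg with length > width for %s (volume %.1f, width %.1f +/- %.1f): widths inconsistent with target volumes",
              nm, clutch_v[cl], p$width_mean, p$width_sd),
              "eggsync_retry_exhausted")
          rows[[length(rows) + 1]] <- data.frame(
            species = nm, year = sp$year[i],
            nest_id = sprintf("%s-%d-%03d", nm, sp$year[i], cl),
            length_mm = round(l, 1), width_mm = round(w, 1))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic data set on disk
#'
#' Writes `eggs.csv` (egg records), `env.csv` (`year,wnao`) and
#' `sim_config.json` (the exact configuration used) to `dir`.  Byte-identical
#' across runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory objects.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  env <- simulate_environment(config)
  series <- simulate_annual_volumes(config, env)
  eggs <- volumes_to_eggs(series, config)
  eggs_path <- file.path(dir, "eggs.csv")
  env_path <- file.path(dir, "env.csv")
  cfg_path <- file.path(dir, "sim_config.json")
  write.csv(eggs, eggs_path, row.names = FALSE, quote = FALSE)
  write.csv(env, env_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(eggs_csv = eggs_path, env_csv = env_path,
                 config_json = cfg_path, eggs = eggs, env = env,
                 series = series))
}
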