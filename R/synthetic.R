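#' Reference cubic OD-dose response for EBT2 film on a Co-60 beam
#'
#' A published cubic calibration for GafChromic EBT2 film on a Co-60
#' teletherapy beam, `dose [cGy] = 1685*OD^3 - 187.9*OD^2 + 1006*OD - 2.328`,
#' used throughout the package as the reference example and as the default
#' ground truth of the synthetic-data generator. The OD domain covers the
#' 50-800 cGy calibration range with margin.
#'
#' @return A `calibration_curve`.
#' @examples
#' od_to_dose(ebt2_co60_curve(), 0.14)
#' @export
ebt2_co60_curve <- function() {
  calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65),
                    r_fit = NA_real_)
}

#' Reference irradiation conditions
#'
#' The reference setup against which correction factors are normalized:
#' 10 cm x 10 cm open field, SSD 100 cm, gantry 0 degrees, no wedge.
#'
#' @return Named numeric vector of reference parameter values.
#' @export
reference_conditions <- function() {
  c(field_size_cm = 10, ssd_cm = 100, gantry_deg = 0, wedge_deg = 0)
}

# relative film over-response vs the reference condition, by parameter.
# Electron contamination inflates the surface reading as field size and
# gantry angle grow; it falls off with SSD and is suppressed by the beam
# hardening of a wedge. The encapsulation cap absorbs contaminating
# electrons, flattening the field-size and gantry trends.
response_slopes <- list(
  unencapsulated = c(field_size_cm = 0.009, ssd_cm = -0.0018,
                     gantry_deg = 0.0014, wedge_deg = -0.0032),
  encapsulated = c(field_size_cm = 0, ssd_cm = -0.0018,
                   gantry_deg = 0, wedge_deg = -0.0032)
)

relative_response <- function(parameter, value, encapsulated = FALSE) {
  slopes <- response_slopes[[if (encapsulated) "encapsulated" else "unencapsulated"]]
  ref <- reference_conditions()[[parameter]]
  1 + slopes[[parameter]] * (value - ref)
}

default_cf_grids <- list(
  field_size_cm = seq(4, 24, by = 2),
  ssd_cm = seq(75, 120, by = 5),
  gantry_deg = seq(0, 90, by = 10),
  wedge_deg = c(0, 15, 30, 45, 60)
)

#' Ground-truth correction-factor set of the synthetic generator
#'
#' Correction factors at the measurement grids implied by the generator's
#' relative-response model: CF = 1 / (relative film response), so CF falls
#' with field size and gantry angle (where contamination inflates the
#' film) and rises with SSD and wedge angle for the unencapsulated film,
#' and is flat in field size and gantry angle for the encapsulated film.
#'
#' @param encapsulated Truth for the encapsulated configuration?
#' @return A `cf_set` with one table per irradiation parameter.
#' @export
default_cf_truth <- function(encapsulated = FALSE) {
  tables <- purrr::imap(default_cf_grids, function(grid, p) {
    cf <- 1 / vapply(grid, relative_response, numeric(1),
                     parameter = p, encapsulated = encapsulated)
    cf_table(p, grid, cf, reference_value = reference_conditions()[[p]])
  })
  cf_set(tables)
}

#' Synthetic measurement scenario
#'
#' Bundles the ground truth and noise model from which all synthetic
#' datasets are drawn. A recorded optical density is modelled as the mean
#' reading over a set of `n_films` films irradiated together (film
#' dosimetry protocols irradiate film sets, not single films), with
#' independent Gaussian noise of `noise_sd_od` per film, optionally
#' quantized to the densitometer display precision last.
#'
#' @param true_curve Ground-truth `calibration_curve`.
#' @param cf_truth Ground-truth `cf_set` for the unencapsulated film.
#' @param cf_truth_encapsulated Ground-truth `cf_set` for the encapsulated
#'   film.
#' @param fcal_entrance True entrance calibration factor (chamber dose at
#'   Dmax over unencapsulated surface film dose).
#' @param fcal_entrance_encapsulated Same factor for the encapsulated film
#'   (close to 1/0.7: the cap moves the film's reading toward Dmax).
#' @param noise_sd_od Per-film OD reading noise (standard deviation, OD).
#' @param quantize Quantize recorded ODs to `precision`?
#' @param precision Densitometer display quantum (OD).
#' @param n_films Films per measurement set; recorded OD is the set mean.
#' @param baseline_od Pre-irradiation (background) OD of an unexposed film.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `response_scenario` object.
#' @examples
#' sc <- response_scenario(noise_sd_od = 0.001, seed = 7)
#' @export
response_scenario <- function(true_curve = ebt2_co60_curve(),
                              cf_truth = default_cf_truth(FALSE),
                              cf_truth_encapsulated = default_cf_truth(TRUE),
                              fcal_entrance = 4.134,
                              fcal_entrance_encapsulated = 200 / 139.4528,
                              noise_sd_od = 0,
                              quantize = FALSE,
                              precision = 0.01,
                              n_films = 10,
                              baseline_od = 0.05,
                              seed = 1) {
  stopifnot(inherits(true_curve, "calibration_curve"),
            inherits(cf_truth, "cf_set"),
            inherits(cf_truth_encapsulated, "cf_set"))
  check_scalar(noise_sd_od, "noise_sd_od", nonneg = TRUE)
  check_scalar(fcal_entrance, "fcal_entrance", positive = TRUE)
  check_scalar(seed, "seed")
  structure(
    list(true_curve = true_curve, cf_truth = cf_truth,
         cf_truth_encapsulated = cf_truth_encapsulated,
         fcal_entrance = fcal_entrance,
         fcal_entrance_encapsulated = fcal_entrance_encapsulated,
         noise_sd_od = noise_sd_od, quantize = quantize,
         precision = precision, n_films = n_films,
         baseline_od = baseline_od, seed = as.integer(seed)),
    class = "response_scenario"
  )
}

#' @export
print.response_scenario <- function(x, ...) {
  cat(sprintf(
    "<response_scenario> noise_sd_od = %g, n_films = %d, quantize = %s, seed = %d\n",
    x$noise_sd_od, x$n_films, x$quantize, x$seed))
  invisible(x)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# one recorded OD: mean of n_films noisy per-film readings, then quantized
record_od <- function(od_true, scenario) {
  od <- od_true +
    stats::rnorm(length(od_true), 0,
                 scenario$noise_sd_od / sqrt(scenario$n_films))
  if (scenario$quantize) od <- quantize_od(od, scenario$precision)
  od
}

#' Post-exposure optical-density growth model
#'
#' Radiochromic film keeps darkening after irradiation as polymerization
#' continues. The generator models the net OD as a single-exponential
#' saturation `plateau * (1 - exp(-t / tau))`, where the plateau is the
#' stabilized NOD implied by the calibration curve and the time constant
#' tau grows linearly with dose (low doses stabilize faster): 120 min at
#' 50 cGy to 250 min at 800 cGy by default, calibrated so that even the
#' quantized 800 cGy series settles onto its final display value well
#' before the nominal 1440 min (24 h) read-out time.
#'
#' @param curve Ground-truth `calibration_curve` giving the plateau NOD.
#' @param tau_low,tau_high Time constants (min) at `dose_low`/`dose_high`.
#' @param dose_low,dose_high Doses (cGy) anchoring the tau ramp.
#' @param t_stable Nominal stabilization time (min).
#' @return A `growth_model`.
#' @export
growth_model <- function(curve = ebt2_co60_curve(), tau_low = 120,
                         tau_high = 250, dose_low = 50, dose_high = 800,
                         t_stable = 1440) {
  stopifnot(inherits(curve, "calibration_curve"),
            tau_low > 0, tau_high > 0, dose_high > dose_low)
  structure(list(curve = curve, tau_low = tau_low, tau_high = tau_high,
                 dose_low = dose_low, dose_high = dose_high,
                 t_stable = t_stable),
            class = "growth_model")
}

growth_tau <- function(model, dose) {
  frac <- (dose - model$dose_low) / (model$dose_high - model$dose_low)
  model$tau_low + (model$tau_high - model$tau_low) * min(max(frac, 0), 1)
}

#' Generate a post-exposure OD growth series
#'
#' @param dose Absorbed dose (cGy, > 0) within the curve's range.
#' @param model A [growth_model()].
#' @param times Sorted read-out times in minutes.
#' @param noise_sd_od Gaussian OD noise per reading (default 0: the
#'   densitometer quantization is the dominant readout error).
#' @param quantize Quantize readings to `precision`?
#' @param precision Densitometer display quantum (OD).
#' @param seed Integer seed (only relevant when `noise_sd_od > 0`).
#' @return A tibble with columns `time_min` and `od`.
#' @examples
#' generate_growth_series(200, times = seq(60, 2880, by = 60))
#' @export
generate_growth_series <- function(dose, model = growth_model(),
                                   times = seq(60, 6480, by = 60),
                                   noise_sd_od = 0, quantize = TRUE,
                                   precision = 0.01, seed = 1) {
  check_scalar(dose, "dose", positive = TRUE)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.", class = "filmdose_input_error")
  }
  plateau <- dose_to_od(model$curve, dose)
  tau <- growth_tau(model, dose)
  od <- plateau * (1 - exp(-times / tau))
  if (noise_sd_od > 0) {
    od <- with_seed(seed, od + stats::rnorm(length(od), 0, noise_sd_od))
  }
  if (quantize) od <- quantize_od(od, precision)
  tibble::tibble(time_min = times, od = od)
}

#' Time at which an OD growth series has stabilized
#'
#' A series counts as stabilized from the first reading after which every
#' successive change stays below one readout quantum (< 0.01 OD), with at
#' least `window` readings remaining to support the claim. Returns `NA`
#' (not stabilized) if no such point exists.
#'
#' @param series Numeric OD readings.
#' @param times Read-out times (min), same length as `series`.
#' @param window Minimum number of readings that must back the plateau.
#' @param threshold Maximum successive change still counting as stable
#'   (default one readout quantum, 0.01 OD).
#' @return Stabilization time in minutes, or `NA_real_` if never stable.
#' @export
stabilization_time <- function(series, times, window = 5, threshold = 0.01) {
  if (length(series) != length(times)) {
    abort("`series` and `times` must have the same length.",
          class = "filmdose_input_error")
  }
  n <- length(series)
  if (n < window) return(NA_real_)
  changes <- abs(diff(series))
  unstable <- which(changes >= threshold - 1e-12)
  first_ok <- if (length(unstable) == 0) 1L else max(unstable) + 1L
  if (n - first_ok + 1L < window) return(NA_real_)
  times[first_ok]
}

#' Generate a synthetic calibration dataset
#'
#' Draws chamber-referenced calibration points from the scenario's true
#' curve: the NOD of each film set is the exact inverse of the delivered
#' dose plus readout noise, optionally quantized.
#'
#' @param scenario A [response_scenario()].
#' @param doses_cGy Delivered doses (cGy) within the true curve's range;
#'   the ten-point 50-800 cGy schedule by default.
#' @return A tibble with columns `nod` and `dose_cGy`, ready for
#'   [fit_calibration()].
#' @examples
#' generate_calibration_dataset(response_scenario(noise_sd_od = 0.005))
#' @export
generate_calibration_dataset <- function(scenario,
                                         doses_cGy = c(seq(50, 450, by = 50), 800)) {
  stopifnot(inherits(scenario, "response_scenario"))
  if (length(doses_cGy) == 0) {
    return(tibble::tibble(nod = numeric(0), dose_cGy = numeric(0)))
  }
  od_true <- dose_to_od(scenario$true_curve, doses_cGy)
  nod <- with_seed(scenario$seed, record_od(od_true, scenario))
  tibble::tibble(nod = nod, dose_cGy = doses_cGy)
}

#' Generate a correction-factor measurement landscape
#'
#' Paired chamber/film readings across the characterization grids of the
#' four irradiation parameters (field size 4-24 cm, SSD 75-120 cm, gantry
#' 0-90 deg, wedge 0-60 deg), for both film configurations. The chamber
#' dose follows the delivered dose (inverse-square scaled with SSD,
#' attenuated by the wedge); the film dose additionally carries the
#' configuration's relative surface response, which is what the correction
#' factors recover. Characterization irradiations deliver a high dose by
#' default, placing the film signal on the well-resolved upper part of the
#' calibrated range.
#'
#' @param scenario A [response_scenario()].
#' @param delivered_cGy Dose delivered at the reference condition (cGy).
#' @param grids Named list of parameter grids (defaults to the
#'   characterization grids above; each must include the reference value).
#' @return A tibble with columns `parameter`, `value`, `encapsulated`,
#'   `ric_cGy`, `rf_cGy`.
#' @seealso [estimate_cf_set()], [normalized_response()]
#' @export
generate_cf_landscape <- function(scenario, delivered_cGy = 600,
                                  grids = default_cf_grids) {
  stopifnot(inherits(scenario, "response_scenario"))
  check_scalar(delivered_cGy, "delivered_cGy", positive = TRUE)
  ref <- reference_conditions()
  with_seed(scenario$seed + 1L, {
    rows <- purrr::imap(grids, function(grid, p) {
      purrr::map(c(FALSE, TRUE), function(enc) {
        truth <- if (enc) scenario$cf_truth_encapsulated else scenario$cf_truth
        fcal <- if (enc) scenario$fcal_entrance_encapsulated else scenario$fcal_entrance
        # delivered dose at the chamber: inverse-square with SSD,
        # exponential attenuation with wedge angle, flat otherwise
        ric <- switch(p,
          ssd_cm = delivered_cGy * (100 / grid)^2,
          wedge_deg = delivered_cGy * exp(-0.006 * grid),
          rep(delivered_cGy, length(grid)))
        r <- 1 / lookup_cf(truth[[p]], grid)
        df_true <- ric * r / fcal
        od <- record_od(dose_to_od(scenario$true_curve, df_true), scenario)
        rf <- od_to_dose(scenario$true_curve, od, strict = FALSE)
        tibble::tibble(parameter = p, value = grid, encapsulated = enc,
                       ric_cGy = ric, rf_cGy = rf)
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Normalized film response across a measurement landscape
#'
#' The film-to-chamber dose ratio at each condition divided by the same
#' ratio at the parameter's reference value, per parameter and film
#' configuration — the quantity whose trends the correction factors undo
#' (it is 1/CF).
#'
#' @param landscape Output of [generate_cf_landscape()] (or measured data
#'   in the same layout).
#' @return The landscape tibble with a `normalized_response` column.
#' @export
normalized_response <- function(landscape) {
  ref <- reference_conditions()
  landscape |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$parameter, .data$encapsulated) |>
    dplyr::group_modify(function(d, key) {
      iref <- which(abs(d$value - ref[[key$parameter]]) < 1e-9)
      if (length(iref) != 1) {
        abort(sprintf("No reference measurement for %s.", key$parameter),
              class = "filmdose_invalid_argument")
      }
      ratio <- d$rf_cGy / d$ric_cGy
      dplyr::mutate(d, normalized_response = ratio / ratio[iref])
    }) |>
    dplyr::ungroup()
}

#' Estimate a correction-factor set from a measurement landscape
#'
#' Builds one correction-factor table per parameter from the
#' unencapsulated paired readings of a landscape via [build_cf_table()].
#'
#' @param landscape Output of [generate_cf_landscape()].
#' @return A `cf_set`.
#' @export
estimate_cf_set <- function(landscape) {
  ref <- reference_conditions()
  landscape <- dplyr::filter(tibble::as_tibble(landscape), !.data$encapsulated)
  tables <- landscape |>
    dplyr::group_split(.data$parameter) |>
    purrr::map(function(d) {
      p <- d$parameter[1]
      build_cf_table(d, p, reference_value = ref[[p]])
    })
  cf_set(tables)
}

#' Sweep of irradiation conditions spanning the characterized ranges
#'
#' One-parameter-at-a-time condition sets (as the characterization itself
#' varies one parameter while holding the others at reference): six field
#' sizes, six SSDs, five gantry angles and three wedge angles — 20
#' conditions covering field 4-24 cm, SSD 75-120 cm, gantry 0-90 deg and
#' wedge 15-45 deg.
#'
#' @return A 20-row tibble with columns `field_size_cm`, `ssd_cm`,
#'   `gantry_deg`, `wedge_deg` (`NA` = parameter at reference).
#' @export
default_condition_sweep <- function() {
  dplyr::bind_rows(
    tibble::tibble(field_size_cm = c(4, 8, 12, 16, 20, 24)),
    tibble::tibble(ssd_cm = c(75, 85, 95, 105, 115, 120)),
    tibble::tibble(gantry_deg = c(10, 30, 50, 70, 90)),
    tibble::tibble(wedge_deg = c(15, 30, 45))
  )
}

#' Simulate in vivo treatment film readings with ground truth attached
#'
#' For each condition set, delivers the prescribed dose to Dmax and
#' generates the surface film reading an unencapsulated film would record
#' there (prescription scaled by the condition's relative surface response
#' over the entrance calibration factor), as pre/post optical densities
#' with the scenario's noise model. The ground-truth film dose is attached
#' so recovery can be scored.
#'
#' @param scenario A [response_scenario()].
#' @param conditions Data frame whose columns are a subset of
#'   `field_size_cm`, `ssd_cm`, `gantry_deg`, `wedge_deg`; `NA` entries
#'   mean "at reference". One film set per row.
#' @param prescribed_cGy Prescribed dose to Dmax (cGy).
#' @return A list with `readings` (film_id, od_pre, od_post, encapsulated,
#'   condition columns) and `truth` (film_id, df_true_cGy, od_true,
#'   d_entrance_true_cGy).
#' @examples
#' sc <- response_scenario(noise_sd_od = 0.001, seed = 3)
#' simulate_treatment_readings(sc, default_condition_sweep())$readings
#' @export
simulate_treatment_readings <- function(scenario, conditions,
                                        prescribed_cGy = 200) {
  stopifnot(inherits(scenario, "response_scenario"))
  check_scalar(prescribed_cGy, "prescribed_cGy", positive = TRUE)
  conditions <- tibble::as_tibble(conditions)
  known <- names(reference_conditions())
  bad <- setdiff(names(conditions), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition column(s): %s.", paste(bad, collapse = ", ")),
          class = "filmdose_lookup_error")
  }
  r_total <- purrr::pmap_dbl(conditions, function(...) {
    vals <- c(...)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(1)
    prod(purrr::imap_dbl(vals, function(v, p) {
      1 / lookup_cf(scenario$cf_truth[[p]], v)
    }))
  })
  df_true <- prescribed_cGy * r_total / scenario$fcal_entrance
  od_true <- dose_to_od(scenario$true_curve, df_true)
  with_seed(scenario$seed + 2L, {
    od_post <- scenario$baseline_od + record_od(od_true, scenario)
    od_pre <- rep(scenario$baseline_od, length(od_true))
    if (scenario$quantize) od_pre <- quantize_od(od_pre, scenario$precision)
    readings <- dplyr::bind_cols(
      tibble::tibble(film_id = sprintf("film_%02d", seq_along(od_true)),
                     od_pre = od_pre, od_post = od_post,
                     encapsulated = FALSE),
      conditions
    )
    truth <- tibble::tibble(
      film_id = readings$film_id,
      df_true_cGy = df_true,
      od_true = od_true,
      d_entrance_true_cGy = prescribed_cGy
    )
    list(readings = readings, truth = truth)
  })
}
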