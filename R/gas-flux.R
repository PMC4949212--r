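#' Mass emission rate for each chamber sampling window
#'
#' Open-circuit respiration chambers measure emission as the enrichment of
#' the exhaust air over background at a known ventilation rate. With ppm
#' read as a volume (mole) fraction, the ideal-gas law at each window's
#' measured temperature and pressure converts the enriched volume flow to a
#' mass rate:
#' \deqn{rate = flow \times (c_{chamber} - c_{background}) \times 10^{-6}
#'   \times P/(RT) \times M}
#' with flow in L/min, P in kPa, T in K, R = 8.314 kPa L mol^-1 K^-1 and M
#' the molar mass in g/mol, giving g/min.
#'
#' @param windows A chamber-log data frame with columns `chamber_id`,
#'   `flow_L_min`, `temp_K`, `pressure_kPa`, `gas` (one of CH4, H2, CO2),
#'   `conc_chamber_ppm`, `conc_background_ppm`, and usually `duration_s`.
#' @return `windows` plus `rate_g_min` and a `negative_net` flag. Negative
#'   net concentrations are kept (clipping would bias daily means upward)
#'   and flagged with a warning.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   chamber_id = "c1", flow_L_min = 3000, temp_K = 298.15,
#'   pressure_kPa = 101.325, gas = "CH4",
#'   conc_chamber_ppm = 52, conc_background_ppm = 2
#' )
#' window_mass_rate(w)$rate_g_min # ~0.0984 g/min, i.e. ~141.6 g/day
window_mass_rate <- function(windows) {
  need <- c("chamber_id", "flow_L_min", "temp_K", "pressure_kPa", "gas",
            "conc_chamber_ppm", "conc_background_ppm")
  missing <- setdiff(need, names(windows))
  if (length(missing)) {
    abort(paste0("missing chamber-log columns: ", paste(missing, collapse = ", ")))
  }
  bad_gas <- setdiff(unique(windows$gas), names(.MOLAR_MASS))
  if (length(bad_gas)) {
    abort(paste0("unknown gas label(s): ", paste(bad_gas, collapse = ", ")))
  }
  if (any(windows$temp_K <= 0) || any(windows$pressure_kPa <= 0)) {
    abort("temperature and pressure must be positive")
  }
  if (any(windows$flow_L_min <= 0)) abort("flow must be positive")
  if ("duration_s" %in% names(windows) && any(windows$duration_s <= 0)) {
    abort("window duration must be positive")
  }
  net_ppm <- windows$conc_chamber_ppm - windows$conc_background_ppm
  molar_density <- windows$pressure_kPa / (.GAS_CONSTANT * windows$temp_K)
  out <- mutate(
    as_tibble(windows),
    rate_g_min = .data$flow_L_min * net_ppm * 1e-6 * molar_density *
      unname(.MOLAR_MASS[.data$gas]),
    negative_net = net_ppm < 0
  )
  if (any(out$negative_net)) {
    warning(sum(out$negative_net),
            " window(s) have chamber concentration below background; ",
            "negative rates kept and flagged", call. = FALSE)
  }
  out
}

#' Daily gas production and yield per animal-period
#'
#' Scales the duration-weighted mean window rate of each chamber day to 24 h
#' (x 1440 min), averages the chamber days of a period (typically two 24-h
#' confinements), and divides by dry-matter intake for the yield.
#'
#' @param windows Chamber log as for [window_mass_rate()], with `animal_id`
#'   and `period` columns and optionally `day` (chamber-day index; a single
#'   day is assumed when absent).
#' @param dmi Data frame with `animal_id`, `period`, `dmi_kg` (kg DM/day).
#' @return One row per animal x period x gas: `g_day`, `mol_day`
#'   (`g_day / molar_mass`), `dmi_kg`, `g_per_kg_dmi`, and `n_windows`.
#' @export
daily_emission <- function(windows, dmi) {
  if (nrow(windows) == 0) abort("empty chamber log")
  if (!all(c("animal_id", "period") %in% names(windows))) {
    abort("`windows` needs `animal_id` and `period` columns")
  }
  if (!all(c("animal_id", "period", "dmi_kg") %in% names(dmi))) {
    abort("`dmi` needs `animal_id`, `period`, `dmi_kg` columns")
  }
  if (any(dmi$dmi_kg <= 0)) abort("dmi_kg must be positive")
  rated <- window_mass_rate(windows)
  if (!"day" %in% names(rated)) rated$day <- 1L
  if (!"duration_s" %in% names(rated)) rated$duration_s <- 1
  mixed <- rated %>%
    group_by(.data$animal_id, .data$period, .data$day) %>%
    summarise(n_chambers = dplyr::n_distinct(.data$chamber_id), .groups = "drop")
  if (any(mixed$n_chambers > 1)) {
    abort("an animal-period-day maps to more than one chamber_id")
  }
  rated %>%
    group_by(.data$animal_id, .data$period, .data$gas, .data$day) %>%
    summarise(
      g_day = 1440 * sum(.data$rate_g_min * .data$duration_s) /
        sum(.data$duration_s),
      n_windows = n(), .groups = "drop"
    ) %>%
    group_by(.data$animal_id, .data$period, .data$gas) %>%
    summarise(g_day = mean(.data$g_day), n_windows = sum(.data$n_windows),
              .groups = "drop") %>%
    mutate(mol_day = .data$g_day / unname(.MOLAR_MASS[.data$gas])) %>%
    left_join(dmi[c("animal_id", "period", "dmi_kg")],
              by = c("animal_id", "period")) %>%
    mutate(g_per_kg_dmi = .data$g_day / .data$dmi_kg) %>%
    select("animal_id", "period", "gas", "g_day", "mol_day", "dmi_kg",
           "g_per_kg_dmi", "n_windows")
}
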