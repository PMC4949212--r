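#' Reference group means for the chamber dose-response study
#'
#' Reported diet x period group means for the chloroform-cyclodextrin (CCD)
#' dose-response study in rumen-fistulated Brahman steers (two diets, four
#' animals each; control, low, mid, high dose periods) that this package's
#' synthetic generator emulates: dry-matter intake, CH4 and H2 yields, rumen
#' pH, formate, ammonia-N, total SCFA and SCFA molar percentages, together
#' with the pooled standard errors of the means.
#'
#' @return A list with `means` (tibble: diet, period, variable, mean) and
#'   `sems` (tibble: variable, sem; pooled SEM for n = 4 animals per group).
#' @export
reference_means <- function() {
  vars <- c("dmi_kg", "ch4_g_kg_dmi", "h2_g_kg_dmi", "ph", "formate_mM",
            "nh3_n", "total_scfa_mM", "pct_acetate", "pct_propionate",
            "pct_n_butyrate", "pct_iso_butyrate", "pct_n_valerate",
            "pct_iso_valerate")
  hc <- rbind( # hay_concentrate: control, low, mid, high
    dmi_kg          = c(5.9, 5.8, 5.6, 5.0),
    ch4_g_kg_dmi    = c(24, 19, 15, 10),
    h2_g_kg_dmi     = c(0.00, 0.97, 1.43, 3.16),
    ph              = c(6.4, 6.6, 6.6, 6.7),
    formate_mM      = c(0.0, 4.2, 8.5, 12),
    nh3_n           = c(4.4, 2.8, 3.1, 4.2),
    total_scfa_mM   = c(88, 81, 79, 78),
    pct_acetate     = c(62, 56, 55, 53),
    pct_propionate  = c(18, 21, 21, 23),
    pct_n_butyrate  = c(12, 13, 14, 13),
    pct_iso_butyrate = c(1.53, 1.74, 1.81, 1.89),
    pct_n_valerate  = c(3.45, 3.98, 4.03, 4.07),
    pct_iso_valerate = c(3.05, 3.80, 4.39, 4.69)
  )
  hay <- rbind(
    dmi_kg          = c(4.2, 4.6, 4.4, 4.7),
    ch4_g_kg_dmi    = c(27, 21, 17, 12),
    h2_g_kg_dmi     = c(0.00, 0.33, 0.83, 1.73),
    ph              = c(6.6, 6.7, 6.8, 6.7),
    formate_mM      = c(0.0, 0.0, 0.0, 4.2),
    nh3_n           = c(2.3, 4.7, 4.8, 5.2),
    total_scfa_mM   = c(79, 91, 82, 66),
    pct_acetate     = c(67, 62, 61, 58),
    pct_propionate  = c(15, 18, 18, 19),
    pct_n_butyrate  = c(9, 11, 11, 12),
    pct_iso_butyrate = c(1.69, 1.66, 1.85, 2.13),
    pct_n_valerate  = c(3.56, 3.76, 4.01, 4.69),
    pct_iso_valerate = c(3.15, 3.31, 3.92, 4.79)
  )
  long <- function(m, diet) {
    tibble(
      diet = diet,
      period = rep(c("control", "low", "mid", "high"), each = nrow(m)),
      variable = rep(rownames(m), times = ncol(m)),
      mean = as.vector(m)
    )
  }
  sems <- tibble(
    variable = vars,
    sem = c(0.28, 1.40, 0.18, 0.04, 1.06, 0.54, 2.99,
            1.31, 0.76, 0.61, 0.04, 0.10, 0.15)
  )
  list(means = bind_rows(long(hc, "hay_concentrate"), long(hay, "hay")),
       sems = sems)
}

#' Study design for the synthetic chamber experiment
#'
#' @param diets Diet group labels (one group of animals per diet).
#' @param animals_per_diet Animals per diet group.
#' @param periods Ordered period labels; the first must be the control.
#' @param dose_g_per_100kg CCD dose per period (g per 100 kg liveweight);
#'   must be 0 for the control.
#' @param chamber_days_per_period 24-h chamber confinements per period.
#' @param windows_per_day Gas sampling events per chamber day.
#' @param window_duration_s Analysis span of each sampling event (seconds).
#' @return A `study_design` list, validated.
#' @export
study_design <- function(diets = c("hay_concentrate", "hay"),
                         animals_per_diet = 4,
                         periods = c("control", "low", "mid", "high", "post"),
                         dose_g_per_100kg = c(0, 1.0, 1.6, 2.6, 0),
                         chamber_days_per_period = 2,
                         windows_per_day = 24,
                         window_duration_s = 315) {
  if (length(periods) < 2 || periods[1] != "control") {
    abort("`periods` must start with the control period")
  }
  if (length(dose_g_per_100kg) != length(periods)) {
    abort("one dose value per period required")
  }
  if (any(dose_g_per_100kg < 0) || dose_g_per_100kg[1] != 0) {
    abort("doses must be non-negative and 0 in the control period")
  }
  if (animals_per_diet < 1) abort("need at least one animal per diet")
  structure(list(
    diets = diets, animals_per_diet = animals_per_diet,
    periods = periods, dose_g_per_100kg = setNames(dose_g_per_100kg, periods),
    chamber_days_per_period = chamber_days_per_period,
    windows_per_day = windows_per_day,
    window_duration_s = window_duration_s
  ), class = "study_design")
}

#' Effect configuration for the synthetic study
#'
#' Ground-truth means, variability and instrument settings used by
#' [generate_study()]. Defaults reproduce the reported study conditions
#' ([reference_means()]); the post-treatment period reverts to the control
#' means (emissions were reported to return to control levels after
#' withdrawal). Group means with molar percentages are renormalised to sum
#' to exactly 100.
#'
#' @param means,sems As in [reference_means()]; overridable.
#' @param noise_scale Multiplier on every noise source (0 = noise-free:
#'   SEMs, chamber ppm noise and Ct noise all vanish).
#' @param icc_animal Fraction of the between-animal-within-group variance
#'   attributed to a persistent animal effect (drawn once per animal and
#'   reused across periods, the repeated-measures structure).
#' @param n_per_group Group size the SEMs refer to; per-observation SD is
#'   `sem * sqrt(n_per_group)`.
#' @param chamber List of chamber constants: `flow_L_min`, `temp_K`,
#'   `pressure_kPa`, `background_ppm` (named per gas), `conc_noise_ppm`.
#' @param qpcr List with `baseline_ct` (named per target), `shifts` (tibble
#'   target/diet/period/delta_ct_shift on the target Ct; positive = lower
#'   abundance), `rep_sd` (cycles), `animal_sd` (cycles), `n_reps`.
#' @param community List with `phyla` (tibble period/phylum/proportion
#'   ground-truth composition), `taxa_per_phylum`, `reads_per_sample`,
#'   `dm_concentration` (Dirichlet-multinomial precision; smaller = more
#'   overdispersed, as is typical of 16S count data).
#' @return An `effect_config` list, validated.
#' @export
effect_config <- function(means = NULL, sems = NULL, noise_scale = 1,
                          icc_animal = 0.5, n_per_group = 4,
                          chamber = list(), qpcr = list(), community = list()) {
  ref <- reference_means()
  means <- means %||% ref$means
  sems <- sems %||% ref$sems
  if (any(sems$sem < 0)) abort("SEMs must be non-negative")
  if (noise_scale < 0) abort("noise_scale must be non-negative")
  if (icc_animal < 0 || icc_animal > 1) abort("icc_animal must be in [0, 1]")

  # extend to a post period (reverts to control) if the means lack one
  add_post <- function(m) {
    if ("post" %in% m$period) return(m)
    bind_rows(m, m %>% filter(.data$period == "control") %>%
                mutate(period = "post"))
  }
  means <- add_post(means)
  # renormalise molar percentages to sum exactly 100 within diet x period
  means <- means %>%
    group_by(.data$diet, .data$period) %>%
    dplyr::group_modify(function(df, key) {
      is_pct <- df$variable %in% .PCT_COLS
      if (any(is_pct)) {
        df$mean[is_pct] <- 100 * df$mean[is_pct] / sum(df$mean[is_pct])
      }
      df
    }) %>%
    ungroup()

  chamber <- modifyList(list(
    flow_L_min = 3000, temp_K = 298.15, pressure_kPa = 101.325,
    background_ppm = c(CH4 = 2, H2 = 2), conc_noise_ppm = 0.2
  ), chamber)
  qpcr <- modifyList(list(
    baseline_ct = c(total_bacteria = 20, mcrA = 25, protozoa = 28, fungi = 30),
    shifts = default_qpcr_shifts(),
    rep_sd = 0.15, animal_sd = 0.3, n_reps = 3
  ), qpcr)
  community <- modifyList(list(
    phyla = default_community(),
    taxa_per_phylum = 6, reads_per_sample = 10000, dm_concentration = 200
  ), community)

  pct_check <- means %>%
    filter(.data$variable %in% .PCT_COLS) %>%
    group_by(.data$diet, .data$period) %>%
    summarise(s = sum(.data$mean), .groups = "drop")
  if (any(abs(pct_check$s - 100) > 0.5)) {
    abort("configured molar percentages must sum to 100 +/- 0.5")
  }
  structure(list(
    means = means, sems = sems, noise_scale = noise_scale,
    icc_animal = icc_animal, n_per_group = n_per_group,
    chamber = chamber, qpcr = qpcr, community = community
  ), class = "effect_config")
}

# Dose-dependent Ct shifts: methanogens (mcrA) suppressed ~6-fold at the
# high dose on both diets; protozoa mildly promoted on the concentrate diet;
# fungi unaffected.
default_qpcr_shifts <- function() {
  periods <- c("control", "low", "mid", "high", "post")
  grid <- tidyr::expand_grid(
    target = c("mcrA", "protozoa", "fungi"),
    diet = c("hay_concentrate", "hay"), period = periods
  )
  grid$delta_ct_shift <- 0
  mcr <- setNames(c(0, 1.2, 2.0, 2.6, 0), periods)
  pro <- setNames(c(0, -0.3, -0.4, -0.5, 0), periods)
  grid %>% mutate(delta_ct_shift = case_when(
    .data$target == "mcrA" ~ mcr[.data$period],
    .data$target == "protozoa" & .data$diet == "hay_concentrate" ~
      pro[.data$period],
    TRUE ~ 0
  ))
}

# Ground-truth phylum composition per period: Bacteroidetes expands and
# Firmicutes, Synergistetes, Verrucomicrobia and Archaea contract with dose
# (B:F ~ 75:17 at control); post sits near the low dose.
default_community <- function() {
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Synergistetes", "Verrucomicrobia", "Euryarchaeota",
             "Unclassified")
  props <- rbind(
    control = c(0.750, 0.170, 0.030, 0.015, 0.010, 0.010, 0.015),
    low     = c(0.780, 0.150, 0.032, 0.010, 0.008, 0.006, 0.014),
    mid     = c(0.800, 0.135, 0.034, 0.008, 0.006, 0.004, 0.013),
    high    = c(0.820, 0.120, 0.035, 0.006, 0.004, 0.002, 0.013),
    post    = c(0.780, 0.150, 0.032, 0.010, 0.008, 0.006, 0.014)
  )
  tibble(
    period = rep(rownames(props), times = ncol(props)),
    phylum = rep(phyla, each = nrow(props)),
    proportion = as.vector(props)
  )
}

#' Generate a complete synthetic chamber study
#'
#' Draws a full study bundle — chamber gas logs, daily dry-matter intakes,
#' rumen fermentation profiles, qPCR Ct tables and a 16S-style taxon count
#' table — from the configured ground truth. Animal-level values are drawn
#' as group mean + persistent animal effect + residual; chamber
#' concentrations come from a well-mixed steady-state forward model (outlet
#' ppm = background + emission / (flow x molar density x molar mass)) so the
#' flux estimator recovers the configured emission exactly in the noise-free
#' limit. Taxon counts are Dirichlet-multinomial. The RNG state is restored
#' on exit; a fixed seed fixes every generated value.
#'
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A `rumen_study` list: `chamber_log`, `dmi`, `scfa`, `qpcr_ct`,
#'   `taxa` tibbles plus `design`, `effects`, `seed`.
#' @export
generate_study <- function(design = study_design(), effects = effect_config(),
                           seed = 1L) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design")
  if (!inherits(effects, "effect_config")) abort("`effects` must be an effect_config")
  if (!all(design$diets %in% effects$means$diet)) {
    abort("`effects` lacks means for some diets in `design`")
  }
  if (!all(design$periods %in% effects$means$period)) {
    abort("`effects` lacks means for some periods in `design`")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  ns <- effects$noise_scale
  animals <- tibble(
    animal_id = sprintf("steer_%02d", seq_len(design$animals_per_diet *
                                                length(design$diets))),
    diet = rep(design$diets, each = design$animals_per_diet)
  )

  # persistent animal effects, one draw per animal x variable
  sd_tot <- setNames(effects$sems$sem * sqrt(effects$n_per_group) * ns,
                     effects$sems$variable)
  sd_animal <- sd_tot * sqrt(effects$icc_animal)
  sd_resid <- sd_tot * sqrt(1 - effects$icc_animal)
  animal_fx <- tidyr::expand_grid(animal_id = animals$animal_id,
                                  variable = effects$sems$variable) %>%
    mutate(animal_effect = rnorm(n(), 0, sd_animal[.data$variable]))

  nonneg <- c("dmi_kg", "ch4_g_kg_dmi", "h2_g_kg_dmi", "formate_mM",
              "nh3_n", "total_scfa_mM", .PCT_COLS)
  responses <- tidyr::expand_grid(animals, period = design$periods) %>%
    left_join(effects$means, by = c("diet", "period"),
              relationship = "many-to-many") %>%
    left_join(animal_fx, by = c("animal_id", "variable")) %>%
    mutate(
      value = .data$mean + .data$animal_effect +
        rnorm(n(), 0, sd_resid[.data$variable]),
      value = if_else(.data$variable %in% nonneg, pmax(.data$value, 0),
                      .data$value)
    ) %>%
    select("animal_id", "diet", "period", "variable", "value")

  wide <- responses %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value") %>%
    mutate(sample_id = paste(.data$animal_id, .data$period, sep = "_"))
  # renormalise drawn molar percentages so each profile closes to 100
  pct <- as.matrix(wide[.PCT_COLS])
  wide[.PCT_COLS] <- 100 * pct / rowSums(pct)

  dmi <- wide %>% select("animal_id", "diet", "period", dmi_kg = "dmi_kg")
  scfa <- wide %>%
    select("sample_id", "animal_id", "diet", "period", "total_scfa_mM",
           all_of(.PCT_COLS), "formate_mM", "ph", nh3_n = "nh3_n")

  chamber_log <- make_chamber_log(wide, design, effects)
  qpcr_ct <- make_qpcr(wide, design, effects)
  taxa <- make_taxa(wide, design, effects)

  structure(list(
    chamber_log = chamber_log, dmi = dmi, scfa = scfa, qpcr_ct = qpcr_ct,
    taxa = taxa, design = design, effects = effects, seed = as.integer(seed)
  ), class = "rumen_study")
}

# Forward model: constant emission mixed into chamber air at steady state.
make_chamber_log <- function(wide, design, effects) {
  ch <- effects$chamber
  gases <- names(ch$background_ppm)
  yield_col <- c(CH4 = "ch4_g_kg_dmi", H2 = "h2_g_kg_dmi")
  molar_density <- ch$pressure_kPa / (.GAS_CONSTANT * ch$temp_K)
  n_animals_total <- nrow(distinct(wide, .data$animal_id))
  grid <- tidyr::expand_grid(
    wide %>% select("animal_id", "diet", "period", "dmi_kg",
                    all_of(unname(yield_col))),
    day = seq_len(design$chamber_days_per_period),
    window = seq_len(design$windows_per_day),
    gas = gases
  )
  grid %>%
    mutate(
      chamber_id = sprintf("ch%d", (match(.data$animal_id,
        sort(unique(.data$animal_id))) - 1L) %% 4L + 1L),
      g_day = .data$dmi_kg * if_else(.data$gas == "CH4",
                                     .data$ch4_g_kg_dmi, .data$h2_g_kg_dmi),
      rate_g_min = .data$g_day / 1440,
      net_ppm = .data$rate_g_min /
        (ch$flow_L_min * 1e-6 * molar_density * unname(.MOLAR_MASS[.data$gas])),
      conc_background_ppm = ch$background_ppm[.data$gas],
      conc_chamber_ppm = .data$conc_background_ppm + .data$net_ppm +
        rnorm(n(), 0, ch$conc_noise_ppm * effects$noise_scale),
      flow_L_min = ch$flow_L_min, temp_K = ch$temp_K,
      pressure_kPa = ch$pressure_kPa,
      duration_s = design$window_duration_s
    ) %>%
    select("animal_id", "diet", "period", "chamber_id", "day", "window",
           "duration_s", "flow_L_min", "temp_K", "pressure_kPa", "gas",
           "conc_chamber_ppm", "conc_background_ppm")
}

make_qpcr <- function(wide, design, effects) {
  q <- effects$qpcr
  ns <- effects$noise_scale
  targets <- names(q$baseline_ct)
  samples <- wide %>% select("sample_id", "animal_id", "diet", "period")
  animal_ct_fx <- tidyr::expand_grid(
    animal_id = unique(samples$animal_id), target = targets) %>%
    mutate(animal_effect = rnorm(n(), 0, q$animal_sd * ns))
  tidyr::expand_grid(samples, target = targets,
                     replicate = seq_len(q$n_reps)) %>%
    left_join(q$shifts, by = c("target", "diet", "period")) %>%
    left_join(animal_ct_fx, by = c("animal_id", "target")) %>%
    mutate(
      ct = q$baseline_ct[.data$target] +
        dplyr::coalesce(.data$delta_ct_shift, 0) +
        dplyr::coalesce(.data$animal_effect, 0) +
        rnorm(n(), 0, q$rep_sd * ns)
    ) %>%
    select("sample_id", "animal_id", "diet", "period", "target",
           "replicate", "ct")
}

make_taxa <- function(wide, design, effects) {
  cm <- effects$community
  phyla_tbl <- cm$phyla %>% filter(.data$period %in% design$periods)
  phyla <- unique(phyla_tbl$phylum)
  k <- cm$taxa_per_phylum
  # fixed within-phylum weights (geometric decay), so truth is closed-form
  within <- 0.5^(seq_len(k) - 1); within <- within / sum(within)
  taxa_def <- tidyr::expand_grid(phylum = phyla, rank = seq_len(k)) %>%
    mutate(
      taxon_id = sprintf("otu_%s_%02d", tolower(substr(.data$phylum, 1, 4)),
                         .data$rank),
      domain = if_else(.data$phylum == "Euryarchaeota", "Archaea", "Bacteria"),
      lineage = sprintf(
        "d__%s;p__%s;c__%s_cl;o__%s_ord;f__%s_fam_%d;g__%s_gen_%d",
        .data$domain, .data$phylum, .data$phylum, .data$phylum,
        .data$phylum, .data$rank, .data$phylum, .data$rank),
      w_within = within[.data$rank]
    )
  samples <- wide %>% select("sample_id", "animal_id", "diet", "period")
  out <- purrr::pmap(samples, function(sample_id, animal_id, diet, period) {
    this_period <- phyla_tbl[phyla_tbl$period == period, ]
    p_phy <- this_period$proportion[match(taxa_def$phylum, this_period$phylum)]
    p <- p_phy * taxa_def$w_within
    alpha <- cm$dm_concentration * p / sum(p)
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g <- p
    counts <- as.integer(rmultinom(1, cm$reads_per_sample, g / sum(g)))
    tibble(sample_id = sample_id, animal_id = animal_id, diet = diet,
           period = period, taxon_id = taxa_def$taxon_id,
           lineage = taxa_def$lineage, count = counts)
  }) %>% bind_rows()
  out
}

#' Ground truth behind a synthetic bundle
#'
#' @param bundle A [generate_study()] result.
#' @return A long tibble of every generating parameter: the response means
#'   per diet x period (`component = "response_mean"`), the per-variable
#'   SEMs (`"sem"`), the true phylum proportions per period
#'   (`"phylum_proportion"`), derived true community ratios (`"community_ratio"`:
#'   BF, AB, SB, VB per period) and the qPCR Ct shifts (`"qpcr_delta_ct"`).
#' @export
truth_table <- function(bundle) {
  if (!inherits(bundle, "rumen_study")) abort("`bundle` must be a rumen_study")
  eff <- bundle$effects
  phyla <- eff$community$phyla %>%
    filter(.data$period %in% bundle$design$periods)
  bact <- phyla %>% filter(.data$phylum != "Euryarchaeota") %>%
    group_by(.data$period) %>%
    summarise(bacteria = sum(.data$proportion), .groups = "drop")
  wide_p <- phyla %>%
    tidyr::pivot_wider(names_from = "phylum", values_from = "proportion") %>%
    left_join(bact, by = "period")
  ratios <- wide_p %>%
    mutate(BF = .data$Bacteroidetes / .data$Firmicutes,
           AB = .data$Euryarchaeota / .data$bacteria,
           SB = .data$Synergistetes / .data$bacteria,
           VB = .data$Verrucomicrobia / .data$bacteria) %>%
    select("period", "BF", "AB", "SB", "VB") %>%
    tidyr::pivot_longer(-"period", names_to = "name", values_to = "value") %>%
    mutate(component = "community_ratio", diet = NA_character_)
  bind_rows(
    eff$means %>%
      filter(.data$period %in% bundle$design$periods) %>%
      mutate(component = "response_mean") %>%
      rename(name = "variable", value = "mean"),
    eff$sems %>%
      mutate(component = "sem", diet = NA_character_,
             period = NA_character_) %>%
      rename(name = "variable", value = "sem"),
    phyla %>%
      mutate(component = "phylum_proportion", diet = NA_character_) %>%
      rename(name = "phylum", value = "proportion"),
    ratios,
    eff$qpcr$shifts %>%
      filter(.data$period %in% bundle$design$periods) %>%
      mutate(component = "qpcr_delta_ct") %>%
      rename(name = "target", value = "delta_ct_shift")
  ) %>%
    select("component", "diet", "period", "name", "value")
}

#' @export
print.rumen_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic chamber study (seed %d): %d animals x %d periods\n",
    x$seed, nrow(distinct(x$dmi, .data$animal_id)), length(x$design$periods)))
  cat(sprintf("  chamber_log: %d rows | scfa: %d | qpcr_ct: %d | taxa: %d\n",
              nrow(x$chamber_log), nrow(x$scfa), nrow(x$qpcr_ct),
              nrow(x$taxa)))
  invisible(x)
}
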