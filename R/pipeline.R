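#' Validate pipeline input tables
#'
#' Schema and invariant checks for every table the pipeline consumes.
#' Always returns a report rather than throwing: one row per violation with
#' the table, offending row indices and a message.
#'
#' @param inputs A named list with any of `chamber_log`, `dmi`, `scfa`,
#'   `qpcr_ct`, `taxa` (e.g. a [generate_study()] bundle).
#' @return A tibble with columns `table`, `rows`, `message`; zero rows when
#'   everything passes.
#' @export
validate_inputs <- function(inputs) {
  v <- list()
  note <- function(table, rows, message) {
    v[[length(v) + 1]] <<- tibble(
      table = table,
      rows = paste(utils::head(rows, 10), collapse = ","),
      message = message)
  }
  need_cols <- function(df, cols, table) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      note(table, integer(0),
           paste0("missing columns: ", paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  check_rows <- function(df, ok, table, message) {
    if (any(!ok)) note(table, which(!ok), message)
  }

  if (!is.null(inputs$chamber_log)) {
    cl <- inputs$chamber_log
    if (need_cols(cl, c("chamber_id", "flow_L_min", "temp_K", "pressure_kPa",
                        "gas", "conc_chamber_ppm", "conc_background_ppm"),
                  "chamber_log")) {
      check_rows(cl, cl$flow_L_min > 0, "chamber_log", "flow must be positive")
      check_rows(cl, cl$temp_K > 0 & cl$pressure_kPa > 0, "chamber_log",
                 "temperature and pressure must be positive")
      check_rows(cl, cl$conc_chamber_ppm >= 0 & cl$conc_background_ppm >= 0,
                 "chamber_log", "concentrations must be non-negative")
      check_rows(cl, cl$gas %in% names(.MOLAR_MASS), "chamber_log",
                 "unknown gas label")
    }
  }
  if (!is.null(inputs$dmi)) {
    if (need_cols(inputs$dmi, c("animal_id", "period", "dmi_kg"), "dmi")) {
      check_rows(inputs$dmi, inputs$dmi$dmi_kg > 0, "dmi",
                 "dmi_kg must be positive")
    }
  }
  if (!is.null(inputs$scfa)) {
    sc <- inputs$scfa
    if (need_cols(sc, c("sample_id", "total_scfa_mM", "formate_mM",
                        .PCT_COLS), "scfa")) {
      psum <- rowSums(sc[.PCT_COLS])
      check_rows(sc, abs(psum - 100) <= 0.5, "scfa",
                 "molar percentages must sum to 100 +/- 0.5")
      check_rows(sc, sc$total_scfa_mM >= 0 & sc$formate_mM >= 0, "scfa",
                 "concentrations must be non-negative")
      check_rows(sc, apply(sc[.PCT_COLS] >= 0, 1, all), "scfa",
                 "molar percentages must be non-negative")
    }
  }
  if (!is.null(inputs$qpcr_ct)) {
    qc <- inputs$qpcr_ct
    if (need_cols(qc, c("sample_id", "target", "ct"), "qpcr_ct")) {
      check_rows(qc, qc$ct > 0 & qc$ct < 45, "qpcr_ct",
                 "Ct values must lie in (0, 45)")
    }
  }
  if (!is.null(inputs$taxa)) {
    tx <- inputs$taxa
    if (need_cols(tx, c("sample_id", "taxon_id", "lineage", "count"),
                  "taxa")) {
      check_rows(tx, tx$count >= 0, "taxa", "counts must be non-negative")
      check_rows(tx, grepl("d__", tx$lineage, fixed = TRUE), "taxa",
                 "every taxon needs a domain-level assignment")
      totals <- tx %>% group_by(.data$sample_id) %>%
        summarise(tot = sum(.data$count), .groups = "drop")
      if (any(totals$tot <= 0)) {
        note("taxa", which(totals$tot <= 0), "sample totals must be positive")
      }
    }
  }
  if (length(v)) bind_rows(v) else
    tibble(table = character(), rows = character(), message = character())
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> gas flux -> hydrogen stoichiometry ->
#' microbial quantification -> dose-response statistics, producing tidy
#' per-stage tables, a study summary shaped like a results table (variable
#' rows, diet x period means with LSD letters and contrast p-values) and a
#' reproducibility manifest. Stages whose inputs are absent are skipped
#' gracefully; a stage that fails aborts with the stage named.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `simulate` (list passed to [generate_study()]: `seed`, optional
#'   `noise_scale`, ...) or `inputs` (named list of CSV paths or data
#'   frames for `chamber_log`, `dmi`, `scfa`, `qpcr_ct`, `taxa`);
#'   `include_branched`, `dose_spacing`, `alpha`, `control_period`,
#'   `out_dir` (write CSVs + manifest there when given).
#' @return A `rumen_report` list with `emissions`, `hydrogen_balance`,
#'   `redirection`, `fold_changes`, `community_ratios`, `diversity`,
#'   `anova` (named list of fits), `letters`, `summary_table`,
#'   `violations`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(
    simulate = NULL, inputs = NULL, include_branched = FALSE,
    dose_spacing = NULL, alpha = 0.05, control_period = "control",
    out_dir = NULL
  ), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # --- ingest ---------------------------------------------------------
  inp <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      eff_args <- sim[intersect(names(sim), names(formals(effect_config)))]
      des_args <- sim[intersect(names(sim), names(formals(study_design)))]
      bundle <- generate_study(
        design = do.call(study_design, des_args),
        effects = do.call(effect_config, eff_args),
        seed = sim$seed %||% 1L)
      bundle[c("chamber_log", "dmi", "scfa", "qpcr_ct", "taxa")]
    } else if (!is.null(cfg$inputs)) {
      lapply(cfg$inputs, function(x) {
        if (is.character(x)) readr::read_csv(x, show_col_types = FALSE)
        else as_tibble(x)
      })
    } else {
      abort("config needs either `simulate` or `inputs`")
    }
  })

  violations <- validate_inputs(inp)
  if (nrow(violations)) {
    abort(paste0("pipeline stage 'validate' failed: ", nrow(violations),
                 " input violation(s); run validate_inputs() for details"))
  }

  # --- flux -----------------------------------------------------------
  emissions <- NULL
  if (!is.null(inp$chamber_log) && !is.null(inp$dmi)) {
    emissions <- stage("flux", {
      em <- daily_emission(inp$chamber_log, inp$dmi)
      meta <- distinct(inp$dmi[intersect(c("animal_id", "diet"),
                                         names(inp$dmi))])
      if ("diet" %in% names(meta)) em <- left_join(em, meta, by = "animal_id")
      em
    })
  }

  # --- stoichiometry --------------------------------------------------
  hb <- redirection <- NULL
  if (!is.null(inp$scfa)) {
    hb <- stage("stoichiometry", {
      hydrogen_balance(inp$scfa, include_branched = cfg$include_branched) %>%
        left_join(acetate_propionate_ratio(inp$scfa) %>%
                    select("sample_id", "a_p"), by = "sample_id") %>%
        husr_change_vs_control(control_period = cfg$control_period)
    })
  }
  if (!is.null(emissions)) {
    redirection <- stage("stoichiometry", suppressWarnings(
      h2_per_ch4_decrease(emissions, control_period = cfg$control_period)))
  }

  # --- microbial quantification ---------------------------------------
  folds <- ratios <- diversity <- NULL
  if (!is.null(inp$qpcr_ct)) {
    folds <- stage("quant", {
      targets <- setdiff(unique(inp$qpcr_ct$target), "total_bacteria")
      purrr::map(targets, function(tg) {
        ddct_fold_change(inp$qpcr_ct, target = tg,
                         calibrator_period = cfg$control_period) %>%
          mutate(target = tg, .before = 1)
      }) %>% bind_rows()
    })
  }
  if (!is.null(inp$taxa)) {
    ratios <- stage("quant", taxon_ratios(inp$taxa))
    diversity <- stage("quant", alpha_diversity(inp$taxa))
  }

  # --- dose-response statistics ---------------------------------------
  anova_fits <- list()
  letters_tbl <- NULL
  summary_table <- NULL
  if (!is.null(inp$scfa) && all(c("animal_id", "diet", "period") %in%
                                names(inp$scfa))) {
    stats_out <- stage("stats", {
      resp <- build_response_tables(inp, emissions, hb,
                                    control_period = cfg$control_period)
      fit_all_responses(resp, cfg$dose_spacing, cfg$alpha)
    })
    anova_fits <- stats_out$fits
    letters_tbl <- stats_out$letters
    summary_table <- stats_out$summary
  }

  manifest <- list(
    package = "rumenflux",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg[c("include_branched", "alpha", "control_period")],
    dose_spacing = cfg$dose_spacing,
    seed = cfg$simulate$seed,
    input_hashes = lapply(inp, rlang::hash)
  )

  report <- structure(list(
    emissions = emissions, hydrogen_balance = hb, redirection = redirection,
    fold_changes = folds, community_ratios = ratios, diversity = diversity,
    anova = anova_fits, letters = letters_tbl, summary_table = summary_table,
    violations = violations, manifest = manifest, inputs = inp
  ), class = "rumen_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# Long response table per analysis variable, dose periods only (the post
# period is a recovery check, not part of the dose response).
build_response_tables <- function(inp, emissions, hb, control_period) {
  dose_periods <- intersect(c(control_period, "low", "mid", "high"),
                            unique(inp$scfa$period))
  out <- inp$scfa %>%
    select("animal_id", "diet", "period", "total_scfa_mM",
           all_of(.PCT_COLS), "formate_mM", ph = "ph",
           dplyr::any_of("nh3_n")) %>%
    tidyr::pivot_longer(-c("animal_id", "diet", "period"),
                        names_to = "variable", values_to = "value")
  if (!is.null(hb)) {
    out <- bind_rows(out, hb %>%
      select("animal_id", "diet", "period", non_carboxyl_carbon =
               "non_carboxyl_carbon", husr = "husr", a_p = "a_p") %>%
      tidyr::pivot_longer(-c("animal_id", "diet", "period"),
                          names_to = "variable", values_to = "value"))
  }
  if (!is.null(emissions) && "diet" %in% names(emissions)) {
    out <- bind_rows(out, emissions %>%
      mutate(variable = paste0(tolower(.data$gas), "_g_kg_dmi")) %>%
      select("animal_id", "diet", "period", "variable",
             value = "g_per_kg_dmi"))
    out <- bind_rows(out, emissions %>%
      filter(.data$gas == "CH4") %>%
      distinct(.data$animal_id, .data$diet, .data$period, .data$dmi_kg) %>%
      mutate(variable = "dmi_kg") %>%
      select("animal_id", "diet", "period", "variable", value = "dmi_kg"))
  }
  out %>% filter(.data$period %in% dose_periods) %>%
    mutate(period = factor(.data$period, levels = dose_periods))
}

fit_all_responses <- function(resp, dose_spacing, alpha) {
  vars <- unique(resp$variable)
  fits <- list(); letters_list <- list(); summaries <- list()
  for (v in vars) {
    df <- resp %>% filter(.data$variable == v) %>%
      select("animal_id", "diet", dose = "period", "value")
    fit <- tryCatch(repeated_measures_anova(df, dose_spacing = dose_spacing),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[v]] <- fit
    lsd <- lsd_pairwise(fit, alpha = alpha)
    letters_list[[v]] <- mutate(lsd$letters, variable = v, .before = 1)
    ps <- setNames(fit$anova$p, fit$anova$effect)
    cps <- setNames(fit$contrasts$p, fit$contrasts$contrast)
    summaries[[v]] <- lsd$letters %>%
      mutate(cell = sprintf("%.3g%s", .data$mean,
                            if_else(is.na(.data$letters), "",
                                    .data$letters))) %>%
      select("diet", "dose", "cell") %>%
      tidyr::pivot_wider(names_from = c("diet", "dose"),
                         values_from = "cell") %>%
      mutate(variable = v,
             sem = sqrt(fit$ms_within / fit$n_animals_per_diet),
             p_dose = ps[["dose"]], p_diet = ps[["diet"]],
             p_interaction = ps[["dose:diet"]],
             contrast = paste0(
               c("L", "Q")[which(c(cps[["linear"]] %||% 1,
                                   cps[["quadratic"]] %||% 1) <= alpha)],
               collapse = ","),
             .before = 1)
  }
  list(fits = fits, letters = bind_rows(letters_list),
       summary = bind_rows(summaries))
}

#' Write a pipeline report to disk
#'
#' One tidy CSV per stage output plus a YAML manifest recording the seed,
#' flags and input hashes, sufficient to reproduce the run.
#'
#' @param report A `rumen_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("emissions", "hydrogen_balance", "redirection", "fold_changes",
              "community_ratios", "diversity", "letters", "summary_table",
              "violations")
  for (nm in tables) {
    if (!is.null(report[[nm]]) && nrow(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write a synthetic study bundle to disk
#'
#' One CSV per generated table plus a YAML run manifest (seed and design
#' parameters), so a bundle is reproducible from its manifest alone.
#'
#' @param bundle A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  if (!inherits(bundle, "rumen_study")) abort("`bundle` must be a rumen_study")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("chamber_log", "dmi", "scfa", "qpcr_ct", "taxa")) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  des <- bundle$design
  yaml::write_yaml(list(
    seed = bundle$seed,
    design = list(
      diets = des$diets, animals_per_diet = des$animals_per_diet,
      periods = des$periods,
      dose_g_per_100kg = as.list(des$dose_g_per_100kg),
      chamber_days_per_period = des$chamber_days_per_period,
      windows_per_day = des$windows_per_day,
      window_duration_s = des$window_duration_s),
    noise_scale = bundle$effects$noise_scale,
    icc_animal = bundle$effects$icc_animal
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.rumen_report <- function(x, ...) {
  cat("rumenflux pipeline report\n")
  for (nm in c("emissions", "hydrogen_balance", "redirection",
               "fold_changes", "community_ratios", "diversity")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  if (length(x$anova)) {
    cat(sprintf("  anova fits: %s\n",
                paste(names(x$anova), collapse = ", ")))
  }
  invisible(x)
}
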