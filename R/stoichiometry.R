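#' Metabolic-hydrogen stoichiometry from rumen SCFA profiles
#'
#' Rumen fermentation disposes of reducing equivalents (\[2H\]) by
#' methanogenesis, by expelling H2, or by incorporating them into reduced
#' fermentation products. Because metabolite *flows* are rarely measured in
#' vivo, concentrations serve as proxies: \[2H\] incorporated into SCFA
#' (HUSr) is estimated as 2 x propionate + 2 x butyrate + valerate (mM), and
#' \[2H\] incorporated into formate (HUFr) as the formate concentration
#' itself. The average chain length (ACL) of the straight-chain acid pool,
#' and from it the non-carboxyl SCFA carbon `(ACL - 1) x total SCFA`,
#' summarise the carbon (hence energy) retained in fermentation acids once
#' the carboxyl carbon — which carries no energy value to the animal — is
#' set aside.
#'
#' @details
#' The expected input is one row per sample with columns `total_scfa_mM`,
#' `formate_mM`, and molar percentages `pct_acetate`, `pct_propionate`,
#' `pct_n_butyrate`, `pct_iso_butyrate`, `pct_n_valerate`,
#' `pct_iso_valerate` (percentages of `total_scfa_mM`, summing to 100).
#' Conventions:
#' * ACL is computed over formate plus the straight-chain acids
#'   acetate/propionate/n-butyrate/n-valerate only; branched isomers are
#'   excluded (they are amino-acid fermentation products, not chain-
#'   elongation products of the same pool).
#' * The non-carboxyl multiplier `total SCFA` is the sum of the six measured
#'   SCFA; formate enters the ACL average but not the multiplier.
#' * `husr()` excludes branched isomers from the C4/C5 classes by default,
#'   consistent with the ACL convention; `include_branched = TRUE` adds
#'   2 x iso-butyrate + iso-valerate.
#' * The stored iso-valerate value typically includes co-eluting
#'   2-methylbutyrate; no attempt is made to split them.
#'
#' @param data A data frame of fermentation profiles (see Details).
#' @param include_branched Count branched C4/C5 isomers in HUSr?
#' @param pct_tolerance Allowed deviation of the molar-percentage sum from
#'   100. The default 0.5 suits raw laboratory profiles; published tables
#'   rounded to whole percent can miss 100 by a little more, so pass e.g.
#'   `1` when recomputing from printed means.
#' @return `hydrogen_balance()` returns the input id columns plus `husr`,
#'   `hufr`, `acl`, `non_carboxyl_carbon` and `formate_to_scfa_h`
#'   (HUFr/HUSr, `NA` with a warning where HUSr is zero).
#' @export
#' @examples
#' prof <- tibble::tibble(
#'   sample_id = "s1", total_scfa_mM = 91, formate_mM = 0,
#'   pct_acetate = 62, pct_propionate = 18, pct_n_butyrate = 11,
#'   pct_iso_butyrate = 1.66, pct_n_valerate = 3.76, pct_iso_valerate = 3.31
#' )
#' hydrogen_balance(prof)
hydrogen_balance <- function(data, include_branched = FALSE,
                             pct_tolerance = 0.5) {
  conc <- scfa_concentrations(data, pct_tolerance)
  husr <- 2 * conc$propionate_mM + 2 * conc$butyrate_c4_mM(include_branched) +
    conc$valerate_c5_mM(include_branched)
  acl <- scfa_acl(conc)
  out <- dplyr::bind_cols(
    data[intersect(c("sample_id", "animal_id", "period", "diet"), names(data))],
    tibble(
      husr = husr,
      hufr = conc$formate_mM,
      acl = acl,
      non_carboxyl_carbon = (acl - 1) * conc$total_mM
    )
  )
  out$formate_to_scfa_h <- ifelse(out$husr > 0, out$hufr / out$husr, NA_real_)
  if (anyNA(out$formate_to_scfa_h)) {
    warning("HUSr is zero for ", sum(is.na(out$formate_to_scfa_h)),
            " sample(s); formate_to_scfa_h set to NA", call. = FALSE)
  }
  as_tibble(out)
}

# Internal: percent -> mM conversion plus accessors for acid classes.
scfa_concentrations <- function(data, pct_tolerance = 0.5) {
  needed <- c("total_scfa_mM", "formate_mM", .PCT_COLS)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("missing SCFA columns: ", paste(missing, collapse = ", ")))
  }
  pct_sum <- rowSums(data[.PCT_COLS])
  off <- abs(pct_sum - 100) > pct_tolerance
  if (any(off)) {
    abort(paste0("molar percentages must sum to 100 +/- ", pct_tolerance,
                 "; found ", paste(round(pct_sum[off], 2), collapse = ", ")))
  }
  if (any(data$total_scfa_mM < 0) || any(data$formate_mM < 0) ||
      any(as.matrix(data[.PCT_COLS]) < 0)) {
    abort("SCFA concentrations and percentages must be non-negative")
  }
  to_mM <- function(col) data$total_scfa_mM * data[[col]] / 100
  list(
    total_mM = data$total_scfa_mM,
    formate_mM = data$formate_mM,
    acetate_mM = to_mM("pct_acetate"),
    propionate_mM = to_mM("pct_propionate"),
    n_butyrate_mM = to_mM("pct_n_butyrate"),
    iso_butyrate_mM = to_mM("pct_iso_butyrate"),
    n_valerate_mM = to_mM("pct_n_valerate"),
    iso_valerate_mM = to_mM("pct_iso_valerate"),
    butyrate_c4_mM = function(branched) {
      to_mM("pct_n_butyrate") + if (branched) to_mM("pct_iso_butyrate") else 0
    },
    valerate_c5_mM = function(branched) {
      to_mM("pct_n_valerate") + if (branched) to_mM("pct_iso_valerate") else 0
    }
  )
}

.PCT_COLS <- c("pct_acetate", "pct_propionate", "pct_n_butyrate",
               "pct_iso_butyrate", "pct_n_valerate", "pct_iso_valerate")

# ACL over formate + straight-chain acids; errors if the pool is empty.
scfa_acl <- function(conc) {
  num <- conc$formate_mM + 2 * conc$acetate_mM + 3 * conc$propionate_mM +
    4 * conc$n_butyrate_mM + 5 * conc$n_valerate_mM
  den <- conc$formate_mM + conc$acetate_mM + conc$propionate_mM +
    conc$n_butyrate_mM + conc$n_valerate_mM
  if (any(den <= 0)) {
    abort("average chain length undefined: formate + straight-chain acids are all zero")
  }
  num / den
}

#' Per-acid concentrations from molar percentages
#'
#' @inheritParams hydrogen_balance
#' @return The id columns plus one mM column per measured acid.
#' @export
scfa_mM <- function(data, pct_tolerance = 0.5) {
  conc <- scfa_concentrations(data, pct_tolerance)
  dplyr::bind_cols(
    data[intersect(c("sample_id", "animal_id", "period", "diet"), names(data))],
    tibble(
      acetate_mM = conc$acetate_mM, propionate_mM = conc$propionate_mM,
      n_butyrate_mM = conc$n_butyrate_mM, iso_butyrate_mM = conc$iso_butyrate_mM,
      n_valerate_mM = conc$n_valerate_mM, iso_valerate_mM = conc$iso_valerate_mM,
      formate_mM = conc$formate_mM, total_scfa_mM = conc$total_mM
    )
  )
}

#' Acetate:propionate ratio
#'
#' The classic marker of the fermentation shift under methanogenesis
#' inhibition: redirecting \[2H\] into propionate lowers A:P.
#'
#' @inheritParams hydrogen_balance
#' @return Input id columns plus `a_p`.
#' @export
acetate_propionate_ratio <- function(data) {
  if (any(data$pct_propionate <= 0)) {
    abort("acetate:propionate ratio undefined where propionate is zero")
  }
  dplyr::bind_cols(
    data[intersect(c("sample_id", "animal_id", "period", "diet"), names(data))],
    tibble(a_p = data$pct_acetate / data$pct_propionate)
  )
}

#' Percent change in HUSr relative to the control period
#'
#' Expresses the extra \[2H\] captured in SCFA under treatment as a percent
#' of the control-period HUSr. When `animal_id` is present the contrast is
#' within animal; otherwise treated samples are compared with the mean
#' control HUSr of their diet group.
#'
#' @param balance Output of [hydrogen_balance()], with a `period` column.
#' @param control_period Label of the calibrator period.
#' @return `balance` plus `husr_change_pct` (`NA` for control rows).
#' @export
husr_change_vs_control <- function(balance, control_period = "control") {
  if (!"period" %in% names(balance)) abort("`balance` needs a `period` column")
  ctl <- dplyr::filter(balance, .data$period == control_period)
  if (nrow(ctl) == 0) abort("no rows in the control period")
  keys <- intersect(c("animal_id", "diet"), names(balance))
  if ("animal_id" %in% keys) keys <- "animal_id"
  ref <- ctl %>%
    group_by(across(all_of(keys))) %>%
    summarise(.husr_control = mean(.data$husr), .groups = "drop")
  if (any(ref$.husr_control <= 0)) abort("control HUSr must be positive")
  balance %>%
    left_join(ref, by = keys) %>%
    mutate(husr_change_pct = if_else(
      .data$period == control_period, NA_real_,
      100 * (.data$husr - .data$.husr_control) / .data$.husr_control
    )) %>%
    select(-".husr_control")
}

#' H2 expelled per mole of CH4 decrease
#'
#' When methanogenesis is inhibited, each mole of CH4 no longer formed frees
#' 4 mol of H2-equivalents. Relating the H2 actually expelled to the CH4
#' decrease therefore measures how much of the freed \[2H\] escapes the
#' rumen rather than being redirected into fermentation products:
#' `mol_h2_per_mol_ch4_decrease = H2 (mol/day) / (CH4_control - CH4_treated)
#' (mol/day)`, and `h_fraction_recovered` is that ratio divided by 4 (a
#' value of 1 means all freed \[2H\] left as H2).
#'
#' @param emissions A daily-emission table (see [daily_emission()]) with
#'   columns `animal_id`, `period`, `gas`, `mol_day`, containing both CH4
#'   and H2 rows; optionally `diet`.
#' @param control_period Label of the reference period.
#' @return One row per animal x non-control period with the CH4 decrease,
#'   both redirection fields, and `ch4_decreased` flagging rows where the
#'   ratio is defined; where CH4 did not decrease both fields are `NA` with
#'   a warning.
#' @export
h2_per_ch4_decrease <- function(emissions, control_period = "control") {
  need <- c("animal_id", "period", "gas", "mol_day")
  if (!all(need %in% names(emissions))) {
    abort(paste0("`emissions` needs columns: ", paste(need, collapse = ", ")))
  }
  wide <- emissions %>%
    filter(.data$gas %in% c("CH4", "H2")) %>%
    select(all_of(intersect(c("animal_id", "diet", "period", "gas", "mol_day"),
                            names(emissions)))) %>%
    tidyr::pivot_wider(names_from = "gas", values_from = "mol_day")
  if (!all(c("CH4", "H2") %in% names(wide))) {
    abort("`emissions` must contain both CH4 and H2 rows")
  }
  ctl <- wide %>%
    filter(.data$period == control_period) %>%
    group_by(.data$animal_id) %>%
    summarise(ch4_control = mean(.data$CH4), .groups = "drop")
  if (nrow(ctl) == 0) abort("no rows in the control period")
  out <- wide %>%
    filter(.data$period != control_period) %>%
    left_join(ctl, by = "animal_id") %>%
    mutate(
      ch4_decrease_mol_day = .data$ch4_control - .data$CH4,
      ch4_decreased = .data$ch4_decrease_mol_day > 0,
      mol_h2_per_mol_ch4_decrease = if_else(
        .data$ch4_decreased, .data$H2 / .data$ch4_decrease_mol_day, NA_real_),
      h_fraction_recovered = .data$mol_h2_per_mol_ch4_decrease / 4
    ) %>%
    rename(ch4_mol_day = "CH4", h2_mol_day = "H2")
  if (any(!out$ch4_decreased)) {
    warning(sum(!out$ch4_decreased),
            " animal-period(s) show no CH4 decrease; ratio set to NA",
            call. = FALSE)
  }
  out
}

#' Percent decrease in gas yield relative to control
#'
#' @param treated,control Yields (g/kg DMI) or emissions on a common basis;
#'   vectors are paired elementwise.
#' @return `100 * (control - treated) / control`.
#' @export
#' @examples
#' percent_decrease_vs_control(15, 24) # 37.5
percent_decrease_vs_control <- function(treated, control) {
  if (any(control == 0)) abort("control value is zero; percent decrease undefined")
  100 * (control - treated) / control
}

#' Fold ratio between two group-mean yields
#'
#' Typically the H2 yield of one diet group over the other at a common dose.
#'
#' @param numerator,denominator Group-mean yields.
#' @return `numerator / denominator`.
#' @export
#' @examples
#' diet_fold_ratio(1.43, 0.83) # ~1.7
diet_fold_ratio <- function(numerator, denominator) {
  if (any(denominator == 0)) abort("denominator yield is zero")
  numerator / denominator
}
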