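#' Relative quantification of qPCR targets (2^-ddCt)
#'
#' Implements the comparative-Ct method for rumen microbial assays (e.g.
#' mcrA for methanogens, protozoal and fungal 18S/ITS targets) against a
#' total-bacteria reference assay, with the control period as calibrator.
#' Replicate Cts are averaged per sample and target; then per sample
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}, \eqn{\Delta\Delta Ct =
#' \Delta Ct - \overline{\Delta Ct}_{calibrator}} and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}. With assay efficiencies E supplied (from
#' standard curves) the efficiency-corrected (Pfaffl) form
#' \eqn{(1+E_t)^{-\Delta Ct_t^{rel}} / (1+E_r)^{-\Delta Ct_r^{rel}}} is used
#' instead; the default E = 1 for both assays reproduces 2^-ddCt exactly.
#'
#' @param ct Data frame with columns `sample_id`, `target`, `ct` (one row
#'   per replicate), `period`, and optionally `diet`. Cts must lie in
#'   (0, 45).
#' @param target Assay to quantify.
#' @param reference Reference assay label (default `"total_bacteria"`).
#' @param calibrator_period Period whose samples form the calibrator group.
#'   When `diet` is present the calibrator mean is taken within diet, since
#'   diet groups are separate sets of animals.
#' @param efficiency_target,efficiency_reference Amplification efficiencies
#'   in (0, 1.2]; 1 = perfect doubling.
#' @param sd_flag Replicate-Ct standard deviation (cycles) above which a
#'   sample is flagged.
#' @return One row per sample: mean Cts, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`, and `flagged`.
#' @export
ddct_fold_change <- function(ct, target, reference = "total_bacteria",
                             calibrator_period = "control",
                             efficiency_target = 1, efficiency_reference = 1,
                             sd_flag = 0.5) {
  need <- c("sample_id", "target", "ct", "period")
  if (!all(need %in% names(ct))) {
    abort(paste0("`ct` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(ct$ct <= 0 | ct$ct >= 45)) abort("Ct values must lie in (0, 45)")
  for (e in c(efficiency_target, efficiency_reference)) {
    if (e <= 0 || e > 1.2) abort("efficiencies must lie in (0, 1.2]")
  }
  keys <- intersect(c("sample_id", "period", "diet"), names(ct))
  means <- ct %>%
    filter(.data$target %in% c(!!target, reference)) %>%
    group_by(across(all_of(c(keys, "target")))) %>%
    summarise(ct_mean = mean(.data$ct),
              ct_sd = stats::sd(.data$ct), .groups = "drop")
  wide <- means %>%
    tidyr::pivot_wider(id_cols = all_of(keys), names_from = "target",
                       values_from = c("ct_mean", "ct_sd"))
  tcol <- paste0("ct_mean_", target)
  rcol <- paste0("ct_mean_", reference)
  if (!tcol %in% names(wide)) abort(paste0("no Ct rows for target ", target))
  if (!rcol %in% names(wide) || anyNA(wide[[rcol]])) {
    abort(paste0("missing reference (", reference, ") Cts for some samples"))
  }
  if (anyNA(wide[[tcol]])) abort("missing target Cts for some samples")
  wide$ct_target <- wide[[tcol]]
  wide$ct_reference <- wide[[rcol]]
  cal <- wide %>% filter(.data$period == calibrator_period)
  if (nrow(cal) == 0) abort("calibrator group is empty")
  grp <- intersect("diet", keys)
  cal_means <- cal %>%
    group_by(across(all_of(grp))) %>%
    summarise(cal_ct_target = mean(.data$ct_target),
              cal_ct_reference = mean(.data$ct_reference), .groups = "drop")
  out <- if (length(grp)) left_join(wide, cal_means, by = grp) else
    dplyr::cross_join(wide, cal_means)
  sds <- dplyr::coalesce(out[[paste0("ct_sd_", target)]], 0)
  out %>%
    mutate(
      delta_ct = .data$ct_target - .data$ct_reference,
      delta_delta_ct = .data$delta_ct -
        (.data$cal_ct_target - .data$cal_ct_reference),
      fold_change =
        (1 + efficiency_target)^(.data$cal_ct_target - .data$ct_target) /
        (1 + efficiency_reference)^(.data$cal_ct_reference - .data$ct_reference),
      flagged = sds > sd_flag
    ) %>%
    select(all_of(keys), "ct_target", "ct_reference", "delta_ct",
           "delta_delta_ct", "fold_change", "flagged")
}

#' qPCR standard curve
#'
#' A calibration line `Ct = slope * log10(copies) + intercept` fitted to a
#' dilution series of cloned PCR product. Amplification efficiency follows
#' as `10^(-1/slope) - 1` (slope -3.3219 corresponds to 100%).
#'
#' @param slope Cycles per log10 copies; must be negative.
#' @param intercept Ct at one copy.
#' @return A `standard_curve` list with `slope`, `intercept`, `efficiency`.
#' @export
#' @examples
#' standard_curve(-3.3219, 38)
standard_curve <- function(slope, intercept) {
  if (!is.numeric(slope) || slope >= 0) abort("slope must be negative")
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.2) {
    abort(sprintf("implied efficiency %.2f outside (0, 1.2]", eff))
  }
  structure(list(slope = slope, intercept = intercept, efficiency = eff),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f log10(copies) + %.2f (E = %.1f%%)\n",
              x$slope, x$intercept, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the calibration line: `copies = 10^((Ct - intercept)/slope)`,
#' after averaging replicate Cts per sample and target.
#'
#' @param ct Data frame with `sample_id`, `target`, `ct` replicate rows.
#' @param curve A [standard_curve()].
#' @param target Optional assay label to subset to before quantifying.
#' @return One row per sample (x target): `ct_mean` and `copies`.
#' @export
sc_quantify <- function(ct, curve, target = NULL) {
  if (!inherits(curve, "standard_curve")) {
    abort("`curve` must be a standard_curve object")
  }
  if (!is.null(target)) ct <- filter(ct, .data$target == !!target)
  if (nrow(ct) == 0) abort("no Ct rows to quantify")
  ct %>%
    group_by(across(all_of(intersect(
      c("sample_id", "target", "period", "diet"), names(ct))))) %>%
    summarise(ct_mean = mean(.data$ct), .groups = "drop") %>%
    mutate(copies = 10^((.data$ct_mean - curve$intercept) / curve$slope))
}

#' Taxon abundance ratio per sample
#'
#' Ratios of phylum- or domain-level abundances (Bacteroidetes:Firmicutes,
#' Archaea:Bacteria, ...) have been proposed as simple indices of rumen
#' hydrogen flow and relative methane output. Counts matching the numerator
#' lineage filter are summed and divided by the denominator sum, per sample;
#' being a ratio of sums from one sample the value is identical on raw
#' counts and on relative abundances.
#'
#' @param taxa Long-format count table: `sample_id`, `taxon_id`, `lineage`
#'   (semicolon-delimited `d__...;p__...;...` string), `count`, plus any
#'   sample metadata columns (`diet`, `period`, ...).
#' @param numerator,denominator Lineage filters, matched as fixed substrings
#'   of `lineage` (e.g. `"p__Bacteroidetes"`, `"d__Bacteria"`).
#' @return One row per sample with numerator/denominator sums and `ratio`
#'   (`NA` with a warning where the denominator is zero).
#' @export
taxon_ratio <- function(taxa, numerator, denominator) {
  need <- c("sample_id", "lineage", "count")
  if (!all(need %in% names(taxa))) {
    abort(paste0("`taxa` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(taxa$count < 0)) abort("counts must be non-negative")
  meta <- intersect(c("diet", "period", "animal_id"), names(taxa))
  out <- taxa %>%
    group_by(across(all_of(c("sample_id", meta)))) %>%
    summarise(
      numerator_count = sum(.data$count[grepl(numerator, .data$lineage,
                                              fixed = TRUE)]),
      denominator_count = sum(.data$count[grepl(denominator, .data$lineage,
                                                fixed = TRUE)]),
      .groups = "drop"
    ) %>%
    mutate(ratio = if_else(.data$denominator_count > 0,
                           .data$numerator_count / .data$denominator_count,
                           NA_real_))
  if (anyNA(out$ratio)) {
    warning(sum(is.na(out$ratio)), " sample(s) have zero denominator counts",
            call. = FALSE)
  }
  out
}

#' Preset community ratios
#'
#' Computes any of the built-in indices: `BF` (Bacteroidetes:Firmicutes),
#' `AB` (Archaea:Bacteria), `SB` (Synergistetes:Bacteria), `VB`
#' (Verrucomicrobia:Bacteria).
#'
#' @inheritParams taxon_ratio
#' @param presets Character vector of preset codes.
#' @return Stacked [taxon_ratio()] output with a `preset` column.
#' @export
taxon_ratios <- function(taxa, presets = c("BF", "AB", "SB", "VB")) {
  defs <- list(
    BF = c("p__Bacteroidetes", "p__Firmicutes"),
    AB = c("d__Archaea", "d__Bacteria"),
    SB = c("p__Synergistetes", "d__Bacteria"),
    VB = c("p__Verrucomicrobia", "d__Bacteria")
  )
  presets <- match.arg(presets, names(defs), several.ok = TRUE)
  purrr::map(presets, function(p) {
    taxon_ratio(taxa, defs[[p]][1], defs[[p]][2]) %>%
      mutate(preset = p, .before = 1)
  }) %>%
    bind_rows()
}

#' Per-sample alpha diversity
#'
#' Observed richness (taxa with count > 0), the bias-corrected Chao1
#' estimator \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} built from singleton and
#' doubleton counts (the +1 keeps it defined with no doubletons), and
#' Shannon entropy \eqn{H = -\sum p_i \ln p_i} over present taxa.
#'
#' @inheritParams taxon_ratio
#' @return One row per sample: `observed`, `chao1`, `shannon`, `total_count`.
#' @export
alpha_diversity <- function(taxa) {
  need <- c("sample_id", "count")
  if (!all(need %in% names(taxa))) {
    abort(paste0("`taxa` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(taxa$count < 0)) abort("counts must be non-negative")
  meta <- intersect(c("diet", "period", "animal_id"), names(taxa))
  taxa %>%
    group_by(across(all_of(c("sample_id", meta)))) %>%
    summarise(
      observed = sum(.data$count > 0),
      chao1 = sum(.data$count > 0) +
        sum(.data$count == 1) * (sum(.data$count == 1) - 1) /
          (2 * (sum(.data$count == 2) + 1)),
      shannon = {
        p <- .data$count[.data$count > 0] / sum(.data$count)
        if (sum(.data$count) == 0) abort("empty sample: all counts zero")
        -sum(p * log(p))
      },
      total_count = sum(.data$count),
      .groups = "drop"
    )
}
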