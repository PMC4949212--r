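#' Orthogonal polynomial contrasts over dose levels
#'
#' Coefficient vectors for partitioning a dose response into linear,
#' quadratic, ... components. For equally spaced doses the classical
#' integer tables are returned (e.g. linear (-3,-1,1,3) and quadratic
#' (1,-1,-1,1) for four levels); for arbitrary spacing the vectors are built
#' by Gram-Schmidt orthogonalisation of the powers of the dose scores and
#' are zero-sum and mutually orthogonal in either case.
#'
#' @param n_levels Number of dose levels (>= 2; >= 3 for a quadratic term).
#' @param spacing Optional strictly increasing numeric dose values; default
#'   is equal spacing `1:n_levels`.
#' @param degree Highest polynomial degree to return (default
#'   `min(n_levels - 1, 3)`).
#' @return A tibble with `score` and one column per contrast
#'   (`linear`, `quadratic`, `cubic`, ...).
#' @export
#' @examples
#' orthogonal_poly_contrasts(4)
#' orthogonal_poly_contrasts(4, spacing = c(0, 1, 1.6, 2.6))
orthogonal_poly_contrasts <- function(n_levels, spacing = NULL,
                                      degree = min(n_levels - 1, 3)) {
  if (n_levels < 2) abort("need at least 2 dose levels")
  if (is.null(spacing)) spacing <- seq_len(n_levels)
  if (length(spacing) != n_levels) {
    abort("`spacing` must have one value per level")
  }
  if (any(diff(spacing) <= 0)) abort("`spacing` must be strictly increasing")
  if (degree >= n_levels) abort("degree must be < n_levels")
  pm <- stats::poly(spacing, degree = degree)
  cols <- lapply(seq_len(degree), function(k) {
    v <- pm[, k]
    scaled <- v / min(abs(v[abs(v) > 1e-10]))
    if (all(abs(scaled - round(scaled)) < 1e-8)) round(scaled) else v
  })
  names(cols) <- c("linear", "quadratic", "cubic",
                   paste0("deg", seq_len(max(0, degree - 3)) + 3))[seq_len(degree)]
  dplyr::bind_cols(tibble(score = spacing), as_tibble(cols))
}

#' Dose x diet repeated-measures ANOVA with animal as experimental unit
#'
#' Fits the balanced split-plot decomposition for a design in which each
#' animal receives one diet (between-subjects factor) and is measured at
#' every dose level (within-subjects factor):
#' `SS_total = SS_diet + SS_animal(diet) + SS_dose + SS_dose:diet +
#' SS_residual`. Diet is tested against the animal-within-diet mean square;
#' dose, the dose x diet interaction and the polynomial dose contrasts are
#' tested against the within-subjects residual (dose x animal-within-diet)
#' mean square.
#'
#' @param data Data frame with columns `animal_id`, `diet`, `dose` (level
#'   label or value) and `value`. The design must be complete and balanced:
#'   every animal of every diet observed exactly once at every dose, with
#'   the same number of animals per diet, and at least two of each.
#' @param dose_spacing Optional numeric dose values for the polynomial
#'   contrasts (default: levels treated as equally spaced ordinal
#'   categories, the usual statistics-package convention).
#' @return An object of class `rm_anova` with components `anova`
#'   (effect/df/SS/MS/F/p tibble), `contrasts`, `means` (diet x dose cell
#'   means), `dose_means`, `ms_within`, `df_within`, and design sizes.
#'   `tidy()`, `glance()`, [lsd_pairwise()] and [autoplot.rm_anova()]
#'   consume it.
#' @export
repeated_measures_anova <- function(data, dose_spacing = NULL) {
  need <- c("animal_id", "diet", "dose", "value")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyNA(data$value)) abort("missing response values are not supported")
  data <- mutate(data, across(c("animal_id", "diet"), as.character))
  dose_levels <- if (is.factor(data$dose)) levels(data$dose) else
    unique(data$dose)
  data$dose <- factor(data$dose, levels = dose_levels)

  diet_of <- distinct(data, .data$animal_id, .data$diet)
  if (any(duplicated(diet_of$animal_id))) {
    abort("each animal must appear in exactly one diet")
  }
  tab <- table(data$animal_id, data$dose)
  if (any(tab != 1)) {
    abort("unbalanced design: every animal must be observed exactly once at every dose")
  }
  per_diet <- table(diet_of$diet)
  if (length(unique(per_diet)) != 1) {
    abort("unbalanced design: diets must have equal numbers of animals")
  }
  a <- length(per_diet)              # diets
  n <- unname(per_diet[1])           # animals per diet
  d <- nlevels(data$dose)            # dose levels
  if (n < 2) abort("need at least 2 animals per diet")
  if (d < 2) abort("need at least 2 dose levels")

  gm <- mean(data$value)
  diet_means <- data %>% group_by(.data$diet) %>%
    summarise(mean = mean(.data$value), .groups = "drop")
  animal_means <- data %>% group_by(.data$animal_id, .data$diet) %>%
    summarise(mean = mean(.data$value), .groups = "drop")
  dose_means <- data %>% group_by(.data$dose) %>%
    summarise(mean = mean(.data$value), .groups = "drop") %>%
    arrange(.data$dose)
  cell_means <- data %>% group_by(.data$diet, .data$dose) %>%
    summarise(mean = mean(.data$value), n = n(), .groups = "drop")

  ss_diet <- n * d * sum((diet_means$mean - gm)^2)
  ss_animal <- d * sum((animal_means$mean -
    diet_means$mean[match(animal_means$diet, diet_means$diet)])^2)
  ss_dose <- a * n * sum((dose_means$mean - gm)^2)
  cm <- cell_means %>%
    left_join(rename(diet_means, diet_mean = "mean"), by = "diet") %>%
    left_join(rename(dose_means, dose_mean = "mean"), by = "dose")
  ss_int <- n * sum((cm$mean - cm$diet_mean - cm$dose_mean + gm)^2)
  ss_total <- sum((data$value - gm)^2)
  ss_resid <- max(ss_total - ss_diet - ss_animal - ss_dose - ss_int, 0)

  df <- c(diet = a - 1, animal = a * (n - 1), dose = d - 1,
          int = (a - 1) * (d - 1), resid = a * (n - 1) * (d - 1))
  ms <- c(ss_diet, ss_animal, ss_dose, ss_int, ss_resid) / df
  zero_var <- ms[["animal"]] <= 1e-12 * max(ss_total, 1) &&
    ms[["resid"]] <= 1e-12 * max(ss_total, 1)
  f_of <- function(num, err) if (ms[[err]] > 0) ms[[num]] / ms[[err]] else NA_real_
  fs <- c(f_of("diet", "animal"), NA, f_of("dose", "resid"),
          f_of("int", "resid"), NA)
  ps <- ifelse(is.na(fs), NA,
               pf(fs, df[c("diet", "animal", "dose", "int", "resid")],
                  df[c("animal", "animal", "resid", "resid", "resid")],
                  lower.tail = FALSE))

  anova_tbl <- tibble(
    effect = c("diet", "animal(diet)", "dose", "dose:diet", "residual"),
    df = as.integer(df),
    ss = c(ss_diet, ss_animal, ss_dose, ss_int, ss_resid),
    ms = ms, f = fs, p = ps
  )

  ctr <- orthogonal_poly_contrasts(d, spacing = dose_spacing,
                                   degree = min(d - 1, 2))
  cnames <- setdiff(names(ctr), "score")
  contrasts_tbl <- purrr::map(cnames, function(nm) {
    cc <- ctr[[nm]]
    est <- sum(cc * dose_means$mean)
    ss_c <- est^2 / (sum(cc^2) / (a * n))
    fc <- if (ms[["resid"]] > 0) ss_c / ms[["resid"]] else NA_real_
    tibble(contrast = nm, estimate = est, ss = ss_c, f = fc,
           p = if (is.na(fc)) NA_real_ else
             pf(fc, 1, df[["resid"]], lower.tail = FALSE))
  }) %>% bind_rows()

  structure(list(
    anova = anova_tbl, contrasts = contrasts_tbl,
    means = cell_means %>% select("diet", "dose", "mean", "n"),
    dose_means = dose_means, diet_means = diet_means,
    ms_within = ms[["resid"]], df_within = unname(df[["resid"]]),
    ms_animal = ms[["animal"]], df_animal = unname(df[["animal"]]),
    n_diets = a, n_animals_per_diet = n, n_doses = d,
    dose_levels = levels(data$dose), zero_variance = zero_var
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %d diets x %d doses, %d animals/diet\n",
              x$n_diets, x$n_doses, x$n_animals_per_diet))
  print(as.data.frame(x$anova), digits = 4, row.names = FALSE)
  cat("Polynomial dose contrasts:\n")
  print(as.data.frame(x$contrasts), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fisher's LSD pairwise dose comparisons with letter groupings
#'
#' Unadjusted pairwise t-tests between dose means within each diet, using
#' the within-subjects residual mean square and its degrees of freedom, as
#' is conventional after a significant repeated-measures F test. Dose means
#' within a diet that share a letter are not significantly different at
#' `alpha`.
#'
#' @param fit An [repeated_measures_anova()] fit.
#' @param alpha Significance level for declaring a pair different.
#' @return A list with `pairs` (per-diet pairwise differences, t, p) and
#'   `letters` (per diet x dose compact letter display). With zero error
#'   variance the letters are suppressed (`NA`) and `flagged` is set.
#' @export
lsd_pairwise <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "rm_anova")) abort("`fit` must be an rm_anova object")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  n_cell <- fit$n_animals_per_diet
  se_diff <- sqrt(2 * fit$ms_within / n_cell)
  flagged <- !is.finite(se_diff) || se_diff <= 0
  pairs <- fit$means %>%
    group_by(.data$diet) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$dose)
      idx <- utils::combn(nrow(df), 2)
      tibble(
        dose_1 = df$dose[idx[1, ]], dose_2 = df$dose[idx[2, ]],
        diff = df$mean[idx[1, ]] - df$mean[idx[2, ]],
        se = se_diff,
        t = if (flagged) NA_real_ else .data$diff / se_diff,
        p = if (flagged) NA_real_ else
          2 * pt(abs(.data$diff / se_diff), fit$df_within, lower.tail = FALSE)
      )
    }) %>%
    ungroup()
  letters_tbl <- fit$means %>%
    group_by(.data$diet) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, dplyr::desc(.data$mean))
      if (flagged) return(mutate(df, letters = NA_character_))
      dp <- filter(pairs, .data$diet == key$diet)
      sig <- matrix(FALSE, nrow(df), nrow(df),
                    dimnames = list(as.character(df$dose), as.character(df$dose)))
      for (i in seq_len(nrow(dp))) {
        if (!is.na(dp$p[i]) && dp$p[i] <= alpha) {
          sig[as.character(dp$dose_1[i]), as.character(dp$dose_2[i])] <- TRUE
          sig[as.character(dp$dose_2[i]), as.character(dp$dose_1[i])] <- TRUE
        }
      }
      mutate(df, letters = compact_letters(as.character(df$dose), sig))
    }) %>%
    ungroup()
  list(pairs = pairs, letters = letters_tbl, alpha = alpha, flagged = flagged)
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix over the (ordered) mean labels; TRUE = significantly different.
compact_letters <- function(labels, sig) {
  cols <- list(labels) # each column = set of labels sharing a letter
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j <= i || !sig[labels[i], labels[j]]) next
      hit <- which(vapply(cols, function(s)
        all(c(labels[i], labels[j]) %in% s), logical(1)))
      for (h in hit) {
        s <- cols[[h]]
        cols[[h]] <- setdiff(s, labels[i])
        cols <- append(cols, list(setdiff(s, labels[j])))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) {
        for (v in seq_along(cols)) {
          if (u != v && keep[u] && keep[v] &&
              all(cols[[u]] %in% cols[[v]]) &&
              length(cols[[u]]) < length(cols[[v]])) keep[u] <- FALSE
          if (u != v && keep[u] && keep[v] && u > v &&
              setequal(cols[[u]], cols[[v]])) keep[u] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by first (highest) mean they contain, assign letters
  first_idx <- vapply(cols, function(s) min(match(s, labels)), numeric(1))
  cols <- cols[order(first_idx)]
  vapply(labels, function(l) {
    paste0(letters[which(vapply(cols, function(s) l %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}
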