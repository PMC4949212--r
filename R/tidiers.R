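#' Tidy a repeated-measures ANOVA fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One row per effect and polynomial contrast: `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`.
#' @export
tidy.rm_anova <- function(x, ...) {
  bind_rows(
    x$anova %>%
      select(term = "effect", df = "df", sumsq = "ss", meansq = "ms",
             statistic = "f", p.value = "p"),
    x$contrasts %>%
      mutate(df = 1L, meansq = .data$ss) %>%
      select(term = "contrast", "df", sumsq = "ss", "meansq",
             statistic = "f", p.value = "p")
  )
}

#' Glance at a repeated-measures ANOVA fit
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with design sizes, the two error mean squares
#'   and the omnibus p-values.
#' @export
glance.rm_anova <- function(x, ...) {
  ps <- setNames(x$anova$p, x$anova$effect)
  tibble(
    n_diets = x$n_diets, n_animals_per_diet = x$n_animals_per_diet,
    n_doses = x$n_doses,
    ms_animal = x$ms_animal, ms_within = x$ms_within,
    df_animal = x$df_animal, df_within = x$df_within,
    p_diet = ps[["diet"]], p_dose = ps[["dose"]],
    p_interaction = ps[["dose:diet"]],
    zero_variance = x$zero_variance
  )
}
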