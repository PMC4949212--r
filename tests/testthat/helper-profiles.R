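# A fermentation profile row in the package's column layout.
make_profile <- function(sample_id = "s1", total = 88, formate = 0,
                         ac = 62, pr = 18, nbu = 12, ibu = 1.53,
                         nva = 3.45, iva = 3.05, ...) {
  tibble::tibble(
    sample_id = sample_id, total_scfa_mM = total, formate_mM = formate,
    pct_acetate = ac, pct_propionate = pr, pct_n_butyrate = nbu,
    pct_iso_butyrate = ibu, pct_n_valerate = nva, pct_iso_valerate = iva,
    ...
  )
}

# Reported group-mean profile for one diet x period, as a profile row.
reference_profile <- function(diet, period) {
  m <- reference_means()$means
  m <- m[m$diet == diet & m$period == period, ]
  v <- stats::setNames(m$mean, m$variable)
  make_profile(
    sample_id = paste(diet, period, sep = "_"),
    total = v[["total_scfa_mM"]], formate = v[["formate_mM"]],
    ac = v[["pct_acetate"]], pr = v[["pct_propionate"]],
    nbu = v[["pct_n_butyrate"]], ibu = v[["pct_iso_butyrate"]],
    nva = v[["pct_n_valerate"]], iva = v[["pct_iso_valerate"]]
  )
}

# Independent hand oracle for the non-carboxyl SCFA carbon convention:
# ACL over formate + straight-chain acids, six-acid total as multiplier.
oracle_non_carboxyl <- function(total, formate, ac, pr, nbu, nva) {
  conc <- total * c(ac, pr, nbu, nva) / 100
  num <- formate + sum(c(2, 3, 4, 5) * conc)
  den <- formate + sum(conc)
  (num / den - 1) * total
}

# Balanced 2-diet x n-animal x d-dose response table from cell means.
make_response <- function(cell_means, n_animals = 4, sd_animal = 0,
                          sd_resid = 0) {
  diets <- rownames(cell_means)
  doses <- colnames(cell_means)
  rows <- list()
  idx <- 0
  for (di in diets) {
    for (an in seq_len(n_animals)) {
      idx <- idx + 1
      a_eff <- stats::rnorm(1, 0, sd_animal)
      for (do in doses) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal_id = sprintf("a%02d", idx), diet = di, dose = do,
          value = cell_means[di, do] + a_eff + stats::rnorm(1, 0, sd_resid)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$dose <- factor(out$dose, levels = doses)
  out
}
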