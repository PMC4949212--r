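test_that("equally spaced polynomial contrasts reproduce the classical tables", {
  c4 <- orthogonal_poly_contrasts(4)
  expect_equal(c4$linear, c(-3, -1, 1, 3))
  expect_equal(c4$quadratic, c(1, -1, -1, 1))
  c3 <- orthogonal_poly_contrasts(3)
  expect_equal(c3$linear, c(-1, 0, 1))
  expect_equal(c3$quadratic, c(1, -2, 1))
  expect_error(orthogonal_poly_contrasts(1), "at least 2")
})

test_that("contrasts for actual dose spacing are zero-sum and orthogonal", {
  cc <- orthogonal_poly_contrasts(4, spacing = c(0, 1, 1.6, 2.6))
  expect_equal(sum(cc$linear), 0, tolerance = 1e-12)
  expect_equal(sum(cc$quadratic), 0, tolerance = 1e-12)
  expect_equal(sum(cc$linear * cc$quadratic), 0, tolerance = 1e-12)
  if ("cubic" %in% names(cc)) {
    expect_equal(sum(cc$cubic), 0, tolerance = 1e-12)
    expect_equal(sum(cc$linear * cc$cubic), 0, tolerance = 1e-12)
    expect_equal(sum(cc$quadratic * cc$cubic), 0, tolerance = 1e-12)
  }
  # property: any admissible spacing gives zero-sum orthogonal vectors
  set.seed(31)
  for (i in 1:10) {
    sp <- sort(stats::runif(5, 0, 10))
    ci <- orthogonal_poly_contrasts(5, spacing = sp, degree = 3)
    m <- as.matrix(ci[c("linear", "quadratic", "cubic")])
    expect_equal(colSums(m), c(linear = 0, quadratic = 0, cubic = 0),
                 tolerance = 1e-12)
    expect_equal(sum(m[, 1] * m[, 2]), 0, tolerance = 1e-12)
    expect_equal(sum(m[, 1] * m[, 3]), 0, tolerance = 1e-12)
    expect_equal(sum(m[, 2] * m[, 3]), 0, tolerance = 1e-12)
  }
  expect_error(orthogonal_poly_contrasts(4, spacing = c(0, 1, 1, 2)),
               "increasing")
})

test_that("split-plot F statistics agree with the aov error-strata oracle", {
  set.seed(11)
  for (i in 1:5) {
    cm <- matrix(stats::rnorm(8, 20, 4), 2, 4,
                 dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
    df <- make_response(cm, n_animals = 4, sd_animal = 2, sd_resid = 1)
    fit <- repeated_measures_anova(df)

    oracle <- stats::aov(value ~ diet * dose + Error(animal_id),
                         data = df)
    s <- summary(oracle)
    between <- s[["Error: animal_id"]][[1]]
    within <- s[["Error: Within"]][[1]]
    expect_equal(fit$anova$f[fit$anova$effect == "diet"],
                 between["diet", "F value"], tolerance = 1e-8)
    expect_equal(fit$anova$f[fit$anova$effect == "dose"],
                 within["dose", "F value"], tolerance = 1e-8)
    expect_equal(fit$anova$f[fit$anova$effect == "dose:diet"],
                 within["diet:dose", "F value"], tolerance = 1e-8)
    expect_equal(fit$anova$df,
                 c(1L, 6L, 3L, 3L, 18L))
  }
})

test_that("sums of squares partition exactly in the balanced case", {
  set.seed(13)
  cm <- matrix(stats::rnorm(8, 10, 3), 2, 4,
               dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  df <- make_response(cm, sd_animal = 1.5, sd_resid = 0.8)
  fit <- repeated_measures_anova(df)
  ss_total <- sum((df$value - mean(df$value))^2)
  expect_equal(sum(fit$anova$ss), ss_total, tolerance = 1e-10)
})

test_that("degenerate designs and responses are handled explicitly", {
  cm <- matrix(5, 2, 4, dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  df <- make_response(cm)
  fit <- repeated_measures_anova(df)
  expect_true(fit$zero_variance)
  expect_true(all(is.na(fit$anova$f) | fit$anova$f == 0))
  lsd <- lsd_pairwise(fit)
  expect_true(lsd$flagged)
  expect_true(all(is.na(lsd$letters$letters)))

  # unbalanced and malformed designs are rejected
  expect_error(repeated_measures_anova(df[-1, ]), "unbalanced")
  df_swap <- df
  df_swap$diet[which(df_swap$animal_id == "a01")[1]] <- "d2"
  expect_error(repeated_measures_anova(df_swap), "exactly one diet")
  df_small <- dplyr::filter(df, animal_id %in% c("a01", "a05"))
  expect_error(repeated_measures_anova(df_small), "at least 2 animals")
})

test_that("a pure linear dose effect loads on the linear contrast only", {
  cm <- matrix(rep(c(10, 12, 14, 16), each = 2), 2, 4,
               dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  set.seed(17)
  df <- make_response(cm, sd_animal = 1, sd_resid = 1e-3)
  fit <- repeated_measures_anova(df)
  ctr <- fit$contrasts
  expect_gt(ctr$ss[ctr$contrast == "linear"],
            1e4 * ctr$ss[ctr$contrast == "quadratic"])
  expect_gt(ctr$f[ctr$contrast == "linear"], 1e6)
  expect_equal(ctr$estimate[ctr$contrast == "quadratic"], 0,
               tolerance = 1e-2)
})

test_that("LSD letters separate means according to the error variance", {
  # equal true means (p2 = p3) share a letter; distant means do not
  cm <- matrix(rep(c(0, 50, 50, 100), each = 2), 2, 4,
               dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  set.seed(1)
  df <- make_response(cm, sd_animal = 0.5, sd_resid = 0.5)
  fit <- repeated_measures_anova(df)
  lsd <- lsd_pairwise(fit)
  l1 <- lsd$letters |> dplyr::filter(diet == "d1") |> dplyr::arrange(dose)
  shared_23 <- any(strsplit(l1$letters[l1$dose == "p2"], "")[[1]] %in%
                     strsplit(l1$letters[l1$dose == "p3"], "")[[1]])
  expect_true(shared_23)
  expect_false(any(strsplit(l1$letters[l1$dose == "p1"], "")[[1]] %in%
                     strsplit(l1$letters[l1$dose == "p4"], "")[[1]]))
  # widely separated means at tiny error variance get all-distinct letters
  cm2 <- matrix(rep(c(0, 100, 200, 300), each = 2), 2, 4,
                dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  set.seed(6)
  df2 <- make_response(cm2, sd_animal = 0.1, sd_resid = 0.1)
  lsd2 <- lsd_pairwise(repeated_measures_anova(df2))
  for (d in c("d1", "d2")) {
    lets <- lsd2$letters$letters[lsd2$letters$diet == d]
    expect_equal(sort(unname(lets)), c("a", "b", "c", "d"))
  }
  expect_false(lsd2$flagged)
  expect_error(lsd_pairwise(fit, alpha = 1.5), "alpha")
})

test_that("the dose-separation letter pattern is recovered at study effect sizes", {
  # CH4-yield-like means with the study's pooled SEM-derived SDs
  cm <- matrix(rep(c(24, 19, 15, 10), each = 2), 2, 4, byrow = FALSE,
               dimnames = list(c("d1", "d2"),
                               c("control", "low", "mid", "high")))
  sd_tot <- 1.40 * 2
  ok <- 0L
  set.seed(99)
  for (i in 1:100) {
    df <- make_response(cm, sd_animal = sd_tot * sqrt(0.5),
                        sd_resid = sd_tot * sqrt(0.5))
    lsd <- lsd_pairwise(repeated_measures_anova(df))
    lets <- lsd$letters |> dplyr::filter(diet == "d1")
    l <- stats::setNames(lets$letters, as.character(lets$dose))
    shared <- function(x, y) {
      any(strsplit(l[[x]], "")[[1]] %in% strsplit(l[[y]], "")[[1]])
    }
    # control must separate from mid and high (the reported a vs b/bc split)
    if (!shared("control", "mid") && !shared("control", "high")) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})

test_that("tidy and glance return broom-shaped summaries", {
  set.seed(3)
  cm <- matrix(stats::rnorm(8, 15, 3), 2, 4,
               dimnames = list(c("d1", "d2"), paste0("p", 1:4)))
  df <- make_response(cm, sd_animal = 1, sd_resid = 1)
  fit <- repeated_measures_anova(df)
  td <- tidy(fit)
  expect_true(all(c("term", "df", "sumsq", "statistic", "p.value") %in%
                    names(td)))
  expect_setequal(td$term, c("diet", "animal(diet)", "dose", "dose:diet",
                             "residual", "linear", "quadratic"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(gl$p_dose >= 0 & gl$p_dose <= 1))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
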