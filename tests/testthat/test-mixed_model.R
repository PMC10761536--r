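test_that("difference design has one row per animal-matrix with the codings", {
  tab <- impute_lloq(simulate_study(test_config(seed = 5)))
  des <- build_difference_design(tab, "glucose", "PrecisionXtra")
  expect_equal(nrow(des), 56) # 28 animals x 2 matrices
  expect_setequal(unique(des$matrix_wb), c(0, 1))
  expect_equal(sum(des$matrix_wb), 28)
  expect_true(all(des$sex_m %in% c(0, 1)))
  # continuous covariates are mean-centred
  expect_equal(mean(des$weight_c), 0, tolerance = 1e-12)
  expect_equal(mean(des$pcv_c), 0, tolerance = 1e-12)
  # response is POC minus reference
  pv <- paired_vectors(tab, "glucose", "PrecisionXtra", "plasma")
  expect_equal(des$d[des$matrix_wb == 0], pv$poc - pv$ref)
})

test_that("animals with missing covariates are dropped with a warning", {
  tab <- impute_lloq(simulate_study(test_config(seed = 5)))
  tab$weight_kg[tab$animal_id == "YEL01"] <- NA_real_
  expect_warning(
    des <- build_difference_design(tab, "glucose", "PrecisionXtra"),
    "YEL01")
  expect_false("YEL01" %in% des$animal_id)
  expect_equal(nrow(des), 54)
})

test_that("REML collapses to ordinary least squares when group variances are 0", {
  set.seed(51)
  n <- 56
  des <- tibble::tibble(
    animal_id = rep(sprintf("A%02d", 1:28), 2),
    species = rep(rep(c("s1", "s2", "s3", "s4"), times = c(10, 6, 4, 8)), 2),
    sex_m = rep(rbinom(28, 1, 0.5), 2),
    weight_c = rep(rnorm(28), 2),
    pcv_c = rep(rnorm(28, 0, 5), 2),
    bc_c = rep(rnorm(28, 0, 1), 2),
    matrix_wb = rep(c(0, 1), each = 28)
  )
  # no species or individual effect at all: pure fixed-effect + iid noise
  des$d <- 2 + 0.8 * des$sex_m + 0.5 * des$weight_c - 1.2 * des$matrix_wb +
    rnorm(n, 0, 1)
  fit <- suppressMessages(fit_lmm(des))
  ols <- lm(d ~ sex_m + weight_c + pcv_c + bc_c + matrix_wb, data = des)
  expect_true(fit$boundary) # variances estimated at the 0 boundary
  expect_equal(fit$var_species + fit$var_individual, 0, tolerance = 1e-8)
  expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  set.seed(52)
  g <- 6
  m <- 5
  group <- rep(sprintf("g%d", 1:g), each = m)
  y <- 10 + rep(rnorm(g, 0, 3), each = m) + rnorm(g * m, 0, 1)
  des <- tibble::tibble(d = y, species = group)
  fit <- fit_lmm(des, fixed_terms = character(), random_terms = "species")
  # closed-form balanced one-way estimators
  ybar_g <- tapply(y, group, mean)
  mse <- sum((y - rep(ybar_g, each = m))^2) / (g * (m - 1))
  msb <- m * sum((ybar_g - mean(y))^2) / (g - 1)
  expect_gt((msb - mse) / m, 0) # interior solution
  expect_equal(fit$var_residual, mse, tolerance = 1e-6)
  expect_equal(fit$var_species, (msb - mse) / m, tolerance = 1e-6)
  expect_equal(fit$beta$estimate[1], mean(ybar_g), tolerance = 1e-8)
})

test_that("fixed-effect estimates are invariant to row order", {
  tab <- impute_lloq(simulate_study(test_config(seed = 6)))
  des <- build_difference_design(tab, "bhb", "BHBCheck")
  f1 <- suppressMessages(fit_lmm(des))
  set.seed(99)
  f2 <- suppressMessages(fit_lmm(des[sample(nrow(des)), ]))
  expect_equal(f1$beta$estimate, f2$beta$estimate, tolerance = 1e-6)
  expect_equal(f1$var_residual, f2$var_residual, tolerance = 1e-6)
})

test_that("a -2.3 unit matrix effect is recovered at the study design size", {
  # 28 animals x 2 matrices with species and individual intercepts; residual
  # noise sized so the matrix-effect standard error lands near 0.7
  set.seed(53)
  n_a <- 28
  species <- rep(c("s1", "s2", "s3", "s4"), times = c(10, 6, 4, 8))
  b_sp <- rnorm(4, 0, 0.5)
  b_id <- rnorm(n_a, 0, 0.8)
  sigma_e <- 0.7 * sqrt(n_a / 2)
  des <- tibble::tibble(
    animal_id = rep(sprintf("A%02d", 1:n_a), 2),
    species = rep(species, 2),
    sex_m = rep(rbinom(n_a, 1, 0.5), 2),
    weight_c = rep(rnorm(n_a), 2),
    pcv_c = rep(rnorm(n_a, 0, 5), 2),
    bc_c = rep(rnorm(n_a, 0, 1), 2),
    matrix_wb = rep(c(0, 1), each = 28)
  )
  des$d <- 0.5 - 2.3 * des$matrix_wb + b_sp[match(des$species, c("s1",
    "s2", "s3", "s4"))] + b_id[match(des$animal_id, unique(des$animal_id))] +
    rnorm(56, 0, sigma_e)
  fit <- suppressMessages(fit_lmm(des))
  b <- fit$beta[fit$beta$term == "matrix_wb", ]
  expect_lt(abs(b$estimate - (-2.3)), 3 * b$se)
  expect_lt(b$p, 0.05)
  expect_equal(b$se, 0.7, tolerance = 0.35)
  # the narrative rendering template: "estimate +/- SE, p"
  expect_match(sprintf("%.1f ± %.2f mmol/L, p value = %.3f",
                       b$estimate, b$se, b$p),
               "^-?[0-9.]+ ± [0-9.]+ mmol/L")
})

test_that("significance_screen tabulates p < alpha per model", {
  tab <- impute_lloq(simulate_study(test_config(seed = 8)))
  fits <- list(
    glu = suppressMessages(fit_lmm(
      build_difference_design(tab, "glucose", "PrecisionXtra"))),
    bhb = suppressMessages(fit_lmm(
      build_difference_design(tab, "bhb", "PrecisionXtra")))
  )
  scr <- significance_screen(fits)
  expect_setequal(unique(scr$model), c("glu", "bhb"))
  expect_false("(Intercept)" %in% scr$term)
  expect_equal(scr$significant, scr$p < 0.05)
  none <- significance_screen(fits, alpha = 0)
  expect_false(any(none$significant))
})

test_that("the matrix test holds its nominal size at the study design", {
  # 500 null simulations (true matrix effect 0) at 28 animals x 2 matrices;
  # rejection rate of the Satterthwaite t test should be 5% +/- 2.5%
  set.seed(54)
  species <- rep(c("s1", "s2", "s3", "s4"), times = c(10, 6, 4, 8))
  base <- tibble::tibble(
    animal_id = rep(sprintf("A%02d", 1:28), 2),
    species = rep(species, 2),
    sex_m = rep(rbinom(28, 1, 0.5), 2),
    weight_c = rep(rnorm(28), 2),
    pcv_c = rep(rnorm(28, 0, 5), 2),
    bc_c = rep(rnorm(28, 0, 1), 2),
    matrix_wb = rep(c(0, 1), each = 28)
  )
  reject <- logical(500)
  for (i in 1:500) {
    b_sp <- rnorm(4, 0, 1)
    b_id <- rnorm(28, 0, 1)
    des <- base
    des$d <- b_sp[match(des$species, c("s1", "s2", "s3", "s4"))] +
      b_id[match(des$animal_id, unique(des$animal_id))] + rnorm(56, 0, 1)
    fit <- suppressWarnings(suppressMessages(fit_lmm(des)))
    reject[i] <- fit$beta$p[fit$beta$term == "matrix_wb"] < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.025)
})
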