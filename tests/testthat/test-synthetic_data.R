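test_that("the default study has 28 animals across four species", {
  ref <- generate_reference(study_config(seed = 1))
  expect_equal(nrow(ref), 28)
  expect_equal(sort(as.integer(table(ref$species))), c(4, 6, 8, 10))
  expect_true(all(ref$weight_kg > 0))
  expect_true(all(ref$pcv_pct >= 11 & ref$pcv_pct <= 32))
  expect_true(all(ref$true_glucose > 0 & ref$true_bhb > 0))
})

test_that("generation is deterministic and device additions do not perturb it", {
  cfg <- study_config(seed = 123)
  expect_identical(generate_reference(cfg), generate_reference(cfg))
  expect_identical(simulate_study(cfg)$value, simulate_study(cfg)$value)
  # sub-streams: dropping a device leaves other devices' draws unchanged
  cfg_small <- study_config(seed = 123,
                            device_specs = default_device_specs()[-1, ])
  full <- simulate_study(cfg)
  small <- simulate_study(cfg_small)
  pick <- function(t) t$value[t$device == "NovaVet" & t$replicate_id == 0]
  expect_identical(pick(full), pick(small))
})

test_that("without outliers the analyte stays inside lognormal range", {
  sp <- default_species_specs()[4, ] # yellow stingrays
  sp$n_animals <- 10000L
  sp$outlier_prob <- 0
  ref <- generate_reference(study_config(seed = 2, species_specs = sp))
  bound <- exp(sp$bhb_log_mean + 5.5 * sp$bhb_log_sd)
  expect_lt(max(ref$true_bhb), bound)
  # with the default outlier rate, extreme ketosis values do appear
  sp2 <- default_species_specs()[4, ]
  sp2$n_animals <- 10000L
  ref2 <- generate_reference(study_config(seed = 2, species_specs = sp2))
  expect_gt(max(ref2$true_bhb), bound)
})

test_that("noise-free devices reproduce the truth exactly", {
  dv <- tibble::tibble(device = "Exact", analyte = "glucose",
                       alpha_const = 0, beta_prop = 1, sigma0 = 0,
                       sigma1 = 0, lloq = 0, uloq = Inf)
  cfg <- study_config(seed = 3, device_specs = dv, reference_cv = 0)
  ref <- generate_reference(cfg)
  tab <- generate_measurements(ref, cfg)
  pl <- tab[tab$device == "Exact" & tab$matrix == "plasma", ]
  expect_equal(pl$value[match(ref$animal_id, pl$animal_id)],
               ref$true_glucose)
  # the meter itself (LLOQ 0) censors nothing; the reference analyzer's own
  # 20 mg/dL LLOQ may still censor low-glucose animals
  expect_false(any(tab$censored[tab$device == "Exact"]))
})

test_that("below-LLOQ truths yield censored records", {
  dv <- tibble::tibble(device = "Exact", analyte = "glucose",
                       alpha_const = 0, beta_prop = 1, sigma0 = 0,
                       sigma1 = 0, lloq = 20, uloq = Inf)
  sp <- default_species_specs()[1, ]
  sp$glucose_log_mean <- log(12) # most truths below the 20 mg/dL LLOQ
  sp$glucose_log_sd <- 0.05
  cfg <- study_config(seed = 4, species_specs = sp, device_specs = dv)
  tab <- generate_measurements(generate_reference(cfg), cfg)
  dev_rows <- tab[tab$device == "Exact", ]
  expect_true(all(dev_rows$censored))
  expect_true(all(is.na(dev_rows$value)))
  expect_equal(unique(dev_rows$lloq), 20)
  imp <- impute_lloq(tab)
  expect_equal(unique(imp$value[imp$device == "Exact"]), 10)
})

test_that("censoring fraction matches the normal-CDF prediction", {
  sp <- default_species_specs()[1, ]
  sp$n_animals <- 10000L
  dv <- tibble::tibble(device = "M", analyte = "glucose", alpha_const = 2,
                       beta_prop = 0.9, sigma0 = 4, sigma1 = 0.1,
                       lloq = 20, uloq = Inf)
  cfg <- study_config(seed = 9, species_specs = sp, device_specs = dv)
  ref <- generate_reference(cfg)
  tab <- generate_measurements(ref, cfg)
  obs <- mean(tab$censored[tab$device == "M" & tab$matrix == "plasma"])
  mu <- dv$alpha_const + dv$beta_prop * ref$true_glucose
  sg <- dv$sigma0 + dv$sigma1 * ref$true_glucose
  pred <- mean(pnorm((dv$lloq - mu) / sg))
  expect_lt(abs(obs - pred), 4 * sqrt(pred * (1 - pred) / nrow(ref)))
})

test_that("replicate runs share truth, have n_rep rows, and zero-noise CV 0", {
  cfg <- study_config(seed = 10)
  ref <- generate_reference(cfg)
  reps <- generate_replicates(ref, cfg)
  counts <- table(reps$animal_id, reps$device, reps$analyte, reps$matrix)
  expect_true(all(counts[counts > 0] == 5))
  expect_equal(length(unique(reps$animal_id)), 2)
  expect_true(all(unique(reps$animal_id) %in%
                    ref$animal_id[ref$species == "yellow"]))

  dv0 <- tibble::tibble(device = "Exact", analyte = "bhb", alpha_const = 0,
                        beta_prop = 1, sigma0 = 0, sigma1 = 0, lloq = 0,
                        uloq = Inf)
  cfg0 <- study_config(seed = 10, device_specs = dv0)
  reps0 <- generate_replicates(generate_reference(cfg0), cfg0)
  one <- reps0$value[reps0$animal_id == reps0$animal_id[1] &
                       reps0$matrix == "plasma"]
  expect_equal(cv_percent(one), 0)
})

test_that("replicate CV converges to the delta-method limit", {
  dv <- tibble::tibble(device = "M", analyte = "glucose", alpha_const = 0,
                       beta_prop = 1, sigma0 = 4, sigma1 = 0, lloq = 0,
                       uloq = Inf)
  sp <- default_species_specs()[1, ]
  sp$n_animals <- 1L
  cfg <- study_config(seed = 11, species_specs = sp, device_specs = dv,
                      n_replicate_animals = 1L, n_replicates = 2000L)
  ref <- generate_reference(cfg)
  reps <- generate_replicates(ref, cfg)
  vals <- reps$value[reps$matrix == "plasma"]
  expect_equal(length(vals), 2000)
  expect_equal(cv_percent(vals), 100 * 4 / ref$true_glucose,
               tolerance = 0.05)
})

test_that("Bland-Altman bias on a proportionality-1 device recovers the offsets", {
  dv <- tibble::tibble(device = rep("M", 2), analyte = c("glucose", "bhb"),
                       alpha_const = c(5, 0.1), beta_prop = c(1, 1),
                       sigma0 = c(3, 0.05), sigma1 = c(0, 0),
                       lloq = c(0, 0), uloq = c(Inf, Inf))
  cfg <- study_config(seed = 12, device_specs = dv,
                      matrix_effect = c(glucose = 4, bhb = 0))
  tab <- impute_lloq(simulate_study(cfg))
  pv_p <- paired_vectors(tab, "glucose", "M", "plasma")
  ba_p <- bland_altman(pv_p$poc, pv_p$ref)
  se <- ba_p$sd_diff / sqrt(ba_p$n)
  expect_lt(abs(ba_p$mean_bias - 5), 3 * se)
  pv_wb <- paired_vectors(tab, "glucose", "M", "whole_blood")
  ba_wb <- bland_altman(pv_wb$poc, pv_wb$ref)
  expect_lt(abs(ba_wb$mean_bias - 9), 3 * ba_wb$sd_diff / sqrt(ba_wb$n))
})
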