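# Deterministic sub-stream seeds: one global study seed, sub-streams derived
# by hashing a documented key order (stage, species/device, analyte) so that
# adding a device never perturbs the reference draws or other devices.
substream_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147481563
  as.integer((seed %% 2147481563 + h * 7919) %% 2147481563 + 1)
}

#' Default species specifications for the synthetic study
#'
#' Four stingray species with the study's sample sizes and weight ranges,
#' and lognormal reference-analyte distributions parameterised from the
#' per-species medians and ranges the study reports (glucose in mg/dL, a
#' right-skewed beta-hydroxybutyrate distribution in mmol/L with a rare
#' high outlier among yellow stingrays).
#'
#' @return A tibble with one row per species.
#' @export
default_species_specs <- function() {
  tibble::tibble(
    species = c("atlantic", "cownose", "southern", "yellow"),
    n_animals = c(10L, 6L, 4L, 8L),
    weight_min = c(0.8, 3.85, 5.4, 0.6),
    weight_max = c(1.8, 6.8, 9.2, 1.65),
    glucose_log_mean = log(c(26, 48, 36, 30)),
    glucose_log_sd = c(0.35, 0.20, 0.20, 0.40),
    bhb_log_mean = log(c(0.22, 0.31, 0.23, 0.22)),
    bhb_log_sd = c(0.35, 0.50, 0.20, 0.55),
    outlier_prob = c(0, 0, 0, 0.125),
    outlier_scale = c(10, 10, 10, 10)
  )
}

#' Default device specifications for the synthetic study
#'
#' Three POC meters per analyte with constant (`alpha_const`, analyte units)
#' plus proportional (`beta_prop`) bias and heteroscedastic noise
#' `sd = sigma0 + sigma1 * true`, and the meters' quantification limits
#' (glucose LLOQ 20 mg/dL on all three; beta-hydroxybutyrate LLOQ 0.1 mmol/L
#' on two meters and 0 on the third). Bias parameters emulate the magnitudes
#' the validated meters showed; they are not calibration constants.
#'
#' @return A tibble with one row per (device, analyte).
#' @export
default_device_specs <- function() {
  tibble::tibble(
    device = rep(c("BHBCheck", "PrecisionXtra", "NovaVet"), 2),
    analyte = rep(c("glucose", "bhb"), each = 3),
    alpha_const = c(37, -6, 8, 0.2, 0, 0.05),
    beta_prop = c(1.4, 1.3, 0.3, 1.3, 1.8, 0.8),
    sigma0 = c(1, 1, 0.5, 0.02, 0.01, 0.01),
    sigma1 = c(0.03, 0.08, 0.01, 0.08, 0.02, 0.03),
    lloq = c(20, 20, 20, 0.1, 0, 0.1),
    uloq = c(600, 500, 600, 8, 8, 8)
  )
}

#' Configuration of a synthetic meter-validation study
#'
#' Bundles every tunable of the generator: species specs (sample sizes,
#' weights, analyte distributions), device specs (bias, noise, LLOQ/ULOQ),
#' covariate ranges (PCV 11-32%, buffy coat 0-4%, total solids 4.4-8.1
#' g/dL), the replicate-precision design (2 animals x 5 replicates), an
#' additive whole-blood matrix effect per analyte, and the reference
#' analyzer's noise (percent CV) and LLOQs.
#'
#' @param seed Integer study seed; every draw is deterministic given it.
#' @param species_specs Tibble as in [default_species_specs()].
#' @param device_specs Tibble as in [default_device_specs()].
#' @param pcv_range,bc_range,ts_range Length-2 covariate ranges.
#' @param n_replicate_animals Animals in the replicate-precision subset.
#' @param n_replicates Replicates per run (default 5).
#' @param matrix_effect Named additive whole-blood shift per analyte, in
#'   analyte units.
#' @param reference_cv Reference analyzer imprecision, percent CV.
#' @param reference_lloq Named reference LLOQ per analyte.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         species_specs = default_species_specs(),
                         device_specs = default_device_specs(),
                         pcv_range = c(11, 32),
                         bc_range = c(0, 4),
                         ts_range = c(4.4, 8.1),
                         n_replicate_animals = 2L,
                         n_replicates = 5L,
                         matrix_effect = c(glucose = 0, bhb = 0),
                         reference_cv = 2,
                         reference_lloq = c(glucose = 20, bhb = 0)) {
  stopifnot(
    pcv_range[1] <= pcv_range[2], bc_range[1] <= bc_range[2],
    ts_range[1] <= ts_range[2],
    all(species_specs$weight_min <= species_specs$weight_max),
    all(species_specs$glucose_log_sd > 0),
    all(species_specs$bhb_log_sd > 0),
    all(species_specs$outlier_prob >= 0 & species_specs$outlier_prob <= 1),
    all(device_specs$sigma0 >= 0), all(device_specs$sigma1 >= 0),
    all(device_specs$lloq >= 0),
    n_replicates >= 2, reference_cv >= 0
  )
  cfg <- list(
    seed = as.integer(seed),
    species_specs = species_specs,
    device_specs = device_specs,
    pcv_range = pcv_range, bc_range = bc_range, ts_range = ts_range,
    n_replicate_animals = as.integer(n_replicate_animals),
    n_replicates = as.integer(n_replicates),
    matrix_effect = matrix_effect,
    reference_cv = reference_cv,
    reference_lloq = reference_lloq
  )
  class(cfg) <- "study_config"
  cfg
}

#' Generate per-animal true analyte values and covariates
#'
#' Draws the study population: per animal a species label, sex (Bernoulli
#' 1/2), weight (uniform in the species range), PCV/BC/TS (uniform in the
#' configured ranges), a true glucose concentration (species lognormal) and
#' a true beta-hydroxybutyrate concentration (species lognormal, multiplied
#' by `outlier_scale` with probability `outlier_prob` to emulate rare
#' extreme ketosis). Deterministic under the config seed.
#'
#' @param config A [study_config()].
#' @return A tibble, one row per animal: `animal_id, species, sex,
#'   weight_kg, pcv_pct, bc_pct, ts_gdl, true_glucose, true_bhb`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "study_config"))
  sp <- config$species_specs
  prefix <- toupper(substr(sp$species, 1, 3))
  out <- vector("list", nrow(sp))
  for (k in seq_len(nrow(sp))) {
    n <- sp$n_animals[k]
    set.seed(substream_seed(config$seed, "reference", sp$species[k]))
    is_out <- runif(n) < sp$outlier_prob[k]
    out[[k]] <- tibble::tibble(
      animal_id = sprintf("%s%02d", prefix[k], seq_len(n)),
      species = sp$species[k],
      sex = ifelse(rbinom(n, 1, 0.5) == 1, "M", "F"),
      weight_kg = runif(n, sp$weight_min[k], sp$weight_max[k]),
      pcv_pct = runif(n, config$pcv_range[1], config$pcv_range[2]),
      bc_pct = runif(n, config$bc_range[1], config$bc_range[2]),
      ts_gdl = runif(n, config$ts_range[1], config$ts_range[2]),
      true_glucose = rlnorm(n, sp$glucose_log_mean[k], sp$glucose_log_sd[k]),
      true_bhb = rlnorm(n, sp$bhb_log_mean[k], sp$bhb_log_sd[k]) *
        ifelse(is_out, sp$outlier_scale[k], 1)
    )
  }
  dplyr::bind_rows(out)
}

# one measured reading per animal under the device error model; returns a
# list(value, censored, lloq, truncated)
measure_device <- function(truth, alpha, beta, sigma0, sigma1, lloq,
                           shift = 0) {
  mu <- alpha + beta * truth + shift
  y <- mu + rnorm(length(truth), 0, sigma0 + sigma1 * truth)
  truncated <- y < 0
  y[truncated] <- 0
  censored <- y < lloq
  list(value = ifelse(censored, NA_real_, y),
       censored = censored,
       lloq = ifelse(censored, lloq, NA_real_),
       truncated = truncated)
}

measurement_rows <- function(reference, analyte, matrix, device, meas,
                             replicate_id = 0L) {
  tibble::tibble(
    animal_id = reference$animal_id,
    species = reference$species,
    sex = reference$sex,
    weight_kg = reference$weight_kg,
    pcv_pct = reference$pcv_pct,
    bc_pct = reference$bc_pct,
    ts_gdl = reference$ts_gdl,
    analyte = analyte,
    matrix = matrix,
    device = device,
    value = meas$value,
    censored = meas$censored,
    lloq = meas$lloq,
    above_uloq = FALSE,
    replicate_id = as.integer(replicate_id)
  )
}

#' Generate primary-run measurements for every device and the reference
#'
#' Applies the measurement-error model to the true values: a POC reading is
#' `alpha_const + beta_prop * true + matrix_effect * 1[whole blood] + eps`
#' with `eps ~ Normal(0, (sigma0 + sigma1 * true)^2)`; each POC device reads
#' both whole blood and plasma, the reference analyzer reads plasma only
#' with multiplicative noise at `reference_cv` percent. Negative simulated
#' readings are truncated at 0 (and counted in attribute `n_truncated`);
#' readings below a device's LLOQ become censored records. Deterministic
#' under the config seed via per-(device, analyte) sub-streams.
#'
#' @param reference Output of [generate_reference()].
#' @param config A [study_config()] (supplies device specs, matrix effect,
#'   reference noise and seed).
#' @return A `measurement_table` of `replicate_id = 0` rows.
#' @export
generate_measurements <- function(reference, config) {
  stopifnot(inherits(config, "study_config"))
  dv <- config$device_specs
  rows <- list()
  n_trunc <- 0L
  for (k in seq_len(nrow(dv))) {
    an <- dv$analyte[k]
    truth <- reference[[paste0("true_", an)]]
    shift <- unname(config$matrix_effect[an])
    if (is.na(shift)) shift <- 0
    set.seed(substream_seed(config$seed, "measure", dv$device[k], an))
    wb <- measure_device(truth, dv$alpha_const[k], dv$beta_prop[k],
                         dv$sigma0[k], dv$sigma1[k], dv$lloq[k],
                         shift = shift)
    pl <- measure_device(truth, dv$alpha_const[k], dv$beta_prop[k],
                         dv$sigma0[k], dv$sigma1[k], dv$lloq[k])
    n_trunc <- n_trunc + sum(wb$truncated) + sum(pl$truncated)
    rows[[paste(dv$device[k], an, "wb")]] <-
      measurement_rows(reference, an, "whole_blood", dv$device[k], wb)
    rows[[paste(dv$device[k], an, "p")]] <-
      measurement_rows(reference, an, "plasma", dv$device[k], pl)
  }
  for (an in ANALYTES) {
    truth <- reference[[paste0("true_", an)]]
    set.seed(substream_seed(config$seed, "measure", "reference", an))
    ref_lloq <- unname(config$reference_lloq[an])
    if (is.na(ref_lloq)) ref_lloq <- 0
    meas <- measure_device(truth, 0, 1, 0, config$reference_cv / 100,
                           ref_lloq)
    rows[[paste("reference", an)]] <-
      measurement_rows(reference, an, "plasma", "reference", meas)
    n_trunc <- n_trunc + sum(meas$truncated)
  }
  tab <- dplyr::bind_rows(rows)
  validate_measurement_table(tab)
  new_measurement_table(tab, metadata = list(
    seed = config$seed, stage = "primary", generator = "pocagree",
    n_truncated = n_trunc
  ))
}

#' Generate replicate-precision runs
#'
#' Re-measures a subset of animals `n_replicates` times in rapid succession
#' (shared truth, independent noise draws) with every device on both
#' matrices, emulating the intra-assay repeatability design (default: 2
#' yellow stingrays, 5 replicates). Rows carry `replicate_id` 1..n_rep.
#'
#' @param reference Output of [generate_reference()].
#' @param config A [study_config()].
#' @param animal_ids Animals to re-measure; default the first
#'   `n_replicate_animals` yellow stingrays (falling back to the first
#'   animals overall if that species is absent).
#' @return A `measurement_table` of replicate rows.
#' @export
generate_replicates <- function(reference, config, animal_ids = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(animal_ids)) {
    pool <- reference$animal_id[reference$species == "yellow"]
    if (length(pool) == 0) pool <- reference$animal_id
    animal_ids <- head(pool, config$n_replicate_animals)
  }
  stopifnot(length(animal_ids) <= nrow(reference))
  sub <- reference[match(animal_ids, reference$animal_id), ]
  if (any(is.na(sub$animal_id))) {
    stop("unknown animal_ids in replicate subset", call. = FALSE)
  }
  dv <- config$device_specs
  rows <- list()
  for (k in seq_len(nrow(dv))) {
    an <- dv$analyte[k]
    truth <- sub[[paste0("true_", an)]]
    shift <- unname(config$matrix_effect[an])
    if (is.na(shift)) shift <- 0
    set.seed(substream_seed(config$seed, "replicate", dv$device[k], an))
    for (r in seq_len(config$n_replicates)) {
      wb <- measure_device(truth, dv$alpha_const[k], dv$beta_prop[k],
                           dv$sigma0[k], dv$sigma1[k], dv$lloq[k],
                           shift = shift)
      pl <- measure_device(truth, dv$alpha_const[k], dv$beta_prop[k],
                           dv$sigma0[k], dv$sigma1[k], dv$lloq[k])
      rows[[paste(dv$device[k], an, "wb", r)]] <-
        measurement_rows(sub, an, "whole_blood", dv$device[k], wb, r)
      rows[[paste(dv$device[k], an, "p", r)]] <-
        measurement_rows(sub, an, "plasma", dv$device[k], pl, r)
    }
  }
  tab <- dplyr::bind_rows(rows)
  new_measurement_table(tab, metadata = list(
    seed = config$seed, stage = "replicates", animal_ids = animal_ids
  ))
}

#' Simulate a complete synthetic validation study
#'
#' Composes [generate_reference()], [generate_measurements()] and
#' [generate_replicates()] into one `measurement_table` holding the full
#' study: primary paired runs for every device/analyte/matrix plus the
#' replicate-precision subset. Deterministic under the config seed; the
#' truths and config are attached as metadata.
#'
#' @param config A [study_config()].
#' @return A `measurement_table`.
#' @export
simulate_study <- function(config = study_config()) {
  reference <- generate_reference(config)
  prim <- generate_measurements(reference, config)
  reps <- generate_replicates(reference, config)
  tab <- dplyr::bind_rows(prim, reps)
  validate_measurement_table(tab)
  new_measurement_table(tab, metadata = list(
    seed = config$seed, config = config, truths = reference,
    generator = "pocagree"
  ))
}
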