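#' Build the difference-model design for one meter and analyte
#'
#' Assembles the response and covariates for the random-intercept mixed
#' model that screens what drives disagreement: one row per (animal,
#' specimen matrix) with response `d = poc - ref` (the meter's reading minus
#' the reference laboratory's plasma reading), fixed-effect codings
#' `sex_m` (F = 0, M = 1) and `matrix_wb` (plasma = 0, whole blood = 1),
#' mean-centred continuous covariates (weight, PCV, buffy coat), and two
#' grouping labels (species and animal; animals are nested in species by
#' construction of ids). Animals with a missing fixed-effect covariate are
#' dropped from this design (with a warning) but never from the agreement
#' statistics.
#'
#' @param table An imputed `measurement_table`.
#' @param analyte `"glucose"` or `"bhb"`.
#' @param device POC device name.
#' @return A tibble of class `lmm_design` with columns `animal_id, species,
#'   d, sex_m, weight_c, pcv_c, bc_c, matrix_wb`. Centering constants are
#'   attached as attribute `centers`.
#' @export
build_difference_design <- function(table, analyte, device) {
  rows <- list()
  for (mat in MATRICES) {
    pv <- tryCatch(paired_vectors(table, analyte, device, mat),
                   error = function(e) NULL)
    if (is.null(pv)) next
    rows[[mat]] <- tibble::tibble(
      animal_id = pv$animal_ids,
      species = pv$covariates$species,
      d = pv$poc - pv$ref,
      sex = pv$covariates$sex,
      weight_kg = pv$covariates$weight_kg,
      pcv_pct = pv$covariates$pcv_pct,
      bc_pct = pv$covariates$bc_pct,
      matrix_wb = as.numeric(mat == "whole_blood")
    )
  }
  if (length(rows) == 0) {
    stop("no paired data for device '", device, "', analyte '", analyte,
         "'", call. = FALSE)
  }
  des <- dplyr::bind_rows(rows)
  covars <- c("sex", "weight_kg", "pcv_pct", "bc_pct")
  miss <- !stats::complete.cases(des[covars])
  if (all(miss)) {
    stop("every animal is missing a fixed-effect covariate; cannot build ",
         "the difference model", call. = FALSE)
  }
  if (any(miss)) {
    warning("dropping ", length(unique(des$animal_id[miss])),
            " animal(s) with missing covariates from the mixed model: ",
            paste(unique(des$animal_id[miss]), collapse = ", "),
            call. = FALSE)
    des <- des[!miss, ]
  }
  if (length(unique(des$species)) < 2) {
    warning("fewer than 2 species in the design; the species variance ",
            "component is weakly identified", call. = FALSE)
  }
  centers <- c(weight_kg = mean(des$weight_kg), pcv_pct = mean(des$pcv_pct),
               bc_pct = mean(des$bc_pct))
  out <- tibble::tibble(
    animal_id = des$animal_id,
    species = des$species,
    d = des$d,
    sex_m = as.numeric(des$sex == "M"),
    weight_c = des$weight_kg - centers["weight_kg"],
    pcv_c = des$pcv_pct - centers["pcv_pct"],
    bc_c = des$bc_pct - centers["bc_pct"],
    matrix_wb = des$matrix_wb
  )
  attr(out, "centers") <- centers
  class(out) <- c("lmm_design", class(out))
  out
}

#' Fit the random-intercept difference model by REML
#'
#' Fits `d ~ fixed effects + (1 | species) + (1 | animal)` by restricted
#' maximum likelihood, with Satterthwaite degrees of freedom for the
#' fixed-effect t tests. Fixed-effect terms that do not vary in the design
#' (e.g. `matrix_wb` when only plasma pairs exist) are dropped with a
#' message; random terms can be restricted via `random_terms` (useful for
#' reduced designs such as a one-way species layout). Boundary variance
#' estimates (a component estimated at exactly 0) are legitimate REML
#' solutions and are flagged, not treated as errors.
#'
#' @param design An `lmm_design` from [build_difference_design()], or any
#'   data frame with column `d`, grouping columns, and numeric fixed-effect
#'   columns.
#' @param fixed_terms Character vector of fixed-effect columns; `NULL`
#'   (default) uses every non-grouping numeric column that varies.
#' @param random_terms Grouping columns given random intercepts (default
#'   `c("species", "animal_id")`, restricted to columns present).
#' @return An object of class `lmm_fit`: tibble `beta` (term, estimate, se,
#'   df, t, p), variance components `var_species`, `var_individual`,
#'   `var_residual`, counts, `converged`, `boundary`, `loglik_reml`, and the
#'   underlying `lmerTest` model as `model`.
#' @export
fit_lmm <- function(design, fixed_terms = NULL,
                    random_terms = c("species", "animal_id")) {
  stopifnot(is.data.frame(design), "d" %in% names(design))
  random_terms <- intersect(random_terms, names(design))
  if (length(random_terms) == 0) {
    stop("no grouping column available for random intercepts", call. = FALSE)
  }
  if (is.null(fixed_terms)) {
    cand <- setdiff(names(design), c("d", random_terms))
    cand <- cand[vapply(design[cand], is.numeric, logical(1))]
    fixed_terms <- cand
  }
  varies <- vapply(fixed_terms,
                   function(v) length(unique(design[[v]])) > 1, logical(1))
  if (any(!varies)) {
    message("dropping constant fixed-effect term(s): ",
            paste(fixed_terms[!varies], collapse = ", "))
    fixed_terms <- fixed_terms[varies]
  }
  p <- length(fixed_terms) + 1
  if (nrow(design) < p + 3) {
    stop("too few observations (", nrow(design), ") for ", p,
         " fixed effects", call. = FALSE)
  }
  fixed_part <- if (length(fixed_terms) == 0) "1"
                else paste(fixed_terms, collapse = " + ")
  random_part <- paste(sprintf("(1 | %s)", random_terms), collapse = " + ")
  form <- stats::as.formula(paste("d ~", fixed_part, "+", random_part))
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = design, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  smry <- suppressMessages(summary(fit))
  ct <- smry$coefficients # Estimate, Std. Error, df, t value, Pr(>|t|)
  beta <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    se = unname(ct[, "Std. Error"]),
    df = unname(ct[, "df"]),
    t = unname(ct[, "t value"]),
    p = unname(ct[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) NA_real_ else v[1]
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  out <- list(
    beta = beta,
    var_species = getvar("species"),
    var_individual = getvar("animal_id"),
    var_residual = getvar("Residual"),
    n_obs = nrow(design),
    n_species = if ("species" %in% names(design))
      length(unique(design$species)) else NA_integer_,
    n_individuals = if ("animal_id" %in% names(design))
      length(unique(design$animal_id)) else NA_integer_,
    converged = is.null(conv_msgs) ||
      !any(grepl("failed to converge", conv_msgs, ignore.case = TRUE)),
    boundary = lme4::isSingular(fit),
    loglik_reml = as.numeric(logLik(fit, REML = TRUE)),
    model = fit
  )
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat("Random-intercept difference model (REML",
      if (x$boundary) ", boundary fit" else "", ")\n", sep = "")
  cat("  n =", x$n_obs, "observations,", x$n_individuals, "animals,",
      x$n_species, "species\n")
  cat("  Variance components: species", format(round(x$var_species, digits)),
      "| individual", format(round(x$var_individual, digits)),
      "| residual", format(round(x$var_residual, digits)), "\n")
  print(as.data.frame(x$beta), digits = digits)
  invisible(x)
}

#' Screen covariates for significant effects across fitted models
#'
#' Tabulates which fixed effects reach `p < alpha` in each fitted
#' difference model, reproducing the narrative "which covariates affect
#' agreement" summary.
#'
#' @param fits Named list of `lmm_fit` objects (names identify
#'   device/analyte).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `model, term, estimate, se, p, significant`
#'   (intercept rows excluded).
#' @export
significance_screen <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), length(fits) > 0)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  rows <- lapply(names(fits), function(nm) {
    b <- fits[[nm]]$beta
    b <- b[b$term != "(Intercept)", ]
    tibble::tibble(
      model = nm, term = b$term, estimate = b$estimate, se = b$se, p = b$p,
      significant = b$p < alpha
    )
  })
  dplyr::bind_rows(rows)
}
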