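#' Assemble the full agreement report for a validation study
#'
#' Runs the whole analysis pipeline on a measurement table: half-LLOQ
#' imputation, per-analyzer summary statistics, replicate precision (CV%),
#' percent bias / observed total error / relative-error zones, Bland-Altman
#' and Passing-Bablok agreement per (device, analyte, matrix), and the
#' random-intercept mixed-model covariate screen per (device, analyte).
#' Statistical failures in one block (e.g. too few pairs) are recorded in
#' that block and do not abort the others.
#'
#' @param table A `measurement_table` (censored rows are imputed
#'   automatically if they have not been already).
#' @param alpha Significance level for all CIs and flags (default 0.05).
#' @param exclude_ids Animal ids excluded from Bland-Altman and
#'   Passing-Bablok *plot data* only (statistics always use all pairs),
#'   mirroring outlier handling in published figures.
#' @return An object of class `agreement_report` with tibbles `summary`,
#'   `error`, `agreement`, `lmm_coefficients`, `lmm_variance`, lists of the
#'   underlying `ba_result`/`pb_fit`/`lmm_fit` objects, plot data, a list
#'   `failures`, and `provenance` (input hash, seed if synthetic, package
#'   version, timestamp).
#' @export
agreement_report <- function(table, alpha = 0.05, exclude_ids = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  meta <- table_metadata(table)
  if (any(table$censored & is.na(table$value))) {
    message("imputing ", sum(table$censored & is.na(table$value)),
            " below-LLOQ value(s) at half the LLOQ")
    table <- impute_lloq(table)
  }
  devices <- setdiff(unique(table$device), "reference")
  analytes <- intersect(ANALYTES, unique(table$analyte))
  prim <- table[table$replicate_id == 0, ]
  reps <- table[table$replicate_id > 0, ]

  failures <- list()
  note_failure <- function(key, msg) {
    failures[[key]] <<- conditionMessage(msg)
    NULL
  }

  # ---- summary block (Table-1 style), POC devices then reference ----
  summary_rows <- list()
  for (an in analytes) {
    combos <- unique(prim[prim$analyte == an, c("device", "matrix")])
    combos <- combos[order(match(combos$device, c(devices, "reference")),
                           match(combos$matrix, MATRICES)), ]
    for (k in seq_len(nrow(combos))) {
      sel <- prim$analyte == an & prim$device == combos$device[k] &
        prim$matrix == combos$matrix[k]
      lloq <- suppressWarnings(max(prim$lloq[sel], na.rm = TRUE))
      st <- summary_stats(prim$value[sel], prim$censored[sel],
                          lloq = if (is.finite(lloq)) lloq else NA_real_)
      summary_rows[[paste(an, k)]] <- dplyr::bind_cols(
        tibble::tibble(analyte = an, device = combos$device[k],
                       matrix = combos$matrix[k]), st)
    }
  }
  summary_tab <- dplyr::bind_rows(summary_rows)

  # ---- replicate precision: per-animal CV averaged over the subset ----
  precision_cv <- function(an, dev, mat) {
    sel <- reps$analyte == an & reps$device == dev & reps$matrix == mat
    if (!any(sel)) return(NA_real_)
    per_animal <- tapply(reps$value[sel], reps$animal_id[sel], function(v) {
      tryCatch(cv_percent(v), error = function(e) NA_real_)
    })
    mean(unlist(per_animal), na.rm = TRUE)
  }

  # ---- error / agreement blocks per (device, analyte, matrix) ----
  error_rows <- list()
  agreement_rows <- list()
  ba_fits <- list()
  pb_fits <- list()
  ba_points <- list()
  pb_points <- list()
  for (an in analytes) {
    for (dev in devices) {
      for (mat in MATRICES) {
        key <- paste(an, dev, mat, sep = ".")
        pv <- tryCatch(paired_vectors(table, an, dev, mat),
                       error = function(e) note_failure(key, e))
        if (is.null(pv)) next
        n <- length(pv$poc)
        cv <- precision_cv(an, dev, mat)
        bias <- bias_percent(pv$poc, pv$ref)
        zones <- zone_proportions(pv$poc, pv$ref)
        error_rows[[key]] <- tibble::tibble(
          analyte = an, device = dev, matrix = mat, n = n,
          cv_pct = cv, bias_pct = bias,
          te_obs_pct = if (is.na(cv)) NA_real_
                       else total_error_observed(cv, bias),
          zone12 = zones[["zone12"]], zone15 = zones[["zone15"]],
          zone20 = zones[["zone20"]],
          n_imputed_pairs = sum(pv$poc_censored | pv$ref_censored)
        )
        ba <- tryCatch(bland_altman(pv$poc, pv$ref, alpha = alpha),
                       error = function(e) note_failure(key, e))
        pb <- tryCatch(
          withCallingHandlers(
            pb_fit(pv$ref, pv$poc, alpha = alpha),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) note_failure(key, e))
        if (!is.null(ba)) {
          ba_fits[[key]] <- ba
          bp <- ba_plot_data(pv$poc, pv$ref, alpha = alpha,
                             exclude_ids = exclude_ids,
                             animal_ids = pv$animal_ids)
          ba_points[[key]] <- dplyr::bind_cols(
            tibble::tibble(analyte = an, device = dev, matrix = mat),
            bp$points)
        }
        if (!is.null(pb)) {
          pb_fits[[key]] <- pb
          pp <- pb_plot_data(pv$ref, pv$poc, alpha = alpha,
                             exclude_ids = exclude_ids,
                             animal_ids = pv$animal_ids)
          pb_points[[key]] <- dplyr::bind_cols(
            tibble::tibble(analyte = an, device = dev, matrix = mat),
            pp$points)
        }
        if (!is.null(ba) || !is.null(pb)) {
          agreement_rows[[key]] <- tibble::tibble(
            analyte = an, device = dev, matrix = mat, n = n,
            ba_bias = if (is.null(ba)) NA_real_ else ba$mean_bias,
            ba_bias_lo = if (is.null(ba)) NA_real_ else ba$ci_bias[1],
            ba_bias_hi = if (is.null(ba)) NA_real_ else ba$ci_bias[2],
            significant_bias = if (is.null(ba)) NA else ba$significant_bias,
            loa_lower = if (is.null(ba)) NA_real_ else ba$loa_lower,
            loa_lower_lo = if (is.null(ba)) NA_real_ else ba$ci_loa_lower[1],
            loa_lower_hi = if (is.null(ba)) NA_real_ else ba$ci_loa_lower[2],
            loa_upper = if (is.null(ba)) NA_real_ else ba$loa_upper,
            loa_upper_lo = if (is.null(ba)) NA_real_ else ba$ci_loa_upper[1],
            loa_upper_hi = if (is.null(ba)) NA_real_ else ba$ci_loa_upper[2],
            pb_intercept = if (is.null(pb)) NA_real_ else pb$intercept,
            pb_intercept_lo = if (is.null(pb)) NA_real_
                              else pb$ci_intercept[1],
            pb_intercept_hi = if (is.null(pb)) NA_real_
                              else pb$ci_intercept[2],
            pb_slope = if (is.null(pb)) NA_real_ else pb$slope,
            pb_slope_lo = if (is.null(pb)) NA_real_ else pb$ci_slope[1],
            pb_slope_hi = if (is.null(pb)) NA_real_ else pb$ci_slope[2],
            constant_bias = if (is.null(pb)) NA else pb$constant_bias,
            proportional_bias = if (is.null(pb)) NA
                                else pb$proportional_bias
          )
        }
      }
    }
  }

  # ---- mixed-model screen per (device, analyte) ----
  lmm_fits <- list()
  for (an in analytes) {
    for (dev in devices) {
      key <- paste(an, dev, sep = ".")
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          fit_lmm(build_difference_design(table, an, dev)))),
        error = function(e) note_failure(paste0("lmm.", key), e))
      if (!is.null(fit)) lmm_fits[[key]] <- fit
    }
  }
  lmm_coef <- if (length(lmm_fits) > 0) {
    significance_screen(lmm_fits, alpha = alpha)
  } else {
    tibble::tibble(model = character(), term = character(),
                   estimate = numeric(), se = numeric(), p = numeric(),
                   significant = logical())
  }
  lmm_var <- dplyr::bind_rows(lapply(names(lmm_fits), function(nm) {
    f <- lmm_fits[[nm]]
    tibble::tibble(model = nm, var_species = f$var_species,
                   var_individual = f$var_individual,
                   var_residual = f$var_residual, n_obs = f$n_obs,
                   converged = f$converged, boundary = f$boundary)
  }))

  out <- list(
    summary = summary_tab,
    error = dplyr::bind_rows(error_rows),
    agreement = dplyr::bind_rows(agreement_rows),
    lmm_coefficients = lmm_coef,
    lmm_variance = lmm_var,
    ba = ba_fits, pb = pb_fits, lmm = lmm_fits,
    ba_plot_data = dplyr::bind_rows(ba_points),
    pb_plot_data = dplyr::bind_rows(pb_points),
    failures = failures,
    provenance = list(
      input_hash = hash_table(table),
      seed = meta$seed,
      n_imputed = sum(table$censored),
      excluded_ids = exclude_ids,
      package_version = as.character(utils::packageVersion("pocagree")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  )
  class(out) <- "agreement_report"
  out
}

hash_table <- function(table) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_measurements(table, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report:", nrow(x$agreement), "device/analyte/matrix",
      "blocks,", length(x$lmm), "mixed models\n")
  cat("Input hash:", x$provenance$input_hash, "\n")
  if (length(x$failures) > 0) {
    cat("Blocks with statistical failures:",
        paste(names(x$failures), collapse = ", "), "\n")
  }
  cat("\n-- Error metrics --\n")
  print(render_error_table(x))
  cat("\n-- Agreement (Bland-Altman / Passing-Bablok) --\n")
  print(render_agreement_table(x))
  invisible(x)
}

# ---- render-time rounding: integers for mg/dL, 1 decimal for mmol/L and
# percents, matching the field's table style ----

fmt_conc <- function(v, analyte) {
  analyte <- rep_len(analyte, length(v))
  ifelse(is.na(v), "", ifelse(analyte == "glucose",
                              sprintf("%.0f", v), sprintf("%.1f", v)))
}
fmt_pct <- function(v) ifelse(is.na(v), "", sprintf("%.1f", v))
fmt_ci <- function(v, lo, hi, analyte, star = FALSE) {
  paste0(fmt_conc(v, analyte), " (", fmt_conc(lo, analyte), ", ",
         fmt_conc(hi, analyte), ")", ifelse(star, "*", ""))
}

#' Render the summary block in the field's table layout
#' @param report An `agreement_report`.
#' @return A data frame of formatted strings.
#' @export
render_summary_table <- function(report) {
  s <- report$summary
  data.frame(
    analyte = s$analyte, analyzer = s$device,
    matrix = ifelse(s$matrix == "whole_blood", "WB", "P"),
    n = s$n,
    mean = fmt_conc(s$mean, s$analyte), sd = fmt_conc(s$sd, s$analyte),
    median = fmt_conc(s$median, s$analyte),
    min = ifelse(s$any_censored_min, s$min_label,
                 fmt_conc(s$min, s$analyte)),
    max = fmt_conc(s$max, s$analyte),
    check.names = FALSE
  )
}

#' Render the precision/bias/total-error block
#' @param report An `agreement_report`.
#' @return A data frame of formatted strings.
#' @export
render_error_table <- function(report) {
  e <- report$error
  data.frame(
    analyte = e$analyte, analyzer = e$device,
    matrix = ifelse(e$matrix == "whole_blood", "WB", "P"),
    n = e$n, cv = fmt_pct(e$cv_pct), bias = fmt_pct(e$bias_pct),
    te_obs = fmt_pct(e$te_obs_pct),
    `<12% RE` = fmt_pct(e$zone12), `<15% RE` = fmt_pct(e$zone15),
    `<20% RE` = fmt_pct(e$zone20),
    check.names = FALSE
  )
}

#' Render the Bland-Altman / Passing-Bablok block
#' @param report An `agreement_report`.
#' @return A data frame of formatted strings.
#' @export
render_agreement_table <- function(report) {
  a <- report$agreement
  data.frame(
    analyte = a$analyte, analyzer = a$device,
    matrix = ifelse(a$matrix == "whole_blood", "WB", "P"),
    bias = fmt_ci(a$ba_bias, a$ba_bias_lo, a$ba_bias_hi, a$analyte,
                  a$significant_bias %in% TRUE),
    lower_loa = fmt_ci(a$loa_lower, a$loa_lower_lo, a$loa_lower_hi,
                       a$analyte),
    upper_loa = fmt_ci(a$loa_upper, a$loa_upper_lo, a$loa_upper_hi,
                       a$analyte),
    intercept = fmt_ci(a$pb_intercept, a$pb_intercept_lo, a$pb_intercept_hi,
                       a$analyte, a$constant_bias %in% TRUE),
    slope = fmt_ci(a$pb_slope, a$pb_slope_lo, a$pb_slope_hi, "bhb",
                   a$proportional_bias %in% TRUE),
    check.names = FALSE
  )
}

#' Write an agreement report to disk
#'
#' Emits the three rendered table-style CSVs (rounding applied at write
#' time only), the mixed-model coefficient and variance-component CSVs,
#' Bland-Altman and Passing-Bablok plot-data CSVs, and `report.json`
#' carrying every statistic at full precision plus provenance.
#'
#' @param report An `agreement_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  w(render_summary_table(report), "table1_summary.csv")
  w(render_error_table(report), "table2_error.csv")
  w(render_agreement_table(report), "table3_agreement.csv")
  w(as.data.frame(report$lmm_coefficients), "lmm_coefficients.csv")
  if (nrow(report$lmm_variance) > 0) {
    w(as.data.frame(report$lmm_variance), "lmm_variance_components.csv")
  }
  if (nrow(report$ba_plot_data) > 0) {
    w(as.data.frame(report$ba_plot_data), "ba_plot_data.csv")
  }
  if (nrow(report$pb_plot_data) > 0) {
    w(as.data.frame(report$pb_plot_data), "pb_plot_data.csv")
  }
  json <- list(
    summary = report$summary, error = report$error,
    agreement = report$agreement,
    lmm_coefficients = report$lmm_coefficients,
    lmm_variance = report$lmm_variance,
    failures = report$failures, provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
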