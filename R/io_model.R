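#' @importFrom stats median qnorm qt rbinom rlnorm rnorm runif sd setNames
#'   coef logLik pt quantile lm
#' @importFrom utils read.csv write.csv head
NULL

# Column schema of the long-format measurement CSV. `value` is either a
# decimal number or a censoring token "<X" where X is the instrument LLOQ.
MEASUREMENT_COLUMNS <- c(
  "animal_id", "species", "sex", "weight_kg", "pcv_pct", "bc_pct", "ts_gdl",
  "analyte", "matrix", "device", "value", "replicate_id"
)

ANALYTES <- c("glucose", "bhb")
MATRICES <- c("whole_blood", "plasma")
SEXES <- c("M", "F")

new_measurement_table <- function(records, metadata = list()) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  attr(out, "metadata") <- metadata
  class(out) <- c("measurement_table", class(out))
  out
}

#' Access metadata attached to a measurement table
#'
#' @param table A `measurement_table`.
#' @return A named list (study name, seed, generator parameters, ...).
#' @export
table_metadata <- function(table) {
  attr(table, "metadata") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_measurement_table <- function(tab) {
  bad_analyte <- setdiff(unique(tab$analyte), ANALYTES)
  if (length(bad_analyte) > 0) {
    stop("unknown analyte(s): ", paste(bad_analyte, collapse = ", "),
         call. = FALSE)
  }
  bad_matrix <- setdiff(unique(tab$matrix), MATRICES)
  if (length(bad_matrix) > 0) {
    stop("unknown matrix value(s): ", paste(bad_matrix, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(tab$sex[!is.na(tab$sex)]), SEXES)
  if (length(bad_sex) > 0) {
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$animal_id, tab$analyte, tab$matrix, tab$device,
               tab$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (animal_id, analyte, matrix, device, replicate_id) key: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }
  ref_wb <- tab$device == "reference" & tab$matrix != "plasma"
  if (any(ref_wb)) {
    stop("reference device rows must have matrix = plasma (rows: ",
         paste(head(which(ref_wb), 5), collapse = ", "), ")", call. = FALSE)
  }
  invisible(tab)
}

parse_value_tokens <- function(raw, rows) {
  raw <- trimws(raw)
  censored <- grepl("^<", raw)
  value <- rep(NA_real_, length(raw))
  lloq <- rep(NA_real_, length(raw))
  num_part <- ifelse(censored, sub("^<\\s*", "", raw), raw)
  parsed <- suppressWarnings(as.numeric(num_part))
  bad <- is.na(parsed) & !is.na(raw) & nzchar(raw)
  if (any(bad)) {
    stop("malformed numeric in column 'value', row ", rows[which(bad)[1]],
         ": '", raw[which(bad)[1]], "'", call. = FALSE)
  }
  value[!censored] <- parsed[!censored]
  lloq[censored] <- parsed[censored]
  list(value = value, censored = censored, lloq = lloq)
}

#' Read a long-format measurement CSV
#'
#' Reads paired analyzer measurements in the package's long CSV schema
#' (`animal_id, species, sex, weight_kg, pcv_pct, bc_pct, ts_gdl, analyte,
#' matrix, device, value, replicate_id`). The `value` cell holds either a
#' decimal number or a left-censoring token `"<X"`, where `X` is the
#' instrument's lower limit of quantification (LLOQ). Censored cells are
#' flagged and their value left `NA`; apply [impute_lloq()] before computing
#' statistics. An optional device-specification table supplies LLOQ/ULOQ per
#' (device, analyte); readings above the ULOQ are flagged, never altered.
#'
#' @param path Path to the measurement CSV.
#' @param device_specs Optional data frame with columns
#'   `device, analyte, lloq, uloq`, or a path to such a CSV.
#' @return A `measurement_table` (tibble) with columns of the schema plus
#'   `censored` (logical), `lloq` (numeric) and `above_uloq` (logical).
#' @export
read_measurements <- function(path, device_specs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), MEASUREMENT_COLUMNS)) {
    stop("CSV header must be exactly: ",
         paste(MEASUREMENT_COLUMNS, collapse = ","), call. = FALSE)
  }
  n <- nrow(raw)
  num_col <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & nzchar(trimws(raw[[col]]))
    if (any(bad)) {
      stop("malformed numeric in column '", col, "', row ", which(bad)[1],
           ": '", raw[[col]][which(bad)[1]], "'", call. = FALSE)
    }
    x
  }
  parsed <- parse_value_tokens(raw$value, seq_len(n))
  tab <- tibble::tibble(
    animal_id = raw$animal_id,
    species = raw$species,
    sex = ifelse(nzchar(trimws(raw$sex)), trimws(raw$sex), NA_character_),
    weight_kg = num_col("weight_kg"),
    pcv_pct = num_col("pcv_pct"),
    bc_pct = num_col("bc_pct"),
    ts_gdl = num_col("ts_gdl"),
    analyte = raw$analyte,
    matrix = raw$matrix,
    device = raw$device,
    value = parsed$value,
    censored = parsed$censored,
    lloq = parsed$lloq,
    above_uloq = FALSE,
    replicate_id = as.integer(num_col("replicate_id"))
  )
  if (!is.null(device_specs)) {
    specs <- if (is.character(device_specs)) {
      read.csv(device_specs, check.names = FALSE)
    } else {
      as.data.frame(device_specs)
    }
    needed <- c("device", "analyte", "lloq", "uloq")
    if (!all(needed %in% names(specs))) {
      stop("device_specs must have columns: ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    known <- specs$device
    bad_dev <- setdiff(unique(tab$device), c(known, "reference"))
    if (length(bad_dev) > 0) {
      stop("unknown device(s): ", paste(bad_dev, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(paste(tab$device, tab$analyte),
                 paste(specs$device, specs$analyte))
    # fill LLOQ for censored rows that lacked a numeric token suffix,
    # and flag above-ULOQ readings
    fill <- tab$censored & is.na(tab$lloq) & !is.na(idx)
    tab$lloq[fill] <- specs$lloq[idx[fill]]
    has_uloq <- !is.na(idx) & !is.na(specs$uloq[idx])
    tab$above_uloq <- has_uloq & !is.na(tab$value) &
      tab$value > ifelse(is.na(idx), Inf, specs$uloq[idx])
  }
  validate_measurement_table(tab)
  new_measurement_table(tab, metadata = list(source = path))
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: censored rows are rendered as `"<LLOQ"`
#' tokens (regardless of whether imputation has been applied), uncensored
#' values at full precision, so `read -> write -> read` round-trips values
#' and censoring flags exactly.
#'
#' @param table A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  value <- ifelse(table$censored,
                  paste0("<", format(table$lloq, trim = TRUE, digits = 15)),
                  vapply(table$value, function(v) {
                    if (is.na(v)) "" else format(v, trim = TRUE, digits = 15)
                  }, character(1)))
  out <- data.frame(
    animal_id = table$animal_id, species = table$species, sex = table$sex,
    weight_kg = table$weight_kg, pcv_pct = table$pcv_pct,
    bc_pct = table$bc_pct, ts_gdl = table$ts_gdl, analyte = table$analyte,
    matrix = table$matrix, device = table$device, value = value,
    replicate_id = table$replicate_id,
    check.names = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute left-censored readings at half the LLOQ
#'
#' Readings below an instrument's lower limit of quantification are replaced
#' by half that LLOQ (a 20 mg/dL LLOQ yields 10 mg/dL), the single-imputation
#' rule that introduces the least bias among constant substitutes. The
#' censored flag is retained so reports can state how many values were
#' imputed. Idempotent: re-applying changes nothing.
#'
#' @param table A `measurement_table`.
#' @return The table with every censored row's `value` set to `lloq / 2`.
#' @export
impute_lloq <- function(table) {
  cen <- table$censored
  if (any(cen & (is.na(table$lloq) | table$lloq <= 0))) {
    bad <- which(cen & (is.na(table$lloq) | table$lloq <= 0))[1]
    stop("censored row ", bad, " has missing or non-positive LLOQ",
         call. = FALSE)
  }
  table$value[cen] <- table$lloq[cen] / 2
  table
}

#' Extract paired POC/reference vectors for one device, analyte and matrix
#'
#' Builds the aligned vectors every agreement statistic consumes: the POC
#' meter's primary-run readings (`replicate_id == 0`) for the requested
#' analyte/matrix, matched animal-by-animal to the reference laboratory's
#' plasma readings for the same analyte. Animals lacking either measurement
#' are dropped and reported. Pairs are ordered by `animal_id`
#' (lexicographic) so output is reproducible.
#'
#' @param table An imputed `measurement_table` (see [impute_lloq()]).
#' @param analyte `"glucose"` or `"bhb"`.
#' @param device POC device name.
#' @param matrix `"whole_blood"` or `"plasma"` (the POC specimen type).
#' @return A list with numeric vectors `poc` and `ref` (equal length, one
#'   entry per animal), logical vectors `poc_censored`/`ref_censored`, a
#'   tibble `covariates` (one row per retained animal), `animal_ids`, and
#'   `dropped_ids`.
#' @export
paired_vectors <- function(table, analyte, device, matrix) {
  stopifnot(analyte %in% ANALYTES, matrix %in% MATRICES)
  prim <- table[table$replicate_id == 0 & table$analyte == analyte, ]
  poc_rows <- prim[prim$device == device & prim$matrix == matrix, ]
  ref_rows <- prim[prim$device == "reference" & prim$matrix == "plasma", ]
  if (nrow(poc_rows) == 0) {
    stop("no rows for device '", device, "', analyte '", analyte,
         "', matrix '", matrix, "'", call. = FALSE)
  }
  if (any(is.na(poc_rows$value)) || any(is.na(ref_rows$value))) {
    stop("censored values present; apply impute_lloq() before pairing",
         call. = FALSE)
  }
  ids <- sort(union(poc_rows$animal_id, ref_rows$animal_id))
  pi <- match(ids, poc_rows$animal_id)
  ri <- match(ids, ref_rows$animal_id)
  complete <- !is.na(pi) & !is.na(ri)
  dropped <- ids[!complete]
  ids <- ids[complete]
  pi <- pi[complete]
  ri <- ri[complete]
  if (length(ids) < 3) {
    stop("fewer than 3 complete POC/reference pairs for device '", device,
         "' (", analyte, ", ", matrix, ")", call. = FALSE)
  }
  cov <- tibble::tibble(
    animal_id = ids,
    species = poc_rows$species[pi],
    sex = poc_rows$sex[pi],
    weight_kg = poc_rows$weight_kg[pi],
    pcv_pct = poc_rows$pcv_pct[pi],
    bc_pct = poc_rows$bc_pct[pi],
    ts_gdl = poc_rows$ts_gdl[pi]
  )
  list(
    poc = poc_rows$value[pi],
    ref = ref_rows$value[ri],
    poc_censored = poc_rows$censored[pi],
    ref_censored = ref_rows$censored[ri],
    covariates = cov,
    animal_ids = ids,
    dropped_ids = dropped
  )
}
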