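# In-code fixtures: tiny measurement CSVs exercising the public read surface.

measurement_header <- paste(
  "animal_id,species,sex,weight_kg,pcv_pct,bc_pct,ts_gdl,analyte,matrix",
  "device,value,replicate_id", sep = ","
)

write_fixture_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(measurement_header, rows), path)
  path
}

# a 4-animal paired glucose study: one meter + reference, one censored value
small_glucose_rows <- function() c(
  "A01,atlantic,F,1.2,24,0,7.0,glucose,whole_blood,MeterX,46,0",
  "A02,atlantic,M,1.0,20,1,6.5,glucose,whole_blood,MeterX,30,0",
  "A03,yellow,F,0.9,28,0,7.5,glucose,whole_blood,MeterX,<20,0",
  "A04,yellow,M,1.4,22,2,6.0,glucose,whole_blood,MeterX,55,0",
  "A01,atlantic,F,1.2,24,0,7.0,glucose,plasma,reference,40,0",
  "A02,atlantic,M,1.0,20,1,6.5,glucose,plasma,reference,40,0",
  "A03,yellow,F,0.9,28,0,7.5,glucose,plasma,reference,25,0",
  "A04,yellow,M,1.4,22,2,6.0,glucose,plasma,reference,50,0"
)

read_small_table <- function(extra_rows = character()) {
  read_measurements(write_fixture_csv(c(small_glucose_rows(), extra_rows)))
}

# fast low-volume study config for end-to-end tests
test_config <- function(seed = 42, ...) {
  study_config(seed = seed, ...)
}
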