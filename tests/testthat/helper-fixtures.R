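# In-code fixture builders: tiny EHR tables with sensible defaults so tests
# only state what matters.

pt <- function(patient_id, birth_date = "1970-06-15", gender = "female",
               ethnicity = "chinese", death_date = as.Date(NA),
               terminal_flag = FALSE) {
  tibble::tibble(patient_id = patient_id, birth_date = as.Date(birth_date),
                 gender = gender, ethnicity = ethnicity,
                 death_date = as.Date(death_date),
                 terminal_flag = terminal_flag)
}

dx <- function(patient_id, code, system = "icd10", date = "2012-03-01") {
  tibble::tibble(patient_id = patient_id, code = code, system = system,
                 date = as.Date(date))
}

enc <- function(patient_id, modality = "primary_care",
                start_date = "2012-06-01", end_date = as.Date(NA)) {
  tibble::tibble(patient_id = patient_id, modality = modality,
                 start_date = as.Date(start_date),
                 end_date = as.Date(end_date))
}

inpatient <- function(patient_id, start_date, end_date = start_date) {
  enc(patient_id, "inpatient", start_date, as.Date(end_date))
}

empty_patients <- function() pt(character(0))
empty_dx <- function() dx(character(0), character(0))
empty_enc <- function() enc(character(0))

default_cfg <- segmentation_config()
cat34 <- default_catalog()
segment_factor <- popsegment:::segment_factor

write_tmp_csv <- function(df, name, dir) {
  path <- file.path(dir, name)
  readr::write_csv(df, path, na = "", progress = FALSE)
  path
}
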