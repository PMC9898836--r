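# shared fixture builders

day0 <- as.Date("2015-01-01")

# minimal valid ECG row(s); override any field via ...
make_ecgs <- function(n = 1, ...) {
  out <- tibble::tibble(
    ecg_id = sprintf("e%04d", seq_len(n)),
    patient_id = "p0001",
    date = day0,
    rhythm = "sinus",
    heart_rate_bpm = 75,
    qrs_ms = 90,
    qt_ms = 380,
    setting = "outpatient",
    sex = "female"
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_fills <- function(fill_days, supplies, patient_id = "p0001",
                       drug = "drugx") {
  tibble::tibble(
    patient_id = patient_id,
    drug = drug,
    fill_date = day0 + fill_days,
    days_supply = supplies,
    source = "pharmacy_fill"
  )
}

# small generator configuration for fast end-to-end tests
small_config <- function(seed = 11, n_patients = 250, ...) {
  generator_config(n_patients = n_patients, seed = seed, ...)
}
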