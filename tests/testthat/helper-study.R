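# The scaled-down simulation study shared by the accuracy and calibration
# tests: 50 wells from a 5-Mb genome with 10 planted duplication pairs
# (5-20 kb, 94-99% identity), C_R = 1.5x, 2% well genome fraction, seed 1.
# Run once per session and memoised.

study_cache <- new.env()

acceptance_study <- function() {
  if (is.null(study_cache$st)) {
    study_cache$st <- sim_study(n_wells = 50, seed = 1,
                                config = sim_config(), quiet = TRUE)
  }
  study_cache$st
}
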