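fixture_path <- function() {
  system.file("extdata", "table1_icc.csv", package = "iccpool")
}

fixture_table <- function() {
  read_study_table(fixture_path())
}

# literal transcription of the Swiger formula, kept independent of the
# package implementation for oracle checks
swiger_ref <- function(rho, n, k) {
  m <- n / k
  2 * (n - 1) * (1 - rho)^2 * (1 + (m - 1) * rho)^2 / (m^2 * (n - k) * (k - 1))
}

# two-record table in two studies with well-separated estimates
two_record_table <- function(w1 = 1, w2 = 1, sw1 = 1, sw2 = 1) {
  study_table(study_id = c("a", "b"), outcome_id = c(1, 1),
              icc = c(0.02, 0.30), n = c(500, 500), k = c(20, 20),
              study_weight = c(sw1, sw2), outcome_weight = c(w1, w2))
}

quick_control <- function(...) {
  icc_control(n_chains = 2, n_iter = 2000, n_burnin = 500, ...)
}
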