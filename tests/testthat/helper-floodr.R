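# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs on a laptop in a few minutes.

# a compact cohort configuration for unit tests
tiny_config <- function(n_subjects = 4L, events_per_sample = 1000L, ...) {
  cohort_config(n_subjects = n_subjects,
                events_per_sample = events_per_sample, ...)
}

# concentrations table with a single neutrophil population carrying all mass
single_subset_concentrations <- function(label = "CD16brightCD62Lbright") {
  conc <- default_subset_concentrations()
  conc$concentration <- ifelse(conc$population == label, 2, 0)
  conc
}

# three cleanly separated clusters for exact-classification tests:
# narrow dispersion, no background noise, modes >= 10x apart across thresholds
separated_config <- function(events_per_sample = 2000L) {
  cohort_config(
    n_subjects = 1L, sessions = "morning", days = 1L,
    events_per_sample = events_per_sample,
    subject_cv = 0, sample_cv = 0, subject_marker_cv = 0,
    marker_cv = 0.10, granule_cv = 0, noise_sd = 0
  )
}

# bootstrap standard error of the median
boot_se_median <- function(x, reps = 200L) {
  stats::sd(vapply(seq_len(reps), function(i) {
    stats::median(sample(x, replace = TRUE))
  }, numeric(1)))
}

# brute-force one-way within-subject sums of squares by explicit loops,
# independent of the package's vectorised decomposition
bruteforce_rm_ss <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- sum(y) / (n * k)
  ss_subject <- 0; ss_time <- 0; ss_total <- 0
  for (i in seq_len(n)) ss_subject <- ss_subject + k * (mean(y[i, ]) - grand)^2
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(y[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_total <- ss_total + (y[i, j] - grand)^2
  }
  ss_error <- ss_total - ss_subject - ss_time
  list(ss_subject = unname(ss_subject), ss_time = unname(ss_time),
       ss_error = unname(ss_error),
       f = unname((ss_time / (k - 1)) / (ss_error / ((n - 1) * (k - 1)))))
}

# long tibble from a subjects x times matrix
rm_long <- function(y) {
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(nrow(y))), times = ncol(y)),
    time = rep(colnames(y), each = nrow(y)),
    value = as.vector(y)
  )
}
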