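# In-code fixtures for property-style tests.

# random but structurally valid cohort; extra_col exercises round-trip
# preservation of unknown columns
random_cohort <- function(n, seed, extra_col = FALSE) {
  set.seed(seed)
  colors <- function() sample(c("GREEN", "YELLOW", "RED"), n, replace = TRUE)
  df <- data.frame(
    patient_id = sprintf("P%03d", sample.int(999, n)),
    mla_deg = round(runif(n, 0, 359.9), 1),
    outcome = sample(c("ICD", "NOICD", "SPONTANEOUS", "OPERATIVE_VD",
                       "ICD_AFTER_FAILURE"), n, replace = TRUE),
    aida_mla = colors(), aida_aop = colors(),
    aida_spd = colors(), aida_ad = colors())
  if (extra_col) df$site <- sample(c("A", "B"), n, replace = TRUE)
  as_cohort(df)
}

# two linearly separated outcome groups: every backend should get these right
separable_cohort <- function(n_per_class = 30) {
  df <- data.frame(
    patient_id = sprintf("C%03d", seq_len(2 * n_per_class)),
    mla_deg = c(rep(90, n_per_class), rep(60, n_per_class)),
    outcome = c(rep("ICD", n_per_class), rep("NOICD", n_per_class)),
    aida_mla = c(rep("RED", n_per_class), rep("GREEN", n_per_class)),
    aida_aop = c(rep("RED", n_per_class), rep("GREEN", n_per_class)),
    aida_spd = c(rep("RED", n_per_class), rep("GREEN", n_per_class)),
    aida_ad = c(rep("RED", n_per_class), rep("GREEN", n_per_class)))
  as_cohort(df)
}
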