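# Shared fixtures built in code.

# a small, fast cohort configuration for tests that do not need trial scale
fast_config <- function(...) {
  cohort_config(n_patients = 30, vocab_size = 60, library_size_mean = 2000,
                seed = 101, ...)
}

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                1L, 3L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("tA", "tB", "tC")))
  taxa_count_table(m)
}

# subject-level analysis frame at the final visit, with the mediator taken
# from the generator truth
final_visit_frame <- function(cohort) {
  d <- cohort$clinical[cohort$clinical$visit_month ==
                         max(cohort$config$visit_months), ]
  tr <- cohort$truth$subjects
  d$treatment <- as.integer(d$arm == "antibiotic")
  d$category <- tr$category[match(d$subject_id, tr$subject_id)]
  d$baseline_normo <- tr$baseline_normo[match(d$subject_id, tr$subject_id)]
  d
}

# mediator-model data frame (subject level)
mediator_frame <- function(cohort) {
  tr <- cohort$truth$subjects
  data.frame(category = tr$category,
             treatment = as.integer(tr$arm == "antibiotic"),
             baseline_normo = tr$baseline_normo,
             age_band = tr$age_band, sex = tr$sex,
             smoking = tr$smoking)
}
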