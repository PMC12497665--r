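# one moderately sized cohort manifest shared by the generator tests
# (generated once per test run)
shared_cohort_env <- new.env()

shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort)) {
    sp <- phantom_spec(n_cases = 150, seed = 42, grid_dim = c(48, 48, 20),
                       regions_per_case = c("1" = 0.2, "2" = 0.3, "3" = 0.5))
    shared_cohort_env$cohort <- generate_cohort(sp, keep_cases = FALSE)
    shared_cohort_env$spec <- sp
  }
  list(manifest = shared_cohort_env$cohort$manifest,
       spec = shared_cohort_env$spec)
}
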