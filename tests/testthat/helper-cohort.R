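# Shared fixtures, generated in code and memoized across test files.

.tc_fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .tc_fixtures)) assign(key, expr, envir = .tc_fixtures)
  get(key, envir = .tc_fixtures)
}

# small cohort for fast module tests
small_cohort <- function() memo("small", {
  generate_cohort(generator_config(n_nodes = 24, n_subjects = 4, seed = 42))
})

# the acceptance-scale stated world: 20 subjects x 74 nodes, mixing weight
# calibrated to the 0.49 inter-subject correlation target
acc_config <- function() memo("acc_config", {
  calibrate_intersubject_mix(generator_config(n_subjects = 20, seed = 11),
                             target = 0.49)
})

acc_cohort <- function() memo("acc_cohort", generate_cohort(acc_config()))

# per-subject pairwise energies for the acceptance cohort, computed once
acc_pairwise <- function() memo("acc_pairwise", {
  lapply(acc_cohort()$subjects, pairwise_energies)
})
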