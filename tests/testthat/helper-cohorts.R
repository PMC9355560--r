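# Simulation-study cohorts shared by the parameter-recovery and
# brain-behaviour acceptance tests: computed once per test run, on first use.
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohorts <- function(n_cohorts = 10L, n_per_group = 6L) {
  key <- sprintf("c_%d_%d", n_cohorts, n_per_group)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  res <- lapply(seq_len(n_cohorts), function(i) {
    run_cohort(n_per_group = n_per_group, seed = 1000L + i,
               settings = study_settings("reduced"))
  })
  .cohort_cache[[key]] <- res
  res
}

# final-superblock group means for one representation
final_superblock_means <- function(cohort, representation) {
  tab <- cohort$superblock_table
  last <- max(tab$superblock)
  sel <- tab[tab$representation == representation & tab$superblock == last, ]
  c(stress = sel$mean_accuracy[sel$group == "stress"],
    control = sel$mean_accuracy[sel$group == "control"])
}
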