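# Shared cohort constructors for the suite.  Small problem sizes keep
# individual tests fast; the acceptance tests build their own cohorts
# at the sizes the analysis design calls for.

two_group_spec <- function(n_per_group = 8, n_rois = 20,
                           n_informative_edges = 10, d = 3,
                           subject_sd = 0.1, scan_sd = 0.1, seed = 101) {
  spec <- cohort_spec(list(group_spec(n_per_group, 19, 35, "young"),
                           group_spec(n_per_group, 55, 85, "old")),
                      n_rois = n_rois,
                      n_informative_edges = n_informative_edges,
                      subject_sd = subject_sd, scan_sd = scan_sd,
                      seed = seed)
  spec$edge_effect <- if (subject_sd > 0 || scan_sd > 0)
    edge_effect_for_d(d, spec) else 0.5
  spec
}

noiseless_binary_cohort <- function(n_per_group = 5, n_rois = 12, seed = 7) {
  spec <- two_group_spec(n_per_group, n_rois, n_informative_edges = 6,
                         subject_sd = 0, scan_sd = 0, seed = seed)
  generate_cohort(spec)
}

linear_age_spec <- function(n_subjects = c(10, 8, 6), n_rois = 20,
                            n_informative_edges = 10, edge_effect = 0.15,
                            subject_sd = 0.1, scan_sd = 0.1, seed = 202) {
  cohort_spec(list(group_spec(n_subjects[1], 19, 37, "young"),
                   group_spec(n_subjects[2], 42, 60, "middle"),
                   group_spec(n_subjects[3], 61, 85, "old")),
              n_rois = n_rois, n_informative_edges = n_informative_edges,
              edge_effect = edge_effect, subject_sd = subject_sd,
              scan_sd = scan_sd, seed = seed)
}

extdata <- function(f) system.file("extdata", f, package = "connsvm")
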