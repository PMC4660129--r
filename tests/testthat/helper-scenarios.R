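# Build the full feature pathway for one synthetic dataset: generate,
# label, restrict to pre-index history, featurize.
featurized_dataset <- function(spec, seed) {
  ds <- generate_cohort(spec, seed = seed)
  cohort <- build_cohort(ds$log, ds$vocabulary$target_code)
  x <- build_features(prior_events(ds$log, cohort), cohort)
  list(dataset = ds, cohort = cohort, features = x,
       planted = planted_feature_names(ds))
}
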