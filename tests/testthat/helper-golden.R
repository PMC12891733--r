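# Frozen toy-study regression: the exact run whose reports are stored
# under tests/testthat/golden/.

golden_cfg <- function() {
  sim_config(n_subjects = 4, n_clonotypes = 500, depth = 10000,
             n_spiked_per_antigen = 3, public_clone_count = 1,
             tumor_overlap_count = 2, seed = 101)
}

# simulate the toy study and run both pipelines; returns the output dirs
run_golden_study <- function(root = tempfile("golden_run")) {
  study_dir <- file.path(root, "study")
  simulate_study_dir(golden_cfg(), study_dir)
  study <- read_study(study_dir)
  run_expansion_pipeline(study, file.path(root, "expansion"))
  run_elispot_pipeline(study, file.path(root, "elispot"))
  list(study = study_dir,
       expansion = file.path(root, "expansion"),
       elispot = file.path(root, "elispot"))
}

golden_compare_files <- function() {
  c("expansion/specific_catalogue.tsv", "expansion/equitability.tsv",
    "expansion/public_clonotypes.tsv", "expansion/tumor_overlap.tsv",
    "expansion/expansion_summary.json",
    "elispot/responder_calls.tsv", "elispot/antigen_positivity.tsv",
    "elispot/survival_strata.tsv", "elispot/elispot_summary.json")
}
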