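# Cohort fixtures shared across test files. Everything is generated in
# code under fixed seeds; heavyweight feature tables are computed once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# smooth blob volume for interpolation / registration checks
blob_volume <- function(dims = c(24, 24, 24), center = (dims + 1) / 2,
                        width = 5, spacing = c(1, 1, 1)) {
  X <- array(rep(seq_len(dims[1]), prod(dims[2:3])), dims)
  Y <- array(rep(rep(seq_len(dims[2]), each = dims[1]), dims[3]), dims)
  Z <- array(rep(seq_len(dims[3]), each = prod(dims[1:2])), dims)
  r2 <- (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2
  volume(100 * exp(-r2 / (2 * width^2)), spacing = spacing)
}

pair_cohort <- function() {
  cached("pair_cohort",
         generate_cohort(c("MSA-P" = 34, "PD" = 56), master_seed = 1))
}

pair_tables <- function(kind) {
  key <- paste0("pair_tab_", kind)
  cached(key, cohort_features(pair_cohort(), kind))
}

null_truth_table <- function() {
  cached("null_truth_table", {
    co <- generate_cohort(c("MSA-P" = 34, "PD" = 56),
                          spec = phantom_spec(effects = phantom_effects(scale = 0)),
                          master_seed = 2)
    tab <- cohort_features(co, "truth")
    rm(co); gc(verbose = FALSE)
    tab
  })
}

mean_test_auc <- function(report) {
  s <- report$summary
  s$AUC.mean[s$split == "test"]
}
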