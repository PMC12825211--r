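# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A selective 8-configuration interference trial plus its preprocessing.
selective_trial <- function() cached("selective_trial", function() {
  spec <- trial_spec(n_configs = 8, mode = "TIS4", seed = 1)
  labels <- enumerate_sweep(cuff_grid(), "TIS4")$label[1:8]
  lib <- motif_library(labels, "selective", seed = 1)
  trial <- generate_trial(spec, lib)
  trial$prep <- preprocess_trial(trial$series, trial$epochs)
  trial$lib <- lib
  trial
})

# A nonselective 8-configuration bipolar trial plus preprocessing.
nonselective_trial <- function() cached("nonselective_trial", function() {
  spec <- trial_spec(n_configs = 8, mode = "BP2", seed = 2)
  labels <- enumerate_sweep(cuff_grid(), "BP2")$label[1:8]
  lib <- motif_library(labels, "nonselective", seed = 2)
  trial <- generate_trial(spec, lib)
  trial$prep <- preprocess_trial(trial$series, trial$epochs)
  trial$lib <- lib
  trial
})

# A small 2-configuration trial for fast embedding tests.
tiny_trial <- function() cached("tiny_trial", function() {
  spec <- trial_spec(n_configs = 2, mode = "TIS4", seed = 3)
  labels <- enumerate_sweep(cuff_grid(), "TIS4")$label[1:2]
  lib <- motif_library(labels, "selective", seed = 3)
  trial <- generate_trial(spec, lib)
  trial$prep <- preprocess_trial(trial$series, trial$epochs)
  trial
})
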