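# Shared cache so that expensive reference computations (the ABM grid
# search, the training datasets) are built once per test run.
.abmode_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .abmode_test_cache)) {
    assign(name, force(expr), envir = .abmode_test_cache)
  }
  get(name, envir = .abmode_test_cache)
}

# plain-column view of a trajectory for value comparisons
strip_traj <- function(tr) {
  df <- as.data.frame(tr)
  attributes(df) <- attributes(df)[c("names", "class")]
  rownames(df) <- NULL
  df
}
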