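# Shared fixture cache: building the default synthetic panel and running
# the pipeline on it takes tens of seconds, so test files share one copy.
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- make_fixture(sim_config(seed = 7))
  }
  .fixture_cache$fx
}

default_report <- function() {
  if (is.null(.fixture_cache$report)) {
    .fixture_cache$report <- run_pipeline(default_fixture())
  }
  .fixture_cache$report
}
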