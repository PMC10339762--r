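# shared test helpers: a tiny synthetic assignment table, cached copies of
# the packaged fixture and of the full pipeline run (both are deterministic,
# so one instance serves every test file)

.cache <- new.env(parent = emptyenv())

# small, well-separated eight-peak fingerprint for unit tests (enough
# residues for the mean + 2 SD threshold to behave sensibly)
tiny_assignments <- function() {
  assignment_table(
    residue = c(5L, 11L, 20L, 31L, 44L, 52L, 63L, 71L),
    code = c("A", "C", "S", "H", "K", "G", "T", "V"),
    w_H = c(7.6, 8.2, 8.8, 9.3, 7.9, 8.5, 9.0, 7.3),
    w_N = c(108, 115, 122, 128, 118, 106, 131, 125),
    name = "tiny")
}

test_fixture <- function(seed = 20230223L) {
  key <- paste0("fx", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- make_ccl28_fixture(seed)
  .cache[[key]]
}

pipeline_report_cached <- function() {
  if (is.null(.cache$report)) {
    cfg <- pipeline_config()
    .cache$report <- run_pipeline(cfg, test_fixture(cfg$seed))
  }
  .cache$report
}
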