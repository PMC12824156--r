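# Shared fixtures: small cohort configs and a CSV writer for IO tests.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_videos = 2, duration_s = 20, n_observers = 15, seed = 7L),
    list(...))
  do.call(synthetic_config, args)
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

valid_rows <- c(
  "observer_id,video_id,condition,time_s,valence,arousal",
  "o1,v1,context_only,0,0.2,-0.1",
  "o1,v1,context_only,0.5,0.3,0",
  "o2,v1,ground_truth,0,-0.8,0.9")
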