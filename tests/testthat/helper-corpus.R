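# shared fixtures, generated once per test session

.fx <- new.env(parent = emptyenv())

# small three-source corpus: walk + clap + forward fall, 5 subjects each,
# exercising all three unit/rate dialects
tiny_sources <- function(n_subjects = 5, acts = default_activity_profiles()[c(1, 5, 6)]) {
  mk <- function(name, rate, au, gu)
    list(dataset_name = name, sample_rate = rate, acc_units = au,
         gyr_units = gu, n_subjects = n_subjects, activities = acts,
         trials_per_activity = 3, trial_duration = 15)
  list(mk("TinyA", 18, "g", "rad/s"),
       mk("TinyB", 20, "m/s2", "deg/s"),
       mk("TinyC", 50, "g", "rad/s"))
}

tiny_manifest <- function() {
  if (is.null(.fx$manifest)) {
    cfg <- generator_config(tiny_sources(), seed = 7)
    dir <- file.path(tempdir(), "fallarc-tiny-corpus")
    .fx$manifest <- generate_dataset(cfg, dir)
  }
  .fx$manifest
}

tiny_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- harmonize_corpus(tiny_manifest())
  .fx$corpus
}

tiny_features <- function() {
  if (is.null(.fx$features))
    .fx$features <- featurize_corpus(tiny_corpus(), window_spec(rate = 18))
  .fx$features
}

# fixture with a planted label-copy, a few informative columns, and noise
planted_features <- function(n = 240, n_cols = 78, n_informative = 3,
                             seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  x <- as.data.frame(matrix(rnorm(n * n_cols), n, n_cols))
  names(x) <- sprintf("f%02d", seq_len(n_cols))
  x[["f01"]] <- y                                   # label copy
  for (j in seq_len(n_informative))
    x[[j + 1]] <- y * 1.5 + rnorm(n, 0, 1)          # informative but noisy
  groups <- sprintf("subj%02d", rep_len(1:12, n))
  list(x = x, y = y, groups = groups,
       informative = sprintf("f%02d", 1:(n_informative + 1)),
       noise = sprintf("f%02d", (n_informative + 2):n_cols))
}
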