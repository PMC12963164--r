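# Shared fixtures, built in code.

# A classifier oracle that thresholds the normalized cyan-like value: cheap
# stand-in for the SVM in pipeline-mechanics tests.
threshold_classifier <- function(threshold = 60) {
  function(features) ifelse(features$dCyan > threshold, "after", "before")
}

# Reference SVM trained once per test run on ten noisy synthetic scenes
# (mirroring a ten-video training set) and cached for every test that needs
# a real model.
.model_cache <- new.env(parent = emptyenv())

trained_test_model <- function() {
  if (!is.null(.model_cache$model)) {
    return(.model_cache$model)
  }
  feats <- list()
  onsets <- numeric(0)
  for (s in 1:10) {
    cfg <- random_scene_config(1000 + s, duration = 300, entry_time = 60,
                               noise_sd = 8, drape_ramp = 15)
    sc <- generate_scene(cfg)
    box <- expand_box(
      detect_bed(sc$video, cfg$entry_time,
                 color_region_detector(cfg$pre_drape_color)),
      1.2, c(sc$video$width, sc$video$height))
    f <- extract_color_features(sc$video, box, cfg$entry_time)
    feats[[s]] <- normalize_to_entry(f)
    onsets <- c(onsets, cfg$drape_onset - cfg$entry_time)
  }
  train <- assemble_training_set(feats, onsets, seed = 99)
  .model_cache$model <- train_drape_classifier(train)
  .model_cache$model
}

# Brute-force window-scan oracle for the confirmation rule (equally spaced
# streams): first index i with run_length consecutive "after" labels.
confirm_oracle <- function(labels, t, run_length = 10) {
  n <- length(labels)
  if (n >= run_length) {
    for (i in seq_len(n - run_length + 1)) {
      if (all(labels[i:(i + run_length - 1)] == "after")) {
        return(list(status = "detected", onset_t = t[i],
                    confirm_t = t[i + run_length - 1]))
      }
    }
  }
  list(status = "not_detected", onset_t = NA_real_, confirm_t = NA_real_)
}

# Brute-force exact two-sided signed-rank p by enumerating all 2^n sign
# assignments (mid-ranks for ties), independent of the package's
# generating-function implementation.
signed_rank_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
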