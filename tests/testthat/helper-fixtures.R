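# Shared fixtures, built once per test run and cached. The "standard
# protocol" is the desk-scale study: 10 subjects (5 per class), 2
# sessions of 2 minutes at 100 Hz, clearly separable morphology; the
# scaled classifier is the full architecture at reduced width (16 hidden
# units), trained 50 epochs at learning rate 0.002.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

std_cohort <- function() fixture("cohort", function() {
  generate_cohort(n_per_class = 5, sessions = 2, duration_s = 120,
                  fs = 100, seed = 11)
})

std_dataset <- function() fixture("dataset", function() {
  build_window_dataset(std_cohort(), preprocess = TRUE)
})

std_raw_dataset <- function() fixture("raw_dataset", function() {
  build_window_dataset(std_cohort(), preprocess = FALSE)
})

std_split <- function() fixture("split", function() {
  split_dataset(std_dataset(), seed = 5)
})

scaled_spec <- function() {
  model_spec(lstm_hidden = 16L, attn_width = 16L, dense_width = 32L,
             dropout = 0)
}

scaled_config <- function(seed = 1L) {
  train_config(learn_rate = 0.002, batch_size = 32L, num_epochs = 50L,
               rng_seed = seed)
}

# trained models are expensive; cache per (kind, seed)
std_trained <- function(kind = "lstm_attention", seed = 1L) {
  key <- sprintf("model_%s_%d", kind, seed)
  fixture(key, function() {
    train_model(kind, std_dataset(), std_split(), scaled_spec(),
                scaled_config(seed))
  })
}

test_accuracy_of <- function(model) {
  ds <- std_dataset(); spl <- std_split()
  X <- ds$X[spl == "test", , drop = FALSE]
  y <- ds$label[spl == "test"]
  pred <- model$classes[max.col(predict_proba(model, X))]
  evaluation_report(pred, y)$accuracy
}

# one clean healthy record with ground truth, reused across files
clean_record <- function(hr = 75, seed = 3, duration = 30,
                         noise_sd = 0, drift_amp = 0, jitter = 0.03) {
  p <- subject_profile("S1", "healthy", hr, hr_jitter_sd = jitter,
                       noise_sd = noise_sd, drift_amp = drift_amp,
                       rng_seed = seed)
  generate_record(p, duration, 100)
}

# tiny architecture for fast structural/gradient tests
tiny_spec <- function(dropout = 0) {
  model_spec(input_len = 80L, conv1_kernels = 2L, conv1_width = 40L,
             conv1_stride = 20L, lstm_layers = 2L, lstm_hidden = 3L,
             attn_width = 3L, conv2_kernels = 2L, conv2_width = 2L,
             conv2_stride = 1L, dense_width = 4L, dropout = dropout)
}
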