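# Shared fixtures, built programmatically and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

tiny_sim_config <- function(seed = 7L, sigma = 0) {
  gait_sim_config(n_subjects = 1L, n_cycles_per_subject = 10L,
                  noise = noise_config(sigma = sigma), seed = seed)
}

tiny_dataset <- function() memo("tiny_ds", function() build_dataset(tiny_sim_config()))

# the scaled-down study dataset used by the distillation checks
study_dataset <- function() {
  memo("study_ds", function() {
    build_dataset(gait_sim_config(n_subjects = 2L, n_cycles_per_subject = 30L,
                                  seed = 11L))
  })
}

study_teacher <- function() {
  memo("study_teacher", function() {
    train_teacher(study_dataset(), teacher_config("test"),
                  train_config(epochs = 40L, batch_size = 14L, seed = 5L),
                  joint = "hip")
  })
}

random_psd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(rnorm(d * d), d, d)
  crossprod(w)
}

held_out_r2 <- function(pred, cycles, joint = "hip", axis = 3L) {
  d <- gaitkd:::stack_student_inputs(cycles, joint)
  mean(vapply(seq_along(cycles), function(i) {
    accuracy_metrics(d$tau[i, , axis], pred[i, , axis])["r2"]
  }, numeric(1)))
}
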