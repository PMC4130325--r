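# One trained study (test profile, fixed seed) shared by the acceptance and
# integration tests; built on first use and cached for the rest of the run.

.study_cache <- new.env(parent = emptyenv())

acceptance_config <- function() default_config("test", seed = 1)

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- acceptance_config()
    ts <- build_trainset(cfg)
    .study_cache$trainset <- ts
    .study_cache$study <- train_study(cfg, trainset = ts)
  }
  .study_cache$study
}

# Untrained control: same architecture and seed handling, no learning.
untrained_study <- function() {
  if (is.null(.study_cache$untrained)) {
    st <- acceptance_study()
    .study_cache$untrained <- train_study(st$config, trainset = st$trainset,
                                          train = FALSE)
  }
  .study_cache$untrained
}

acceptance_scenes <- function() {
  if (is.null(.study_cache$scenes)) {
    cfg <- acceptance_config()
    # 16 scenes (64 objects) so that at least 48 object patches are scored
    # even when a few saliency fixations land beyond the match radius
    .study_cache$scenes <- make_scene_set(16, seed = cfg$seed,
                                          size = cfg$scene$size,
                                          n_distractors = cfg$scene$n_distractors,
                                          noise_amp = cfg$scene$noise_amp)
  }
  .study_cache$scenes
}

acceptance_scene_report <- function() {
  if (is.null(.study_cache$report)) {
    .study_cache$report <- suppressWarnings(
      run_scene_pipeline(acceptance_study(), acceptance_scenes()))
  }
  .study_cache$report
}

untrained_scene_report <- function() {
  if (is.null(.study_cache$report0)) {
    # same scenes, hence same saliency and fixations: only the network differs
    .study_cache$report0 <- suppressWarnings(
      run_scene_pipeline(untrained_study(), acceptance_scenes(),
                         fixations = acceptance_scene_report()$fixations))
  }
  .study_cache$report0
}

acceptance_translation_sweep <- function() {
  if (is.null(.study_cache$tsweep)) {
    .study_cache$tsweep <- evaluate_translation_sweep(acceptance_study())
  }
  .study_cache$tsweep
}

acceptance_view_sweep <- function() {
  if (is.null(.study_cache$vsweep)) {
    .study_cache$vsweep <- evaluate_view_sweep(acceptance_study())
  }
  .study_cache$vsweep
}
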