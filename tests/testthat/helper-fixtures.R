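# shared fixtures; expensive objects are built once per session

tiny_arch <- function(num_classes = 2L)
  gptnext_spec(filters = c(4L, 8L, 16L, 32L, 24L), input_side = 32L,
               num_classes = num_classes, expansion_factor = 2L)

small_arch <- function(num_classes = 3L)
  gptnext_spec(filters = c(8L, 16L, 32L, 64L, 96L), input_side = 64L,
               num_classes = num_classes)

rand_image <- function(side, seed = 1) {
  set.seed(seed)
  array(runif(side * side * 3), c(side, side, 3))
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a tiny untrained model, reused across read-only tests
tiny_model <- function() memo("tiny_model", build_model(tiny_arch(), init_seed = 7L))

# 2-class strong-signal synthetic images + a model trained on them for 5 epochs
trained_small <- function() memo("trained_small", {
  sspec <- synthetic_image_spec(n_classes = 2, train_per_class = 32,
                                test_per_class = 10, image_side = 64, seed = 3)
  ds <- generate_image_arrays(sspec)
  model <- build_model(small_arch(2L), init_seed = 5L)
  res <- train_model(model, ds$train, train_config(max_epochs = 5L, seed = 11L))
  list(ds = ds, model = res$model, trace = res$trace)
})

# one full pipeline run (synth -> train -> features -> select -> evaluate)
# on the default 3-class synthetic study conditions
e2e_run <- function() memo("e2e_run", {
  root <- file.path(tempdir(), "gptnext-e2e")
  cfg <- pipeline_config(data_dir = file.path(root, "data"),
                         artifacts_dir = file.path(root, "artifacts"),
                         train = train_config(max_epochs = 5L, seed = 1L),
                         seed = 42L)
  suppressMessages({
    run_synth(cfg)
    run_train(cfg)
    run_features(cfg, "train")
    run_features(cfg, "test")
    run_select(cfg)
    reports <- run_evaluate(cfg)
  })
  list(cfg = cfg, reports = reports)
})
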