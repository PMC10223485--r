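#' Read a YAML configuration
#'
#' Sections `preprocess:`, `augment:`, `model:`, `train:`, `split:`, and
#' `synthetic:` map onto [preprocess_config()], [augmentation_config()],
#' [ensemble_spec()], [train_config()], [split_spec()], and
#' [synthetic_config()]; fields missing from the file keep their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return Named list of the six configuration objects.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    unknown <- setdiff(names(args), known)
    if (length(unknown) > 0L) {
      stop("unknown field(s) in '", section, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    do.call(ctor, lapply(args, unlist))
  }
  list(
    preprocess = build("preprocess", preprocess_config),
    augment = build("augment", augmentation_config),
    model = build("model", ensemble_spec),
    train = build("train", train_config),
    split = build("split", split_spec),
    synthetic = build("synthetic", synthetic_config)
  )
}

#' Run the full synthetic end-to-end experiment
#'
#' The desk-scale counterpart of the real-data protocol: generate the
#' multi-subject synthetic collection, filter/normalize/segment it (with
#' normalization statistics fitted on non-test subjects only), hold out one
#' young and one elderly subject, train the default class-based ensemble
#' under `n_seeds` seeds with online augmentation, and evaluate per-event
#' metrics on the held-out subjects.
#'
#' @param seed Master seed; generator and per-run training seeds derive
#'   from it.
#' @param n_seeds Number of replicate training runs (default 3).
#' @param max_epochs Training epoch cap per run (default 30).
#' @param synth A [synthetic_config()]; its `rng_seed` is set from `seed`.
#' @param spec,train_cfg,aug Architecture, training, and augmentation
#'   configuration.
#' @param n_test_young,n_test_elderly Held-out subjects per group.
#' @param verbose Print training progress.
#' @return List with `report` (a `fall_report`), `fits`, `splits`, and
#'   `block_counts` (per-class block histogram of the full dataset).
#' @export
run_synthetic_experiment <- function(seed = 1L,
                                     n_seeds = 3L,
                                     max_epochs = 30L,
                                     synth = synthetic_config(),
                                     spec = ensemble_spec(),
                                     train_cfg = train_config(),
                                     aug = augmentation_config(),
                                     n_test_young = 1L,
                                     n_test_elderly = 1L,
                                     verbose = FALSE) {
  synth$rng_seed <- as.integer(seed)
  dataset <- generate_dataset(synth)
  dataset$trials <- lapply(dataset$trials, select_channels)

  pre_cfg <- preprocess_config(sample_rate_hz = synth$sample_rate_hz)
  sp <- split_spec(n_test_young = n_test_young, n_test_elderly = n_test_elderly,
                   split_seed = as.integer(seed))

  # decide test subjects first so normalization statistics come from
  # training subjects only
  set.seed(sp$split_seed)
  test_subjects <- c(
    sample(dataset$roster$subject_id[dataset$roster$group == "young"], n_test_young),
    sample(dataset$roster$subject_id[dataset$roster$group == "elderly"], n_test_elderly)
  )
  sp$test_subjects <- test_subjects
  trial_subject <- vapply(dataset$trials, function(t) t$trial$subject_id, "")
  fit_trials <- dataset$trials[!(trial_subject %in% test_subjects)]

  pp <- preprocess_trials(dataset$trials, pre_cfg, fit_trials = fit_trials)
  splits <- make_splits(pp$blocks, sp)

  train_cfg$max_epochs <- as.integer(max_epochs)
  seeds <- as.integer(seed) * 100L + seq_len(n_seeds)
  fits <- train_replicates(splits$train, splits$val, spec, train_cfg, aug,
                           seeds = seeds, verbose = verbose)
  report <- evaluation_report(fits, splits$test)
  list(report = report, fits = fits, splits = splits,
       block_counts = tabulate(pp$blocks$label + 1L, 3L),
       stats = pp$stats)
}
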