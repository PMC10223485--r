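#' Subject-wise split specification
#'
#' The test partition holds complete subjects (default four young and two
#' elderly, the real-data protocol), so no individual contributes blocks to
#' both training and test. The remaining blocks are split 80/20 into
#' train/validation, stratified by block label.
#'
#' @param test_subjects Explicit character vector of test subject ids, or
#'   `NULL` to draw `n_test_young` + `n_test_elderly` deterministically with
#'   `split_seed`.
#' @param n_test_young,n_test_elderly Group counts when drawing.
#' @param train_val_ratio Fraction of remaining blocks used for training.
#' @param split_seed Seed for the subject draw and the stratified shuffle.
#' @return A `split_spec`.
#' @export
split_spec <- function(test_subjects = NULL,
                       n_test_young = 4L, n_test_elderly = 2L,
                       train_val_ratio = 0.8,
                       split_seed = 1L) {
  stopifnot(train_val_ratio > 0, train_val_ratio < 1)
  structure(
    list(test_subjects = test_subjects,
         n_test_young = as.integer(n_test_young),
         n_test_elderly = as.integer(n_test_elderly),
         train_val_ratio = train_val_ratio,
         split_seed = as.integer(split_seed)),
    class = "split_spec"
  )
}

subject_group_of <- function(subject_id) {
  ifelse(startsWith(subject_id, "SE"), "elderly", "young")
}

# Exact stratified split: per-class largest-remainder rounding so the total
# train count is exactly round(ratio * N) and each class deviates from the
# ratio by less than one block.
stratified_train_indices <- function(labels, ratio) {
  N <- length(labels)
  n_train <- round(ratio * N)
  classes <- sort(unique(labels))
  shuffled <- lapply(classes, function(cl) sample(which(labels == cl)))
  n_c <- lengths(shuffled)
  base <- floor(ratio * n_c)
  frac <- ratio * n_c - base
  leftover <- n_train - sum(base)
  take <- base
  if (leftover > 0L) {
    bump <- order(frac, decreasing = TRUE)[seq_len(leftover)]
    take[bump] <- take[bump] + 1L
  } else if (leftover < 0L) {
    drop_ <- order(frac)[seq_len(-leftover)]
    take[drop_] <- take[drop_] - 1L
  }
  unlist(lapply(seq_along(classes), function(i) {
    shuffled[[i]][seq_len(take[i])]
  }))
}

#' Partition a block dataset into train / validation / test
#'
#' @param ds A `block_dataset`.
#' @param spec A [split_spec()].
#' @return List with `train`, `val`, `test` block datasets and
#'   `test_subjects`.
#' @export
make_splits <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "block_dataset"), inherits(spec, "split_spec"))
  subjects <- unique(ds$subject_id)
  if (length(subjects) < 3L) {
    stop("need at least 3 subjects for a subject-wise split", call. = FALSE)
  }
  test_subjects <- spec$test_subjects
  if (is.null(test_subjects)) {
    groups <- subject_group_of(subjects)
    young <- subjects[groups == "young"]
    elderly <- subjects[groups == "elderly"]
    if (length(young) < spec$n_test_young || length(elderly) < spec$n_test_elderly) {
      stop("not enough subjects per group to draw the requested test set",
           call. = FALSE)
    }
    set.seed(spec$split_seed)
    test_subjects <- c(sample(young, spec$n_test_young),
                       sample(elderly, spec$n_test_elderly))
  }
  missing_subj <- setdiff(test_subjects, subjects)
  if (length(missing_subj) > 0L) {
    stop("test subject(s) absent from dataset: ",
         paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  is_test <- ds$subject_id %in% test_subjects
  rest_idx <- which(!is_test)
  set.seed(spec$split_seed + 1L)
  tr_local <- stratified_train_indices(ds$label[rest_idx], spec$train_val_ratio)
  train_idx <- rest_idx[tr_local]
  val_idx <- setdiff(rest_idx, train_idx)
  out <- list(train = ds[train_idx], val = ds[val_idx],
              test = ds[which(is_test)], test_subjects = test_subjects)
  stopifnot(length(intersect(unique(c(out$train$subject_id, out$val$subject_id)),
                             unique(out$test$subject_id))) == 0L)
  out
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, initial learning rate 0.0005,
#' batch size 128, at most 200 epochs, weighted binary cross-entropy with
#' automatic inverse-frequency class weights.
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is provided.
#' @param class_weights `"auto"` (inverse frequency) or an explicit
#'   non-negative vector, one weight per class.
#' @param early_stop_patience Stop after this many epochs without validation
#'   improvement; `Inf` disables early stopping.
#' @param rng_seed Seed controlling initialization, shuffling, augmentation,
#'   and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 128L,
                         max_epochs = 200L,
                         learning_rate = 0.0005,
                         optimizer = "adam",
                         class_weights = "auto",
                         early_stop_patience = Inf,
                         rng_seed = 1L) {
  stopifnot(batch_size >= 1L, max_epochs >= 1L, learning_rate >= 0,
            identical(optimizer, "adam"))
  structure(
    list(batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate,
         optimizer = optimizer,
         class_weights = class_weights,
         early_stop_patience = early_stop_patience,
         rng_seed = as.integer(rng_seed)),
    class = "train_config"
  )
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (n_classes * N_c)`, normalized so the smallest weight is 1;
#' balanced classes give all-ones.
#'
#' @param x A `block_dataset` or an integer label vector.
#' @param n_classes Number of classes.
#' @return Numeric weight vector of length `n_classes`.
#' @export
class_weights_auto <- function(x, n_classes = 3L) {
  labels <- if (inherits(x, "block_dataset")) x$label else validate_labels(x)
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    stop("class(es) ", paste(which(counts == 0L) - 1L, collapse = ", "),
         " absent from training data; supply explicit class weights",
         call. = FALSE)
  }
  w <- length(labels) / (n_classes * counts)
  w / min(w)
}

bce_eps <- 1e-7

#' Weighted binary cross-entropy loss
#'
#' Each ensemble sub-model is supervised as a one-vs-rest binary task: the
#' loss is `sum_c w_c * BCE(score_c, 1[target == c])`, averaged over the
#' batch. Scores are clipped at `1e-7` to guard `log(0)`.
#'
#' @param scores Numeric vector of per-class scores, or `N x n` matrix.
#' @param target Class label code(s).
#' @param weights Per-class weight vector.
#' @return Non-negative scalar loss.
#' @export
weighted_bce_loss <- function(scores, target, weights) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  n <- ncol(scores)
  stopifnot(length(weights) == n)
  target <- validate_labels(target)
  stopifnot(length(target) == nrow(scores))
  p <- pmin(pmax(scores, bce_eps), 1 - bce_eps)
  Y <- matrix(0, nrow(scores), n)
  Y[cbind(seq_len(nrow(scores)), target + 1L)] <- 1
  ll <- -(Y * log(p) + (1 - Y) * log(1 - p))
  mean(rowSums(sweep(ll, 2L, weights, `*`)))
}

onehot <- function(target, n) {
  Y <- matrix(0, length(target), n)
  Y[cbind(seq_along(target), target + 1L)] <- 1
  Y
}

val_metrics <- function(model, ds, weights) {
  scores <- predict_scores(model, ds)
  loss <- weighted_bce_loss(scores, ds$label, weights)
  pred <- fuse_proposed(scores)
  cm <- confusion_counts(pred, ds$label)
  sens <- vapply(seq_len(3L), function(i) {
    tp <- cm$tp[i]; fn <- cm$fn[i]
    if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  }, 0)
  list(loss = loss, sens = sens)
}

#' Train the class-based ensemble
#'
#' Runs the full training loop: per-epoch shuffling, online augmentation of
#' every training batch, joint weighted-BCE loss over all sub-models (the
#' shared head receives gradients from every class), Adam updates, and
#' per-epoch validation. The returned model carries the parameters of the
#' best validation-loss epoch.
#'
#' @param train_ds,val_ds Training and validation `block_dataset`s.
#' @param spec An [ensemble_spec()] (its `input_shape` is overridden by the
#'   data shape).
#' @param cfg A [train_config()].
#' @param aug An [augmentation_config()]; set `augmented_fraction = 0` to
#'   disable augmentation.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `final_model`, `history`
#'   (per-epoch data frame), and `class_weights`.
#' @export
train_fall_detector <- function(train_ds, val_ds,
                                spec = ensemble_spec(),
                                cfg = train_config(),
                                aug = augmentation_config(),
                                verbose = FALSE) {
  stopifnot(inherits(train_ds, "block_dataset"), inherits(val_ds, "block_dataset"))
  d <- dim(train_ds$samples)
  spec$input_shape <- c(d[2L], d[3L])
  set.seed(cfg$rng_seed)
  model <- build_class_ensemble(spec)
  n <- spec$n_classes
  weights <- if (identical(cfg$class_weights, "auto")) {
    class_weights_auto(train_ds, n)
  } else {
    stopifnot(length(cfg$class_weights) == n, all(cfg$class_weights >= 0))
    cfg$class_weights
  }
  state <- adam_init(model$params)
  N <- n_blocks(train_ds)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- vector("list", cfg$max_epochs)
  aug$rng_seed <- NULL  # inside the loop, randomness flows from cfg$rng_seed
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(N)
    batch_of <- ceiling(seq_along(ord) / cfg$batch_size)
    ep_loss <- 0
    for (b in split(ord, batch_of)) {
      ds_b <- train_ds[b]
      if (aug$augmented_fraction > 0) ds_b <- augment_batch(ds_b, aug)
      fw <- ensemble_forward(model, ds_b$samples, train = TRUE)
      p <- pmin(pmax(fw$scores, bce_eps), 1 - bce_eps)
      Y <- onehot(ds_b$label, n)
      ll <- -(Y * log(p) + (1 - Y) * log(1 - p))
      loss <- mean(rowSums(sweep(ll, 2L, weights, `*`)))
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate", call. = FALSE)
      }
      ep_loss <- ep_loss + loss * length(b)
      dlogits <- sweep(fw$scores - Y, 2L, weights, `*`) / length(b)
      grads <- ensemble_backward(model, fw, dlogits)$grads
      upd <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    vm <- val_metrics(model, val_ds, weights)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / N, val_loss = vm$loss,
      val_sens_non_fall = vm$sens[1L], val_sens_pre_fall = vm$sens[2L],
      val_sens_fall = vm$sens[3L]
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  sens %s",
                      epoch, ep_loss / N, vm$loss,
                      paste(sprintf("%.2f", vm$sens), collapse = "/")))
    }
    if (vm$loss < best$loss) {
      best <- list(loss = vm$loss, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$early_stop_patience) {
      break
    }
  }
  best_model <- model
  best_model$params <- best$params
  list(model = best_model, final_model = model,
       history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
       class_weights = weights, best_epoch = best$epoch)
}

#' Replicated training runs
#'
#' Trains the same configuration under several seeds (three by default, the
#' study's replicate convention); downstream reporting shows mean and
#' standard deviation across the runs.
#'
#' @inheritParams train_fall_detector
#' @param seeds Integer vector of seeds, one run each.
#' @return List of [train_fall_detector()] results.
#' @export
train_replicates <- function(train_ds, val_ds,
                             spec = ensemble_spec(),
                             cfg = train_config(),
                             aug = augmentation_config(),
                             seeds = c(1L, 2L, 3L),
                             verbose = FALSE) {
  lapply(seeds, function(s) {
    cfg$rng_seed <- as.integer(s)
    train_fall_detector(train_ds, val_ds, spec, cfg, aug, verbose = verbose)
  })
}
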