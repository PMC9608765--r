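#' Posture classifier specification
#'
#' Configuration of the multilayer-perceptron posture classifier: a single
#' hidden layer trained by BFGS with weight decay, with early stopping scored
#' on a validation split carved from the training windows. Training is
#' chunked: the optimiser runs `chunk_epochs` iterations at a time
#' (warm-started), the validation accuracy is scored after each chunk, and
#' training stops once `patience` chunks pass without improvement (or at
#' `max_epochs`); the best-scoring weights are kept.
#'
#' @param hidden_layers Hidden-layer sizes; exactly one hidden layer is
#'   supported (default 24 units; see the methods vignette for the sizing
#'   rationale).
#' @param max_epochs Total optimiser iteration budget.
#' @param patience Chunks without validation improvement before stopping.
#' @param chunk_epochs Optimiser iterations per early-stopping chunk.
#' @param validation_fraction Fraction of training windows carved out for the
#'   early-stopping score, in (0, 0.5).
#' @param decay L2 weight decay.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_layers = 24L, max_epochs = 200L,
                            patience = 2L, chunk_epochs = 100L,
                            validation_fraction = 0.15, decay = 1e-3) {
  if (length(hidden_layers) != 1L || hidden_layers < 1L)
    stop("exactly one hidden layer (>= 1 unit) is supported", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must be in (0, 0.5)", call. = FALSE)
  structure(list(hidden = as.integer(hidden_layers),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 chunk_epochs = as.integer(chunk_epochs),
                 validation_fraction = validation_fraction,
                 decay = decay),
            class = "classifier_spec")
}

#' Train the multilayer-perceptron posture classifier
#'
#' Columns are z-scored with statistics computed from the training rows only
#' (stored with the model and re-applied at prediction time). A stratified
#' validation split drives early stopping. Deterministic given
#' `(features, spec, seed)`.
#'
#' @param features A `semg_features` object (the training fold).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for the validation split and weight
#'   initialisation.
#' @return Object of class `semg_mlp` with the fitted network, normalisation
#'   statistics and label order.
#' @export
train_classifier <- function(features, spec = classifier_spec(), seed = 1L) {
  stopifnot(inherits(features, "semg_features"))
  x <- features$x
  labs <- features$posture
  lev <- intersect(posture_vocabulary(), unique(labs))
  if (length(lev) < 2L)
    stop("training data must contain >= 2 posture classes", call. = FALSE)
  if (nrow(x) < 10L * length(lev))
    warning("fewer than 10 windows per class; accuracy estimates will be noisy",
            call. = FALSE)
  y <- factor(labs, levels = lev)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # stratified validation split for early stopping
  val <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1L, round(spec$validation_fraction * length(ix))))))
  tr <- setdiff(seq_along(y), val)
  ytr <- nnet::class.ind(y[tr])
  nw <- (ncol(xs) + 1L) * spec$hidden + (spec$hidden + 1L) * length(lev)
  fit_chunk <- function(wts, maxit) {
    args <- list(x = xs[tr, , drop = FALSE], y = ytr, size = spec$hidden,
                 softmax = TRUE, decay = spec$decay, maxit = maxit,
                 MaxNWts = nw + 1L, trace = FALSE)
    if (!is.null(wts)) args$Wts <- wts
    do.call(nnet::nnet, args)
  }
  val_acc <- function(net) {
    p <- predict(net, xs[val, , drop = FALSE], type = "class")
    mean(p == as.character(y[val]))
  }
  best <- NULL; best_acc <- -Inf; stale <- 0L; used <- 0L; net <- NULL
  while (used < spec$max_epochs && stale <= spec$patience) {
    net <- fit_chunk(if (is.null(net)) NULL else net$wts,
                     min(spec$chunk_epochs, spec$max_epochs - used))
    used <- used + spec$chunk_epochs
    a <- val_acc(net)
    if (a > best_acc + 1e-12) {
      best_acc <- a; best <- net; stale <- 0L
    } else stale <- stale + 1L
    if (net$convergence == 0) break  # optimiser converged inside the chunk
  }
  structure(list(net = best, center = ctr, scale = scl, levels = lev,
                 spec = spec, seed = as.integer(seed),
                 validation_accuracy = best_acc, epochs_used = used),
            class = "semg_mlp")
}

#' @export
print.semg_mlp <- function(x, ...) {
  cat(sprintf("<semg_mlp> %d-%d-%d network, %d classes | val acc %.1f%%\n",
              length(x$center), x$spec$hidden, length(x$levels),
              length(x$levels), 100 * x$validation_accuracy))
  invisible(x)
}

#' Predict posture labels (or posteriors) from a fitted classifier
#'
#' @param object A `semg_mlp` model.
#' @param newdata A `semg_features` object or plain feature matrix with the
#'   training column layout.
#' @param type `"class"` for labels, `"prob"` for the posterior matrix.
#' @param ... Unused.
#' @return Character vector of labels, or an n x K posterior matrix.
#' @export
predict.semg_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "semg_features")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("newdata has ", ncol(x), " columns; the model was trained on ",
         length(object$center), call. = FALSE)
  xs <- scale(x, object$center, object$scale)
  p <- predict(object$net, xs, type = "raw")
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  object$levels[max.col(p, ties.method = "first")]
}

#' Session-rotation plan for TRNk cross-testing
#'
#' Fold f (of `n_sessions` folds) trains on the k contiguous sessions
#' starting at f (wrapping around) and tests on the remaining sessions, so
#' every session serves as test data exactly `n_sessions - k` times.
#'
#' @param k Number of training sessions (TRN level), 1..n_sessions-1.
#' @param n_sessions Total sessions recorded in the day.
#' @return List of folds, each with `train` and `test` session-id vectors.
#' @export
cross_test_plan <- function(k, n_sessions = 10L) {
  if (k < 1L || k >= n_sessions)
    stop("trn level k must be in 1..", n_sessions - 1L, call. = FALSE)
  lapply(seq_len(n_sessions), function(f) {
    train <- ((f - 1L + seq_len(k) - 1L) %% n_sessions) + 1L
    list(train = train, test = setdiff(seq_len(n_sessions), train))
  })
}

#' Row-normalised confusion matrix over the posture vocabulary
#'
#' Entry (i, j) is the percentage of true-class-i windows predicted as class
#' j; each nonempty row sums to 100. Empty true classes yield a zero row and
#' are listed in the `empty_classes` attribute.
#'
#' @param true_labels,predicted_labels Equal-length label vectors drawn from
#'   `labels`.
#' @param labels Class order; defaults to the 12-posture vocabulary.
#' @return K x K numeric matrix of percentages.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             labels = posture_vocabulary()) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(true_labels, predicted_labels)), labels)
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(true_labels, levels = labels),
                  factor(predicted_labels, levels = labels))
  m <- unclass(prop.table(counts, margin = 1L)) * 100
  empty <- rowSums(counts) == 0
  m[empty, ] <- 0
  m <- matrix(as.numeric(m), nrow(counts), dimnames = dimnames(counts))
  attr(m, "empty_classes") <- labels[empty]
  m
}

# accuracy (%) implied by a pooled count matrix
accuracy_from_counts <- function(counts) 100 * sum(diag(counts)) / sum(counts)

#' Session-wise TRNk cross-testing of the posture classifier
#'
#' Executes the ten-fold session-rotation plan at training level k: each fold
#' trains on k sessions and tests on the remaining ones. Per fold, threshold
#' calibration (Hudgins set) and feature normalisation use only that fold's
#' training sessions, so no information leaks from the test sessions.
#' Accuracies are aggregated as mean and standard deviation over folds, and
#' fold confusion counts are pooled before row normalisation.
#'
#' @param recordings List of [semg_recording()] covering exactly one day:
#'   one trial per posture per session plus one rest-calibration trial per
#'   session.
#' @param k TRN level: number of training sessions, 1..n_sessions-1.
#' @param feature_set `"hudgins"` or `"mav"`.
#' @param R Threshold multiplier applied to the training-fold rest RMS.
#' @param classifier_spec A [classifier_spec()].
#' @param window_spec A [window_spec()].
#' @param seed Integer seed; fold f trains with seed `seed + f`.
#' @param vote `"window"` scores each analysis window independently;
#'   `"trial"` aggregates window predictions per test trial by majority vote
#'   (ties broken by mean posterior).
#' @param n_sessions Sessions expected in the day.
#' @return Object of class `semg_eval`: `fold_accuracy` (%), `mean`, `sd`,
#'   row-normalised `confusion`, and metadata.
#' @export
cross_test <- function(recordings, k, feature_set = c("hudgins", "mav"),
                       R = 2, classifier_spec = semgkit::classifier_spec(),
                       window_spec = semgkit::window_spec(), seed = 1L,
                       vote = c("window", "trial"), n_sessions = 10L) {
  feature_set <- match.arg(feature_set)
  vote <- match.arg(vote)
  sess <- sort(unique(vapply(recordings, `[[`, integer(1), "session_id")))
  if (length(sess) != n_sessions)
    stop("expected exactly ", n_sessions, " sessions, found ", length(sess),
         call. = FALSE)
  days <- unique(vapply(recordings, `[[`, integer(1), "day_id"))
  if (length(days) != 1L)
    stop("cross_test operates on a single day; found days ",
         paste(days, collapse = ", "), call. = FALSE)
  plan <- cross_test_plan(k, n_sessions)
  post_recs <- Filter(function(r) r$posture != REST_CAL_LABEL, recordings)
  rest_recs <- Filter(function(r) r$posture == REST_CAL_LABEL, recordings)
  wins <- segment_dataset(post_recs, window_spec)
  win_sess <- vapply(wins, `[[`, integer(1), "session_id")
  rest_sess <- vapply(rest_recs, `[[`, integer(1), "session_id")
  labels_present <- intersect(posture_vocabulary(),
                              unique(vapply(post_recs, `[[`, character(1),
                                            "posture")))
  K <- length(labels_present)
  fold_acc <- numeric(length(plan))
  pooled <- matrix(0, K, K, dimnames = list(labels_present, labels_present))
  for (f in seq_along(plan)) {
    tr_w <- wins[win_sess %in% plan[[f]]$train]
    te_w <- wins[win_sess %in% plan[[f]]$test]
    if (feature_set == "hudgins") {
      tr_rest <- rest_recs[rest_sess %in% plan[[f]]$train]
      if (!length(tr_rest))
        stop("no rest-calibration trial in the training sessions of fold ", f,
             call. = FALSE)
      thr <- calibrate_threshold(tr_rest, R)
      cfg <- feature_config("hudgins", R = R, thresholds = thr)
    } else {
      cfg <- feature_config("mav", R = R)
    }
    ftr <- extract_features(tr_w, cfg)
    fte <- extract_features(te_w, cfg)
    mdl <- train_classifier(ftr, classifier_spec, seed = seed + f)
    if (vote == "trial") {
      trial_id <- paste(fte$session_id, fte$posture)
      prob <- predict(mdl, fte, type = "prob")
      pred_lab <- mdl$levels[max.col(prob, ties.method = "first")]
      true <- character(0); pred <- character(0)
      for (tid in unique(trial_id)) {
        ix <- trial_id == tid
        tab <- table(pred_lab[ix])
        top <- names(tab)[tab == max(tab)]
        win_lab <- if (length(top) == 1L) top else {
          mp <- colMeans(prob[ix, top, drop = FALSE])
          top[which.max(mp)]
        }
        true <- c(true, fte$posture[ix][1L]); pred <- c(pred, win_lab)
      }
    } else {
      true <- fte$posture
      pred <- predict(mdl, fte)
    }
    counts <- table(factor(true, levels = labels_present),
                    factor(pred, levels = labels_present))
    fold_acc[f] <- accuracy_from_counts(counts)
    pooled <- pooled + counts
  }
  conf <- unclass(prop.table(pooled, margin = 1L)) * 100
  conf[rowSums(pooled) == 0, ] <- 0
  structure(list(fold_accuracy = fold_acc, mean = mean(fold_acc),
                 sd = stats::sd(fold_acc), confusion = conf,
                 pooled_counts = unclass(pooled),
                 feature_set = feature_set, R = R, day = days,
                 trn_level = as.integer(k), vote = vote,
                 n_sessions = as.integer(n_sessions), seed = as.integer(seed)),
            class = "semg_eval")
}

#' @export
print.semg_eval <- function(x, ...) {
  cat(sprintf("<semg_eval> day %d TRN%d (%s, R = %g, %s vote)\n",
              x$day, x$trn_level, x$feature_set, x$R, x$vote))
  cat(sprintf("  accuracy: %.1f%% +/- %.1f%% over %d folds\n",
              x$mean, x$sd, length(x$fold_accuracy)))
  invisible(x)
}

#' Long-format accuracy summary across evaluation results
#'
#' @param results A `semg_eval` or list of them (possibly empty).
#' @return data.frame with columns day, trn_level, feature_set, vote, mean,
#'   sd — one row per result.
#' @export
accuracy_trend <- function(results) {
  if (inherits(results, "semg_eval")) results <- list(results)
  if (!length(results))
    return(data.frame(day = integer(), trn_level = integer(),
                      feature_set = character(), vote = character(),
                      mean = numeric(), sd = numeric()))
  do.call(rbind, lapply(results, function(r)
    data.frame(day = r$day, trn_level = r$trn_level,
               feature_set = r$feature_set, vote = r$vote,
               mean = r$mean, sd = r$sd)))
}
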