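#' Classification accuracy at a decision threshold
#'
#' Fraction of epochs whose thresholded probability (`p >= threshold`
#' predicts "target") matches the label.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5; `p = threshold` predicts
#'   the positive class).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stopf("cannot compute accuracy of an empty set")
  if (length(probs) != length(labels)) {
    stopf("probs and labels differ in length")
  }
  mean((probs >= threshold) == (labels == 1))
}

#' Wide-and-deep classifier factory
#'
#' Wraps the detector in the harness contract
#' `fit(epochs, labels, profiles)` / `predict_proba(fitted, epochs,
#' profiles)`, so evaluation designs can also run off-the-shelf baselines
#' implementing the same contract. The one-hot vocabulary is built from the
#' *training* profiles, so a held-out participant is automatically encoded
#' with an all-zero subject block (demographics retained).
#'
#' @param branches `c("wide", "deep")`, or one of them for the ablated
#'   detectors.
#' @param cfg An [ftrl_config()].
#' @param n_passes,batch_size,seed,deep_optimizer Passed to
#'   [fit_widedeep()].
#' @param sexes,age_groups Categorical vocabularies for the sparse features.
#' @param name Classifier label used in result tables.
#' @return A `p300_classifier` list with `fit`, `predict_proba` and `name`.
#' @export
widedeep_classifier <- function(branches = c("wide", "deep"),
                                cfg = ftrl_config(), n_passes = 3,
                                batch_size = 32, seed = 1,
                                deep_optimizer = "ftrl",
                                sexes = c("M", "F"),
                                age_groups = c("young", "mid", "old"),
                                name = paste(branches, collapse = "+")) {
  force(branches)
  structure(list(
    name = name,
    fit = function(epochs, labels, profiles) {
      ep <- epochs
      ep$labels <- as.integer(labels)
      spec <- sparse_feature_spec(names(profiles), sexes, age_groups)
      model <- widedeep_model(spec,
                              n_channels = dim(ep$epochs)[2],
                              n_samples = dim(ep$epochs)[3],
                              branches = branches, seed = seed)
      fit_widedeep(model, ep, profiles, cfg = cfg, n_passes = n_passes,
                   batch_size = batch_size, seed = seed,
                   deep_optimizer = deep_optimizer)$model
    },
    predict_proba = function(fitted, epochs, profiles) {
      predict(fitted, epochs, profiles)
    }
  ), class = "p300_classifier")
}

dataset_profiles <- function(dataset, which = seq_along(dataset)) {
  prs <- lapply(dataset[which], `[[`, "profile")
  stats::setNames(prs, vapply(prs, `[[`, "", "subject_id"))
}

result_table <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("result_table", "data.frame"))
}

#' Within-subject stratified cross-validation
#'
#' The first evaluation design: each participant's epochs are split into
#' `n_folds` stratified folds (every fold is a ~20% test set preserving the
#' target/non-target ratio); the classifier is trained on the remaining
#' folds and the per-participant accuracy is the mean over folds.
#'
#' @param dataset A `p300_dataset` from [preprocess_cohort()].
#' @param classifier A classifier factory such as [widedeep_classifier()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A `result_table` with one row per participant (`participant`,
#'   `classifier`, `accuracy`); per-fold accuracies are attached as attribute
#'   `"folds"`.
#' @export
within_subject_cv <- function(dataset, classifier = widedeep_classifier(),
                              n_folds = 5, seed = 1) {
  with_seed(seed, {
    fold_rows <- list()
    for (subj in dataset) {
      ep <- subj$epochs
      id <- subj$profile$subject_id
      n1 <- sum(ep$labels == 1)
      n0 <- sum(ep$labels == 0)
      if (min(n0, n1) < n_folds) {
        stopf("subject %s has only %d epochs of the minority class (< %d folds)",
              id, min(n0, n1), n_folds)
      }
      fold <- integer(n_epochs(ep))
      for (cl in c(0, 1)) {
        ix <- which(ep$labels == cl)
        fold[ix] <- sample(rep(seq_len(n_folds), length.out = length(ix)))
      }
      profs <- stats::setNames(list(subj$profile), id)
      for (f in seq_len(n_folds)) {
        fitted <- classifier$fit(ep[fold != f], ep$labels[fold != f], profs)
        pr <- classifier$predict_proba(fitted, ep[fold == f], profs)
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          participant = id, classifier = classifier$name, fold = f,
          accuracy = accuracy(pr, ep$labels[fold == f]))
      }
    }
    folds <- do.call(rbind, fold_rows)
    agg <- stats::aggregate(accuracy ~ participant + classifier, folds, mean)
    out <- result_table(agg[order(agg$participant), ])
    attr(out, "folds") <- folds
    out
  })
}

#' Leave-one-subject-out evaluation
#'
#' The cross-participant design: for each participant, train on all other
#' participants' epochs and test on the held-out one, whose subject id is
#' outside the training vocabulary and therefore encoded with the
#' unknown-subject convention.
#'
#' @inheritParams within_subject_cv
#' @return A `result_table` with one row per held-out participant.
#' @export
leave_one_subject_out <- function(dataset, classifier = widedeep_classifier(),
                                  seed = 1) {
  if (length(dataset) < 2) stopf("leave-one-subject-out needs >= 2 subjects")
  with_seed(seed, {
    rows <- lapply(seq_along(dataset), function(s) {
      train_idx <- setdiff(seq_along(dataset), s)
      train_ep <- combine_epoch_sets(lapply(dataset[train_idx], `[[`, "epochs"))
      train_profs <- dataset_profiles(dataset, train_idx)
      fitted <- classifier$fit(train_ep, train_ep$labels, train_profs)
      test <- dataset[[s]]
      all_profs <- c(train_profs, dataset_profiles(dataset, s))
      pr <- classifier$predict_proba(fitted, test$epochs, all_profs)
      data.frame(participant = test$profile$subject_id,
                 classifier = classifier$name,
                 accuracy = accuracy(pr, test$epochs$labels))
    })
    result_table(do.call(rbind, rows))
  })
}

#' Repeated split-half (train 4 / test 4) evaluation
#'
#' The third design: `n_repeats` times, a random half of the participants is
#' selected for training and the classifier is tested on each remaining
#' participant.
#'
#' @inheritParams within_subject_cv
#' @param n_train Number of training subjects per repeat (default 4).
#' @param n_repeats Number of random splits (default 4).
#' @return A `result_table` with one row per (repeat, test participant).
#' @export
split_half <- function(dataset, classifier = widedeep_classifier(),
                       n_train = 4, n_repeats = 4, seed = 1) {
  if (length(dataset) < 2 * n_train) {
    stopf("split-half with %d training subjects needs >= %d subjects",
          n_train, 2 * n_train)
  }
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_repeats)) {
      tr <- sort(sample(seq_along(dataset), n_train))
      te <- setdiff(seq_along(dataset), tr)
      train_ep <- combine_epoch_sets(lapply(dataset[tr], `[[`, "epochs"))
      train_profs <- dataset_profiles(dataset, tr)
      fitted <- classifier$fit(train_ep, train_ep$labels, train_profs)
      for (s in te) {
        test <- dataset[[s]]
        all_profs <- c(train_profs, dataset_profiles(dataset, s))
        pr <- classifier$predict_proba(fitted, test$epochs, all_profs)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_index = r, participant = test$profile$subject_id,
          classifier = classifier$name,
          accuracy = accuracy(pr, test$epochs$labels))
      }
    }
    result_table(do.call(rbind, rows))
  })
}

#' Online sliding-window prediction
#'
#' Emulates the online phase: every `hop_s` seconds the most recent
#' `window_s`-second buffer is causally bandpass-filtered, decimated to
#' `target_fs`, cropped to the trailing 900 ms and scored by the model. The
#' participant's sparse encoding and embedded row are computed once for the
#' whole stream.
#'
#' @param rec A [continuous_recording()] (>= `window_s` long).
#' @param model A trained [widedeep_model()].
#' @param profile The participant's [subject_profile()].
#' @param window_s,hop_s Buffer length and hop, seconds.
#' @param spec Causal [filter_spec()] for the online path.
#' @param montage Analysis montage.
#' @param target_fs Model sampling rate.
#' @return `data.frame(time_s, prob)`, one row per window end.
#' @export
online_sliding_predict <- function(rec, model, profile, window_s = 1,
                                   hop_s = 0.5,
                                   spec = filter_spec(mode = "causal"),
                                   montage = standard_montage(),
                                   target_fs = 100) {
  rec <- select_channels(rec, montage)
  fs <- rec$fs
  dur <- ncol(rec$data) / fs
  if (dur < window_s) {
    warning("stream is shorter than one window; no predictions")
    return(data.frame(time_s = numeric(0), prob = numeric(0)))
  }
  fac <- as.integer(round(fs / target_fs))
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  aa <- anti_alias_fir(fs, target_fs)
  pad <- (length(aa) - 1L) %/% 2L
  n_out <- round(0.9 * target_fs)
  times <- seq(window_s, dur, by = hop_s)
  wlen <- round(window_s * fs)
  eps <- array(0, c(length(times), length(montage), n_out))
  for (i in seq_along(times)) {
    i1 <- round(times[i] * fs)
    buf <- rec$data[, (i1 - wlen + 1):i1, drop = FALSE]
    for (c in seq_len(nrow(buf))) {
      buf[c, ] <- as.numeric(signal::filter(bf, buf[c, ]))
    }
    # baseline on the leading 100 ms, then decimate and keep trailing 900 ms
    buf <- buf - rowMeans(buf[, seq_len(round(0.1 * fs)), drop = FALSE])
    for (c in seq_len(nrow(buf))) {
      f <- stats::filter(c(buf[c, (pad + 1):2], buf[c, ],
                           buf[c, (wlen - 1):(wlen - pad)]), aa, sides = 2)
      dec <- f[pad + seq(1, wlen, by = fac)]
      eps[i, c, ] <- dec[(length(dec) - n_out + 1):length(dec)]
    }
  }
  ep <- epoch_set(eps, numeric(length(times)),
                  rep(profile$subject_id, length(times)), target_fs,
                  channel_names = montage)
  pr <- predict(model, ep, stats::setNames(list(profile), profile$subject_id))
  data.frame(time_s = times, prob = pr)
}

#' Decode the attended character from one run
#'
#' Sums the per-flash target probabilities over the run's sequences for each
#' of the 13 lines; the predicted character sits at the best row and best
#' column (ties resolved toward the lowest index).
#'
#' @param run_probs `data.frame` with columns `line_index` (0..12) and
#'   `prob`, one row per flash of the run.
#' @param cfg A [paradigm_config()].
#' @return `list(row, col)`: 1-based grid position of the decoded character.
#' @export
decode_character <- function(run_probs, cfg = paradigm_config()) {
  counts <- table(factor(run_probs$line_index, levels = 0:(cfg$n_lines - 1)))
  if (any(counts != cfg$sequences_per_run)) {
    bad <- names(counts)[counts != cfg$sequences_per_run]
    stopf("line(s) %s not covered by exactly %d sequences",
          paste(bad, collapse = ", "), cfg$sequences_per_run)
  }
  sums <- tapply(run_probs$prob, factor(run_probs$line_index, levels = 0:(cfg$n_lines - 1)), sum)
  row_scores <- sums[1:cfg$n_rows]
  col_scores <- sums[(cfg$n_rows + 1):cfg$n_lines]
  list(row = unname(which.max(row_scores)),
       col = unname(which.max(col_scores)))
}
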