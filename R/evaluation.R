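# Evaluation metrics and experiment protocols.

#' Precision, recall and accuracy from confusion counts
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts. Alternatively `tp` may
#'   be a list with fields `tp`, `tn`, `fp`, `fn`.
#' @return List with `precision` (`tp / (tp + fp)`), `recall`
#'   (`tp / (tp + fn)`), `accuracy` (`(tp + tn) / total`) and the counts.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accuracy = if (total > 0) (tp + tn) / total else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Disjoint, exhaustive fold assignment
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` index vectors partitioning `1:n`.
#' @export
make_folds <- function(n, k, seed = 1) {
  stopifnot(k >= 1, n >= k)
  with_seed(seed, {
    ord <- sample.int(n)
    split(ord, rep_len(seq_len(k), n))
  })
}

#' Experiment configuration
#'
#' Desk-scale defaults for the synthetic benchmark: a small map stack and a
#' narrow first fully connected layer keep a cohort-sized run in CPU
#' minutes; the optimizer regime (Adam, learning rate 0.001, batch 100,
#' dropout 0.5) matches [train_spec()] defaults.
#'
#' @param task `"labeling"` or `"authentication"`.
#' @param train_fraction Percentage of the gallery used for training.
#' @param n_cycles Consecutive cycles aggregated per probe decision.
#' @param folds Evaluation repetitions with re-drawn splits.
#' @param seed Experiment seed; all sampling, fold and training randomness
#'   derives from it.
#' @param feature_maps,fc1_width Architecture of the per-experiment CNN.
#' @param epochs,batch_size,learning_rate,dropout Training regime.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(task = c("labeling", "authentication"),
                              train_fraction = 100, n_cycles = 1, folds = 1,
                              seed = 1, feature_maps = c(8, 16, 16),
                              fc1_width = 128, epochs = 30, batch_size = 100,
                              learning_rate = 0.001, dropout = 0.5) {
  task <- match.arg(task)
  stopifnot(train_fraction > 0, train_fraction <= 100, n_cycles >= 1)
  structure(list(task = task, train_fraction = train_fraction,
                 n_cycles = n_cycles, folds = folds, seed = seed,
                 feature_maps = feature_maps, fc1_width = fc1_width,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, dropout = dropout),
            class = "experiment_config")
}

#' Encode a raw recording end to end
#'
#' Resamples to a uniform rate, detects gait-cycle starting positions on the
#' acceleration magnitude, and encodes one AE-GDI per detected cycle.
#'
#' @param recording An [imu_recording()].
#' @param rate Resampling rate in Hz, default 50.
#' @param Nw,Nh AE-GDI width and height.
#' @param channels `"a"` or `"aq"`.
#' @param config A [segmentation_config()].
#' @return List with `x` (AE-GDI array), `starts`, `segmentation` and
#'   `rate`.
#' @export
encode_recording <- function(recording, rate = 50, Nw = 64, Nh = 32,
                             channels = "aq",
                             config = segmentation_config()) {
  series <- resample(recording, rate)
  seg <- segment_gait(series$aM, rate, config)
  enc <- encode_cycles(series, seg$starts, Nw, Nh, channels)
  list(x = enc$x, starts = enc$starts, segmentation = seg, rate = rate)
}

# Bind per-recording AE-GDI batches into one labeled set.
bind_batches <- function(batches, subjects, sessions = NULL) {
  keep <- vapply(batches, function(b) dim(b$x)[4] > 0, logical(1))
  batches <- batches[keep]; subjects <- subjects[keep]
  if (!is.null(sessions)) sessions <- sessions[keep]
  counts <- vapply(batches, function(b) dim(b$x)[4], integer(1))
  d <- dim(batches[[1]]$x)
  x <- array(0, c(d[1], d[2], d[3], sum(counts)))
  at <- 0L
  for (i in seq_along(batches)) {
    x[, , , at + seq_len(counts[i])] <- batches[[i]]$x
    at <- at + counts[i]
  }
  list(x = x, subject = rep(subjects, counts),
       sequence = rep(seq_along(batches), counts),
       session = if (is.null(sessions)) NULL else rep(sessions, counts))
}

#' Encode a simulated cohort into labeled AE-GDI sets
#'
#' Runs the full pipeline on every recording of a [simulate_cohort()] result
#' and groups the images by session index, e.g. session 1 as gallery and
#' session 2 as probe.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param ... Passed to [encode_recording()].
#' @return A list of labeled sets, one per session, each with `x`,
#'   `subject` and `sequence` fields.
#' @export
encode_cohort <- function(cohort, ...) {
  n_sessions <- length(cohort$recordings[[1]])
  lapply(seq_len(n_sessions), function(j) {
    batches <- lapply(cohort$recordings, function(rs) {
      encode_recording(rs[[j]]$recording, ...)
    })
    bind_batches(batches, subjects = seq_along(batches))
  })
}

#' Multi-subject gait labeling
#'
#' Trains one K-way classifier on the gallery (optionally a random
#' `train_fraction` percent of it) and labels the probe set, reporting both
#' per-cycle accuracy and per-sequence accuracy, where each probe sequence
#' is decided by [aggregate_cycles()] over all its AE-GDIs.
#'
#' @param gallery,probe Labeled sets with fields `x` (AE-GDI array),
#'   `subject` (integer labels) and optionally `sequence`.
#' @param config An [experiment_config()].
#' @return List with `accuracy` (per-cycle), `accuracy_sequence`,
#'   `per_subject` accuracy table, and the fitted `model`.
#' @export
run_labeling <- function(gallery, probe, config = experiment_config()) {
  classes <- max(gallery$subject, probe$subject)
  if (length(unique(gallery$subject)) < 2) {
    stop("labeling needs at least 2 gallery subjects", call. = FALSE)
  }
  absent <- setdiff(unique(probe$subject), unique(gallery$subject))
  if (length(absent)) {
    warning("probe subjects absent from gallery excluded: ",
            paste(absent, collapse = ", "))
    keep <- !(probe$subject %in% absent)
    probe <- list(x = probe$x[, , , keep, drop = FALSE],
                  subject = probe$subject[keep],
                  sequence = probe$sequence[keep])
  }
  n <- dim(gallery$x)[4]
  idx <- seq_len(n)
  if (config$train_fraction < 100) {
    idx <- with_seed(derive_seed(config$seed, 11), {
      sort(sample.int(n, max(2L, round(n * config$train_fraction / 100))))
    })
  }
  d <- dim(gallery$x)
  spec <- cnn_spec(classes = classes, input_height = d[1], input_width = d[2],
                   channels = d[3], feature_maps = config$feature_maps,
                   fc1_width = config$fc1_width)
  model <- build_cnn(spec, seed = derive_seed(config$seed, 21))
  model <- train_cnn(model, gallery$x[, , , idx, drop = FALSE],
                     gallery$subject[idx],
                     train_spec(epochs = config$epochs,
                                batch_size = config$batch_size,
                                learning_rate = config$learning_rate,
                                dropout = config$dropout,
                                seed = derive_seed(config$seed, 31)))
  probs <- predict(model, probe$x)
  pred <- apply(probs, 1, which.max)
  acc <- mean(pred == probe$subject)
  per_subject <- tapply(pred == probe$subject, probe$subject, mean)
  seq_ids <- probe$sequence %||% probe$subject
  seq_pred <- vapply(unique(seq_ids), function(s) {
    aggregate_cycles(probs[seq_ids == s, , drop = FALSE])
  }, numeric(1))
  seq_truth <- vapply(unique(seq_ids), function(s) {
    probe$subject[seq_ids == s][1]
  }, numeric(1))
  list(accuracy = acc, accuracy_sequence = mean(seq_pred == seq_truth),
       per_subject = per_subject, predictions = pred, model = model)
}

# Split indices into consecutive runs of length n (dropping a short tail
# only when at least one full run exists).
consecutive_chunks <- function(idx, n) {
  if (length(idx) < n) return(list())
  full <- length(idx) %/% n
  lapply(seq_len(full), function(i) idx[((i - 1) * n + 1):(i * n)])
}

#' Per-subject gait authentication
#'
#' For each enrolled subject a binary classifier (genuine vs impostor) is
#' trained on `train_fraction` percent of the subject's gallery cycles plus
#' an equal number of impostor cycles drawn uniformly from the other
#' subjects, then evaluated on the probe set with `n_cycles`-wise
#' aggregation: each decision fuses that many consecutive cycles. Repeated
#' over `folds` re-drawn splits; metrics are averaged over subjects and
#' folds.
#'
#' @inheritParams run_labeling
#' @return List with mean `precision`, `recall`, `accuracy` and a
#'   `per_subject` data frame.
#' @export
run_authentication <- function(gallery, probe,
                               config = experiment_config(task = "authentication")) {
  subjects <- sort(unique(gallery$subject))
  rows <- list()
  for (fold in seq_len(config$folds)) {
    fseed <- derive_seed(config$seed, fold * 97)
    for (s in subjects) {
      pos_g <- which(gallery$subject == s)
      neg_g <- which(gallery$subject != s)
      probe_pos <- which(probe$subject == s)
      if (length(probe_pos) < config$n_cycles) {
        warning(sprintf("subject %d: fewer than %d probe cycles, skipped",
                        s, config$n_cycles))
        next
      }
      n_tr <- max(2L, round(length(pos_g) * config$train_fraction / 100))
      sel <- with_seed(derive_seed(fseed, s), {
        list(pos = sample(pos_g, min(n_tr, length(pos_g))),
             neg = sample(neg_g, min(n_tr, length(neg_g))),
             imp = sample(which(probe$subject != s),
                          min(length(probe_pos), sum(probe$subject != s))))
      })
      xtr <- gallery$x[, , , c(sel$pos, sel$neg), drop = FALSE]
      ytr <- rep(1:2, c(length(sel$pos), length(sel$neg)))
      d <- dim(gallery$x)
      spec <- cnn_spec(classes = 2, input_height = d[1], input_width = d[2],
                       channels = d[3], feature_maps = config$feature_maps,
                       fc1_width = config$fc1_width)
      model <- build_cnn(spec, seed = derive_seed(fseed, s + 7))
      model <- train_cnn(model, xtr, ytr,
                         train_spec(epochs = config$epochs,
                                    batch_size = config$batch_size,
                                    learning_rate = config$learning_rate,
                                    dropout = config$dropout,
                                    seed = derive_seed(fseed, s + 13)))
      decide <- function(idx) {
        chunks <- consecutive_chunks(idx, config$n_cycles)
        vapply(chunks, function(ch) {
          aggregate_cycles(predict(model, probe$x[, , , ch, drop = FALSE]))
        }, numeric(1))
      }
      genuine <- decide(probe_pos)
      impostor <- decide(sel$imp)
      m <- compute_metrics(tp = sum(genuine == 1), fn = sum(genuine == 2),
                           fp = sum(impostor == 1), tn = sum(impostor == 2))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, subject = s, precision = m$precision,
        recall = m$recall, accuracy = m$accuracy)
    }
  }
  per_subject <- do.call(rbind, rows)
  list(precision = mean(per_subject$precision, na.rm = TRUE),
       recall = mean(per_subject$recall, na.rm = TRUE),
       accuracy = mean(per_subject$accuracy, na.rm = TRUE),
       per_subject = per_subject)
}

#' Run a grid of experiments
#'
#' Applies `runner` to every row of `grid` (a data frame of configuration
#' overrides), recording one result row per grid point; individual failures
#' are captured as error messages and the sweep continues.
#'
#' @param grid Data frame; each row is one configuration.
#' @param runner Function taking a named list (one grid row) and returning a
#'   named list of numeric results.
#' @return Data frame binding each grid row to its results (or an `error`
#'   column).
#' @export
run_sweep <- function(grid, runner) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- as.list(grid[i, , drop = FALSE])
    res <- tryCatch(runner(cfg), error = function(e) {
      list(error = conditionMessage(e))
    })
    c(cfg, res)
  })
  nms <- unique(unlist(lapply(out, names)))
  do.call(rbind, lapply(out, function(r) {
    r <- r[nms]; names(r) <- nms
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
}
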