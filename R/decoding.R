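#' Decoding configuration
#'
#' @param test_fraction fraction of trials held out for testing (default
#'   0.33).
#' @param grid regularization values for the linear SVM grid search (default
#'   `10^(-3:3)`).
#' @param population_sizes neuron subset sizes for the sweep (default
#'   5, 10, 15, 20, 25).
#' @param n_iterations random neuron subsets per size (default 50).
#' @param window_s response window in seconds (2 for gratings, 3 for movies;
#'   `NULL` = presentation duration).
#' @param inner_folds folds of the inner cross-validation used to select the
#'   regularization value (default 3).
#' @param seed integer seed.
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(test_fraction = 0.33, grid = 10^(-3:3),
                            population_sizes = seq(5, 25, by = 5),
                            n_iterations = 50, window_s = NULL,
                            inner_folds = 3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, length(grid) >= 1)
  structure(list(test_fraction = test_fraction, grid = grid,
                 population_sizes = population_sizes,
                 n_iterations = n_iterations, window_s = window_s,
                 inner_folds = inner_folds, seed = as.integer(seed)),
            class = "decoding_config")
}

#' Trial feature matrix for decoding
#'
#' One row per presentation: each neuron's mean dF/F over
#' `[onset, onset + window)`. Presentations whose window runs past the end of
#' the recording are dropped with a warning.
#'
#' @param traces `dff_traces` (or matrix) of activity.
#' @param protocol a labeled `stim_protocol`.
#' @param window_s response window in seconds (default: presentation
#'   duration).
#' @return list with `X` (trials x neurons) and `labels` (0-based condition
#'   ids).
#' @export
build_feature_matrix <- function(traces, protocol, window_s = NULL) {
  mat <- trace_matrix(traces)
  fs <- attr(protocol, "frame_rate_hz")
  window_s <- window_s %||% (protocol$duration_frames[1] / fs)
  win <- as.integer(round(window_s * fs))
  keep <- protocol$onset_frame + win - 1L <= ncol(mat)
  if (!all(keep)) {
    warning(sum(!keep), " presentation(s) dropped: window past recording end")
  }
  pres <- protocol[keep, , drop = FALSE]
  X <- t(vapply(seq_len(nrow(pres)), function(p) {
    rowMeans(mat[, pres$onset_frame[p] + seq_len(win) - 1L, drop = FALSE])
  }, numeric(nrow(mat))))
  list(X = X, labels = pres$label)
}

#' Class-balanced train/test split of trials
#'
#' Trial counts are first equalized across classes (downsampling each class
#' to the minimum count by taking the first trials of a seeded permutation),
#' then `ceiling(test_fraction * n)` trials per class go to the test set and
#' the rest to training. Both sides are class-balanced and disjoint.
#'
#' @param labels per-trial class labels.
#' @param test_fraction held-out fraction (default 0.33).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
balanced_split <- function(labels, test_fraction = 0.33, seed = 1L) {
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 3)) stop("every class needs at least 3 trials")
  m <- min(counts)
  n_test <- ceiling(test_fraction * m)
  with_seed(seed, {
    train <- integer(0); test <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))][seq_len(m)]
      test <- c(test, idx[seq_len(n_test)])
      train <- c(train, idx[(n_test + 1L):m])
    }
    list(train = sort(train), test = sort(test))
  })
}

# Decision scores for the positive class of a binary e1071 SVM; e1071 signs
# decision values toward the first training label it saw.
svm_scores <- function(model, X) {
  dv <- attr(predict(model, X, decision.values = TRUE), "decision.values")
  if (grepl("^TRUE", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
}

fit_ovr_svm <- function(X, y, cost) {
  lapply(sort(unique(y)), function(cl) {
    yb <- factor(y == cl, levels = c(FALSE, TRUE))
    model <- NULL
    # libsvm prints iteration-cap notices (stdout and stderr) at extreme costs
    utils::capture.output(utils::capture.output(
      model <- e1071::svm(X, yb, kernel = "linear", cost = cost,
                          scale = FALSE), type = "message"))
    model
  })
}

ovr_score_matrix <- function(models, X) {
  vapply(models, function(m) svm_scores(m, X), numeric(nrow(X)))
}

#' Fit a linear SVM decoder with grid-searched regularization
#'
#' Features are standardized with training statistics, then a one-vs-rest
#' bank of linear-kernel maximum-margin classifiers is trained. The
#' regularization value is chosen from `grid` by inner cross-validated
#' multiclass accuracy (argmax of one-vs-rest decision scores); ties break
#' to the smallest value.
#'
#' @param X trials x neurons training features.
#' @param y training labels.
#' @param grid candidate regularization values (default `10^(-3:3)`).
#' @param inner_folds inner CV folds (default 3).
#' @param seed integer seed for the inner fold assignment.
#' @return A `svm_decoder`: per-class models, chosen `cost`, classes and
#'   feature scaling statistics.
#' @export
fit_decoder <- function(X, y, grid = 10^(-3:3), inner_folds = 3, seed = 1L) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  mu <- colMeans(X); s <- apply(X, 2, sd); s[s == 0] <- 1
  Xs <- scale(X, center = mu, scale = s)
  cost <- grid[1]
  if (length(grid) > 1) {
    # stratified fold ids aligned back to trial order
    fold_of <- integer(length(y))
    with_seed(seed, {
      for (cl in classes) {
        idx <- which(y == cl)
        fold_of[idx] <- sample(rep_len(seq_len(inner_folds), length(idx)))
      }
    })
    acc <- vapply(grid, function(cc) {
      hits <- 0L
      for (f in seq_len(inner_folds)) {
        tr <- fold_of != f; te <- !tr
        if (length(unique(y[tr])) < 2 || !any(te)) next
        models <- fit_ovr_svm(Xs[tr, , drop = FALSE], y[tr], cc)
        sc <- ovr_score_matrix(models, Xs[te, , drop = FALSE])
        pred <- sort(unique(y[tr]))[max.col(sc, ties.method = "first")]
        hits <- hits + sum(pred == y[te])
      }
      hits / length(y)
    }, numeric(1))
    cost <- grid[which.max(acc)]
  }
  models <- fit_ovr_svm(Xs, y, cost)
  structure(list(models = models, classes = classes, cost = cost,
                 center = mu, scale = s),
            class = "svm_decoder")
}

#' @export
print.svm_decoder <- function(x, ...) {
  cat(sprintf("<svm_decoder> linear, %d classes, cost = %g\n",
              length(x$classes), x$cost))
  invisible(x)
}

#' Macro-averaged one-vs-rest AUROC from a score table
#'
#' Per class, the binary AUROC of that class's continuous scores against all
#' other classes pooled; macro-averaged over classes. Ties in scores count
#' half, so each per-class AUROC equals the Mann-Whitney U statistic divided
#' by `n_pos * n_neg`.
#'
#' @param scores trials x classes matrix of decision scores (columns ordered
#'   as `classes`).
#' @param labels per-trial class labels.
#' @param classes class values matching the score columns (default: sorted
#'   unique labels).
#' @return scalar AUROC in \[0, 1\].
#' @export
macro_auroc <- function(scores, labels, classes = sort(unique(labels))) {
  stopifnot(ncol(scores) == length(classes))
  aucs <- vapply(seq_along(classes), function(k) {
    pos <- labels == classes[k]
    as.numeric(pROC::auc(response = pos, predictor = scores[, k],
                         levels = c(FALSE, TRUE), direction = "<",
                         quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}

#' Macro AUROC of a fitted decoder on held-out trials
#'
#' Applies the decoder's training-set feature scaling, computes one-vs-rest
#' decision scores and reduces them with [macro_auroc()].
#'
#' @param decoder a fitted `svm_decoder`.
#' @param X_test,y_test held-out features and labels; every class must be
#'   present.
#' @return scalar AUROC in \[0, 1\].
#' @export
decode_auroc <- function(decoder, X_test, y_test) {
  if (!all(decoder$classes %in% y_test)) {
    stop("every class must be present in the test set")
  }
  Xs <- scale(X_test, center = decoder$center, scale = decoder$scale)
  sc <- ovr_score_matrix(decoder$models, Xs)
  macro_auroc(sc, y_test, decoder$classes)
}

#' Run the full balanced decode once
#'
#' Balanced split, grid-searched linear SVM, macro AUROC on the held-out
#' trials; with `shuffle = TRUE` the labels are first permuted (the chance
#' control).
#'
#' @param X trials x neurons features.
#' @param labels per-trial labels.
#' @param config a [decoding_config()].
#' @param seed integer seed (split, inner CV and permutation).
#' @param shuffle permute labels before the split.
#' @return list with `auroc` and chosen `cost`.
#' @export
decode_once <- function(X, labels, config = decoding_config(), seed = 1L,
                        shuffle = FALSE) {
  if (shuffle) {
    labels <- with_seed(derive_seed(seed, 11L), sample(labels))
  }
  sp <- balanced_split(labels, config$test_fraction, seed)
  dec <- fit_decoder(X[sp$train, , drop = FALSE], labels[sp$train],
                     grid = config$grid, inner_folds = config$inner_folds,
                     seed = derive_seed(seed, 12L))
  list(auroc = decode_auroc(dec, X[sp$test, , drop = FALSE], labels[sp$test]),
       cost = dec$cost)
}

#' Shuffle-null decoding control
#'
#' @inheritParams decode_once
#' @return scalar null AUROC.
#' @export
shuffle_control <- function(X, labels, config = decoding_config(), seed = 1L) {
  decode_once(X, labels, config, seed, shuffle = TRUE)$auroc
}

#' Population-size decoding sweep with paired shuffle nulls
#'
#' For each population size, `n_iterations` random neuron subsets are drawn;
#' each subset is decoded with the full balanced pipeline and with a paired
#' label-shuffled control (same subset, same split seed).
#'
#' @param features output of [build_feature_matrix()] (or a list with `X`
#'   and `labels`).
#' @param config a [decoding_config()].
#' @return A `decoding_sweep`: data.frame `results` (size, iteration, auroc,
#'   auroc_shuffled, cost) plus a per-size `summary`.
#' @export
population_sweep <- function(features, config = decoding_config()) {
  X <- features$X; labels <- features$labels
  n_neurons <- ncol(X)
  sizes <- config$population_sizes
  drop <- sizes > n_neurons
  if (any(drop)) {
    warning("population size(s) ", paste(sizes[drop], collapse = ", "),
            " exceed available neurons; skipped")
    sizes <- sizes[!drop]
  }
  rows <- list()
  for (k in sizes) {
    for (it in seq_len(config$n_iterations)) {
      seed_it <- derive_seed(config$seed, k * 1000L + it)
      subset <- with_seed(seed_it, sample(n_neurons, k))
      Xk <- X[, subset, drop = FALSE]
      main <- decode_once(Xk, labels, config, seed_it)
      null <- shuffle_control(Xk, labels, config, seed_it)
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, iteration = it, auroc = main$auroc,
        auroc_shuffled = null, cost = main$cost)
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate(cbind(auroc, auroc_shuffled) ~ size, results, mean)
  structure(list(results = results, summary = summary, config = config),
            class = "decoding_sweep")
}

#' @export
print.decoding_sweep <- function(x, ...) {
  cat("<decoding_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA comparing decoding sweeps between groups
#'
#' Tests the main effects of experimental group and population size, and
#' their interaction, on AUROC.
#'
#' @param a,b `decoding_sweep` results (or their `results` data.frames) for
#'   the two groups.
#' @param group_names labels for the two groups.
#' @return data.frame (term, df, F, p_value).
#' @export
compare_sweeps <- function(a, b, group_names = c("A", "B")) {
  ra <- if (inherits(a, "decoding_sweep")) a$results else a
  rb <- if (inherits(b, "decoding_sweep")) b$results else b
  d <- rbind(cbind(ra, group = group_names[1]),
             cbind(rb, group = group_names[2]))
  cell <- table(d$group, d$size)
  if (any(cell < 2) || ncol(cell) < 2) {
    stop("need at least 2 observations per group x size cell and 2 sizes")
  }
  fit <- aov(auroc ~ group * factor(size), data = d)
  s <- summary(fit)[[1]]
  data.frame(term = c("group", "size", "group:size"),
             df = s[1:3, "Df"],
             F = s[1:3, "F value"],
             p_value = s[1:3, "Pr(>F)"])
}
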