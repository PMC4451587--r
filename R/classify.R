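#' Gaussian naive Bayes with wrapper feature selection
#'
#' Autonomy level and diagnosis group are predicted from the behavioral
#' profile with a Gaussian naive Bayes classifier: each class gets an
#' empirical prior and an independent Gaussian per feature; posteriors are
#' computed in log space. Model quality is measured by stratified k-fold
#' cross-validation (default k = 20), and the profile can be downsized to
#' its most relevant features by a forward best-first search scored by
#' cross-validated accuracy.
#'
#' @name classification
NULL

VARIANCE_FLOOR <- 1e-9  # relative to squared feature scale

#' Fit a Gaussian naive Bayes model
#'
#' Priors are empirical class frequencies; per class and feature the mean is
#' the sample mean and the variance the population variance (denominator
#' `n`), floored at `variance_floor * max(1, scale^2)` where `scale` is the
#' feature's pooled standard deviation — so constant features keep finite
#' likelihoods.
#'
#' @param x Numeric matrix or data.frame of features (named columns).
#' @param y Class labels (character or factor), one per row.
#' @param variance_floor Relative variance floor.
#' @return An `ecoadl_nb_model`.
#' @export
fit_naive_bayes <- function(x, y, variance_floor = VARIANCE_FLOOR) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!nrow(x)) stop("cannot fit naive Bayes on an empty table")
  if (length(y) != nrow(x)) stop("labels and rows disagree")
  if (anyNA(x)) stop("feature table contains missing values")
  y <- as.character(y)
  classes <- if (is.factor(y)) levels(y) else unique(y)
  scale2 <- pmax(1, apply(x, 2, stats::var) * (nrow(x) - 1) / nrow(x))
  scale2[is.na(scale2)] <- 1
  floor_v <- variance_floor * scale2
  stats_by <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    n <- nrow(xi)
    mu <- colMeans(xi)
    v <- colMeans(xi^2) - mu^2           # population variance
    v <- pmax(v, floor_v)
    list(prior = n / nrow(x), mean = mu, var = v, n = n)
  })
  names(stats_by) <- classes
  structure(list(classes = classes, features = colnames(x),
                 stats = stats_by, variance_floor = floor_v),
            class = "ecoadl_nb_model")
}

#' @export
print.ecoadl_nb_model <- function(x, ...) {
  cat(sprintf("<naive Bayes: %d classes (%s), %d features>\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$features)))
  invisible(x)
}

#' Predict with a Gaussian naive Bayes model
#'
#' Log-space computation: `log posterior = log prior + sum of per-feature
#' Gaussian log densities`, normalized by log-sum-exp. Ties go to the class
#' declared first at fit time.
#'
#' @param model An `ecoadl_nb_model`.
#' @param newdata Numeric matrix/data.frame with the model's feature columns
#'   (or a single named vector).
#' @return data.frame with `class` and one posterior column per class.
#' @export
predict_class <- function(model, newdata) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  missing_f <- setdiff(model$features, colnames(newdata))
  if (length(missing_f))
    stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  newdata <- newdata[, model$features, drop = FALSE]
  storage.mode(newdata) <- "double"
  bad <- which(!is.finite(newdata), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value in feature '",
         model$features[bad[1, 2]], "'")
  logp <- vapply(model$classes, function(cl) {
    s <- model$stats[[cl]]
    ll <- rep(log(s$prior), nrow(newdata))
    for (j in seq_along(model$features)) {
      ll <- ll + stats::dnorm(newdata[, j], s$mean[j], sqrt(s$var[j]),
                              log = TRUE)
    }
    ll
  }, numeric(nrow(newdata)))
  logp <- matrix(logp, nrow = nrow(newdata),
                 dimnames = list(NULL, model$classes))
  m <- apply(logp, 1, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  cls <- model$classes[apply(post, 1, which.max)]  # first max = declaration order
  out <- data.frame(class = cls, stringsAsFactors = FALSE)
  out[model$classes] <- post
  out
}

# deterministic stratified fold assignment: within each class, shuffle rows
# with the seeded RNG and deal them round-robin across folds
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  folds <- integer(n)
  rng <- new_rng(seed)
  offset <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[rng_sample(rng, length(idx))]
    f <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    folds[idx] <- f
    offset <- (offset + length(idx)) %% k  # balance fold sizes across classes
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Rows are partitioned into `k` stratified folds (seeded shuffle within
#' class, round-robin deal); each fold is predicted by a model fit on the
#' other `k - 1`. When a training split misses a class entirely, that class
#' is still predictable through a prior-only fallback (its likelihood term
#' is dropped); the condition is recorded in the report.
#'
#' @param x Feature matrix/data.frame. @param y Labels.
#' @param features Character subset of columns to use (default all).
#' @param k Number of folds (default 20). @param seed Integer seed.
#' @return An `ecoadl_cv_report`: `k`, `seed`, `accuracy`, `n_correct`,
#'   `n_incorrect`, `confusion` (true x predicted), `fold_assignments`,
#'   `notes`.
#' @export
cross_validate <- function(x, y, features = colnames(as.data.frame(x)),
                           k = 20, seed = 1) {
  x <- as.matrix(as.data.frame(x)[features])
  y <- as.character(y)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of rows")
  if (!length(features)) stop("empty feature subset")
  folds <- stratified_folds(y, k, seed)
  classes <- unique(y)
  pred <- character(n)
  notes <- character(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- folds == f
    tr_classes <- unique(y[tr])
    if (length(tr_classes) < length(classes))
      notes <- c(notes, sprintf(
        "fold %d: class(es) %s absent from training; prior-only fallback",
        f, paste(setdiff(classes, tr_classes), collapse = ",")))
    m <- fit_naive_bayes(x[tr, , drop = FALSE], y[tr])
    pred[te] <- predict_class(m, x[te, , drop = FALSE])$class
  }
  conf <- table(true = factor(y, classes), predicted = factor(pred, classes))
  n_correct <- sum(pred == y)
  structure(list(k = k, seed = seed, n = n,
                 accuracy = n_correct / n,
                 n_correct = n_correct, n_incorrect = n - n_correct,
                 confusion = conf, fold_assignments = folds,
                 features = features, notes = notes),
            class = "ecoadl_cv_report")
}

#' @export
print.ecoadl_cv_report <- function(x, ...) {
  cat(sprintf("<%d-fold CV (seed %d): accuracy %.4f (%d/%d correct)>\n",
              x$k, x$seed, x$accuracy, x$n_correct, x$n))
  invisible(x)
}

#' Forward best-first wrapper feature selection
#'
#' Searches feature subsets scored by [cross_validate()] accuracy. The open
#' list holds frontier subsets ordered by score; each expansion grows the
#' current best open node by one feature. The search stops after
#' `stall_limit` consecutive expansions without improving the best score.
#' Ties prefer the smaller subset, then lexicographic feature order.
#'
#' @inheritParams cross_validate
#' @param stall_limit Consecutive non-improving expansions tolerated.
#' @return An `ecoadl_selection`: `selected_features`, `score`,
#'   `search_trace` (data.frame of subset / score in visit order).
#' @export
select_features_best_first <- function(x, y,
                                       features = colnames(as.data.frame(x)),
                                       k = 20, seed = 1, stall_limit = 5) {
  x <- as.data.frame(x)[features]
  score_subset <- function(sub) {
    if (!length(sub)) return(max(table(y)) / length(y))  # majority rate
    cross_validate(x, y, features = sub, k = k, seed = seed)$accuracy
  }
  subset_key <- function(sub) paste0("k:", paste(sort(sub), collapse = "|"))
  visited <- new.env(parent = emptyenv())
  trace_sub <- character(0); trace_score <- numeric(0)
  base_score <- score_subset(character(0))
  assign(subset_key(character(0)), TRUE, envir = visited)
  open <- list(list(sub = character(0), score = base_score))
  best <- open[[1]]
  stall <- 0L
  better <- function(a, b) {  # is a strictly preferred over b
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$sub) != length(b$sub))
      return(length(a$sub) < length(b$sub))
    subset_key(a$sub) < subset_key(b$sub)
  }
  while (length(open) && stall < stall_limit) {
    scores <- vapply(open, `[[`, numeric(1), "score")
    pick <- which.max(scores)   # first max: earlier-inserted node wins ties
    node <- open[[pick]]
    open[[pick]] <- NULL
    improved <- FALSE
    for (f in sort(setdiff(features, node$sub))) {
      sub <- c(node$sub, f)
      key <- subset_key(sub)
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      sc <- score_subset(sub)
      trace_sub <- c(trace_sub, sub("^k:", "", key))
      trace_score <- c(trace_score, sc)
      child <- list(sub = sort(sub), score = sc)
      open[[length(open) + 1L]] <- child
      if (better(child, best)) {
        best <- child
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  structure(list(selected_features = best$sub, score = best$score,
                 baseline_score = base_score,
                 search_trace = data.frame(subset = trace_sub,
                                           score = trace_score)),
            class = "ecoadl_selection")
}

#' @export
print.ecoadl_selection <- function(x, ...) {
  cat(sprintf("<feature selection: %d features, CV accuracy %.4f>\n  %s\n",
              length(x$selected_features), x$score,
              paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' Feature sets used for the two classification tasks
#'
#' The published task-specific profiles: seven features for autonomy staging
#' and six for diagnosis-group classification.
#'
#' @param task `"autonomy"` or `"diagnosis"`.
#' @return Character vector of profile column names.
#' @export
default_feature_set <- function(task = c("autonomy", "diagnosis")) {
  task <- match.arg(task)
  if (task == "autonomy")
    c("single_task_total_duration",
      "single_task_gap_duration",
      "single_task_standard_deviation_steps",
      "dual_task_gap_duration",
      "dual_task_max_steps",
      "person_using_pharmacybasket_frequency_of_event",
      "person_using_pharmacybasket_duration_of_event")
  else
    c("age",
      "single_task_average_steps",
      "single_task_speed_average_from_centroid_information",
      "dual_task_max_steps",
      "dual_task_min_steps",
      "person_reading_inchairreadingtable_duration_of_event")
}
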