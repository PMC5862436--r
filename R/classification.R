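#' Speaker-grouped cross-validation folds
#'
#' Partitions speakers into `k` disjoint groups whose sizes differ by at
#' most one, so that all items of a speaker fall on the same side of every
#' train/test split. Deterministic given `seed`.
#'
#' @param speakers character vector of speaker ids (duplicates allowed;
#'   the distinct ids are partitioned).
#' @param k number of folds.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return list of `k` character vectors of speaker ids.
#' @export
speaker_grouped_folds <- function(speakers, k, seed = NULL) {
  ids <- unique(speakers)
  n <- length(ids)
  if (k > n) stop("k = ", k, " folds exceed the ", n, " distinct speakers")
  if (k < 2L) stop("k must be at least 2")
  perm <- with_seed(seed, sample(ids))
  folds <- split(perm, rep_len(seq_len(k), n))
  names(folds) <- NULL
  folds
}

#' Fit a regularized linear discriminant classifier
#'
#' Pooled-covariance linear discriminant analysis with class priors equal
#' to training frequencies. The pooled covariance is shrunk toward its
#' diagonal with a small fixed coefficient so that collinear or duplicated
#' feature columns (common in averaged binary profiles) remain invertible.
#' Prediction assigns the class maximizing the linear discriminant score.
#'
#' @param x numeric matrix of feature profiles (rows = items).
#' @param y class labels (coerced to factor); every class needs at least
#'   two training items.
#' @param shrinkage diagonal shrinkage coefficient in \[0, 1\].
#' @return object of class `ono_lda` with components `means`, `W` (feature
#'   x class weight matrix), `b` (class intercepts including log priors),
#'   `prior`, `levels` and `features`.
#' @export
fit_lda <- function(x, y, shrinkage = 1e-4) {
  x <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes to fit a discriminant")
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("class(es) with fewer than 2 training items: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  p <- ncol(x)
  lev <- levels(y)
  M <- t(vapply(lev, function(l) colMeans(x[y == l, , drop = FALSE]),
                numeric(p)))
  centred <- x - M[as.integer(y), , drop = FALSE]
  S <- crossprod(centred) / (nrow(x) - length(lev))
  Sreg <- (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
  diag(Sreg) <- diag(Sreg) + 1e-8          # absolute ridge for zero-variance columns
  Sinv_Mt <- solve(Sreg, t(M))             # p x C
  prior <- as.numeric(cnt) / length(y)
  b <- -0.5 * colSums(t(M) * Sinv_Mt) + log(prior)
  structure(list(means = M, W = Sinv_Mt, b = b,
                 prior = setNames(prior, lev), levels = lev,
                 features = colnames(x), shrinkage = shrinkage,
                 n = nrow(x)),
            class = "ono_lda")
}

#' @export
print.ono_lda <- function(x, ...) {
  cat(sprintf("linear discriminant fit: %d classes (%s), %d features, n=%d\n",
              length(x$levels), paste(x$levels, collapse = "/"),
              nrow(x$W), x$n))
  invisible(x)
}

#' @export
coef.ono_lda <- function(object, ...) {
  w <- object$W
  colnames(w) <- object$levels
  rownames(w) <- object$features
  w
}

#' Predict classes from a fitted linear discriminant
#'
#' @param object an [fit_lda()] result.
#' @param newdata numeric matrix with the same feature columns.
#' @param type `"class"` for hard assignments, `"score"` for the linear
#'   discriminant scores, `"posterior"` for softmax-normalized scores.
#' @param ... unused.
#' @export
predict.ono_lda <- function(object, newdata,
                            type = c("class", "score", "posterior"), ...) {
  type <- match.arg(type)
  nd <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(nd)))
    nd <- nd[, object$features, drop = FALSE]
  sc <- nd %*% object$W
  sc <- sweep(sc, 2L, -object$b)           # add intercepts
  colnames(sc) <- object$levels
  if (type == "score") return(sc)
  if (type == "posterior") {
    e <- exp(sc - apply(sc, 1L, max))
    return(e / rowSums(e))
  }
  factor(object$levels[max.col(sc, ties.method = "first")],
         levels = object$levels)
}

#' Matthews correlation coefficient of one one-vs-rest class
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' binary classification score in \[-1, 1\] (+1 perfect, 0 chance, -1
#' complete disagreement). Any zero margin makes the score 0 by
#' convention, matching the chance-level interpretation.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return numeric scalar in \[-1, 1\].
#' @export
phi_binary <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Macro-averaged Matthews coefficient of a multiclass confusion matrix
#'
#' Computes the one-vs-rest binary coefficient for every class and returns
#' their unweighted mean. For a 2-class problem the two one-vs-rest
#' coefficients coincide with the binary coefficient.
#'
#' @param cm square confusion count matrix, rows = true classes,
#'   columns = predicted classes.
#' @return numeric scalar in \[-1, 1\].
#' @export
phi_macro <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), nrow(cm) >= 2L, all(cm >= 0))
  total <- sum(cm)
  phis <- vapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    phi_binary(tp, fp, tn, fn)
  }, numeric(1))
  mean(phis)
}

# labels for a decoding target
target_labels <- function(records, target) {
  switch(target,
         movement = factor(records$movement, levels = MOVEMENTS),
         shape = factor(records$shape),
         sound = factor(records$sound),
         shape_sound = factor(paste(records$shape, records$sound, sep = "-")),
         stop("unknown decoding target '", target, "'"))
}

# encode a modality's records into an ML design matrix + labels
decode_design <- function(table, records, target, subset, policy = "strict") {
  y <- target_labels(records, target)
  if (anyNA(y)) stop("target '", target, "' undefined for some records ",
                     "(wrong modality for this target?)")
  enc <- encode_corpus(table, records, system = "ipa", subset = subset,
                       policy = policy)
  X <- as.matrix(enc[, attr(enc, "features"), drop = FALSE])
  list(X = X, y = droplevels(y), speakers = records$speaker)
}

# one grouped-CV repetition: predict every item exactly once
cv_predict_once <- function(X, y, speakers, k, shrinkage, max_retry = 20L) {
  for (try in seq_len(max_retry)) {
    folds <- speaker_grouped_folds(speakers, k)
    ok <- all(vapply(folds, function(f) {
      tr <- !(speakers %in% f)
      all(table(y[tr]) >= 2L)
    }, logical(1)))
    if (ok) break
    if (try == max_retry)
      stop("could not build folds with every class represented in training")
    if (try == 1L)
      warning("a class had too few training items in some fold; re-drawing folds")
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in folds) {
    test <- speakers %in% f
    stopifnot(!any(speakers[test] %in% speakers[!test]))  # speaker exclusivity
    fit <- fit_lda(X[!test, , drop = FALSE], y[!test], shrinkage = shrinkage)
    pred[test] <- predict(fit, X[test, , drop = FALSE])
  }
  pred
}

confusion_counts <- function(y, pred) {
  table(true = y, predicted = factor(pred, levels = levels(y)))
}

summarize_reps <- function(conf_list, phis, meta) {
  arr <- simplify2array(conf_list)              # C x C x reps, row proportions
  out <- list(
    confusion = apply(arr, c(1, 2), median),
    confusion_iqr = apply(arr, c(1, 2), function(v)
      diff(quantile(v, c(0.25, 0.75), names = FALSE))),
    phi = median(phis),
    phi_iqr = diff(quantile(phis, c(0.25, 0.75), names = FALSE)),
    phi_mean = mean(phis),
    phi_reps = phis)
  structure(c(out, list(manifest = meta)), class = "ono_decoding")
}

#' @export
print.ono_decoding <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("decoding %s [%s features] %s: phi = %.3f (IQR %.3f, %d reps)\n",
              m$target, m$subset,
              if (identical(m$train_modality, m$test_modality))
                sprintf("within %s", m$train_modality)
              else sprintf("%s -> %s", m$train_modality, m$test_modality),
              x$phi, x$phi_iqr, m$reps))
  invisible(x)
}

#' @export
summary.ono_decoding <- function(object, ...) {
  print(object)
  cat("median confusion proportions (rows = true class):\n")
  print(round(object$confusion, 3))
  invisible(object)
}

#' Within-modality decoding under speaker-grouped cross-validation
#'
#' Repeats speaker-grouped k-fold cross-validation: in each repetition new
#' folds are drawn, a discriminant is fitted on the training speakers of
#' each fold and used to predict the held-out speakers, every item being
#' predicted exactly once. Each repetition yields a row-normalized
#' confusion matrix (class-assignment proportions) and a macro-averaged
#' Matthews coefficient; repetitions are summarized by their median and
#' inter-quartile range.
#'
#' @param table a [load_feature_table()] result.
#' @param records transcription records of a single modality (or pass the
#'   full corpus plus `modality`).
#' @param target `"movement"`, `"shape"`, `"sound"` or `"shape_sound"`
#'   (the 2x2 shape-by-frequency problem decoded as 4 classes).
#' @param modality optional modality filter applied to `records`.
#' @param subset ML feature subset: `"all"` (13), `"consonant"` (8) or
#'   `"vowel"` (5).
#' @param k number of speaker folds.
#' @param reps number of cross-validation repetitions.
#' @param seed integer master seed (one sub-seed per repetition).
#' @param shrinkage covariance shrinkage passed to [fit_lda()].
#' @return object of class `ono_decoding`: median/IQR confusion matrices,
#'   `phi` (median), `phi_iqr`, `phi_mean`, per-repetition `phi_reps` and
#'   a `manifest` recording the task, seed, folds and repetitions.
#' @export
decode_within <- function(table, records, target = "movement",
                          modality = NULL, subset = "all", k = 10L,
                          reps = 1000L, seed = NULL, shrinkage = 1e-4) {
  if (!is.null(modality)) records <- records[records$modality == modality, ]
  if (nrow(records) == 0L) stop("no records to decode")
  if (length(unique(records$modality)) != 1L)
    stop("records span several modalities; pass `modality` to select one")
  des <- decode_design(table, records, target, subset)
  seeds <- derive_seeds(seed, reps)
  conf <- vector("list", reps)
  phis <- numeric(reps)
  for (r in seq_len(reps)) {
    pred <- with_seed(seeds[[r]],
      cv_predict_once(des$X, des$y, des$speakers, k, shrinkage))
    cm <- confusion_counts(des$y, pred)
    phis[r] <- phi_macro(cm)
    conf[[r]] <- prop.table(cm, 1L)
  }
  summarize_reps(conf, phis, list(
    target = target, subset = subset,
    train_modality = unique(records$modality),
    test_modality = unique(records$modality),
    k = k, reps = reps, seed = seed, shrinkage = shrinkage,
    n = nrow(records), classes = levels(des$y)))
}

#' Cross-modality decoding transfer
#'
#' In each repetition, speaker-grouped folds are drawn in the training
#' modality and the k classifiers fitted on each fold's training speakers
#' (exactly the classifiers of the within-modality analysis) each predict
#' the complete set of test-modality records. The k confusion matrices
#' and coefficients are averaged within a repetition, then summarized by
#' the median and inter-quartile range across repetitions.
#'
#' @inheritParams decode_within
#' @param train_modality,test_modality distinct modalities; the target
#'   classes must exist in both.
#' @return object of class `ono_decoding`.
#' @export
decode_cross <- function(table, records, target = "movement",
                         train_modality, test_modality, subset = "all",
                         k = 10L, reps = 1000L, seed = NULL,
                         shrinkage = 1e-4) {
  tr <- records[records$modality == train_modality, ]
  te <- records[records$modality == test_modality, ]
  if (nrow(tr) == 0L || nrow(te) == 0L)
    stop("empty training or test modality")
  dtr <- decode_design(table, tr, target, subset)
  dte <- decode_design(table, te, target, subset)
  missing_cls <- setdiff(levels(dtr$y), levels(dte$y))
  if (length(missing_cls))
    stop("target class(es) absent in test modality: ",
         paste(missing_cls, collapse = ", "))
  dte$y <- factor(dte$y, levels = levels(dtr$y))
  seeds <- derive_seeds(seed, reps)
  conf <- vector("list", reps)
  phis <- numeric(reps)
  for (r in seq_len(reps)) {
    res <- with_seed(seeds[[r]], {
      folds <- speaker_grouped_folds(dtr$speakers, k)
      cms <- lapply(folds, function(f) {
        train <- !(dtr$speakers %in% f)
        fit <- fit_lda(dtr$X[train, , drop = FALSE], dtr$y[train],
                       shrinkage = shrinkage)
        pred <- predict(fit, dte$X)
        confusion_counts(dte$y, pred)
      })
      list(cm = Reduce(`+`, lapply(cms, function(m) prop.table(m, 1L))) /
             length(cms),
           phi = mean(vapply(cms, phi_macro, numeric(1))))
    })
    conf[[r]] <- res$cm
    phis[r] <- res$phi
  }
  summarize_reps(conf, phis, list(
    target = target, subset = subset, train_modality = train_modality,
    test_modality = test_modality, k = k, reps = reps, seed = seed,
    shrinkage = shrinkage, n = nrow(te), classes = levels(dtr$y)))
}
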