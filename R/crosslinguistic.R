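#' Ingest a cross-linguistic onomatopoeia word list
#'
#' Reads a UTF-8 TSV with columns `action`, `language`, `form` and
#' tokenizes the orthographic forms as if they were IPA transcriptions
#' (policy `"skip"`: characters outside the inventory are dropped after a
#' diacritic-stripping retry). Forms losing more than half of their
#' characters, duplicate (action, language) rows (last wins) and actions
#' attested in fewer than `min_languages` languages are dropped, with
#' aggregated warnings.
#'
#' @param path TSV path, or a data frame with the same columns.
#' @param table a [load_feature_table()] result.
#' @param min_languages minimum languages per retained action.
#' @return data frame (action, language, form, phonemes) with attributes
#'   `n_dropped_forms` and `n_dropped_actions`.
#' @export
ingest_wordlist <- function(path, table, min_languages = 10L) {
  df <- if (is.data.frame(path)) path
        else read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("action", "language", "form")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("word list missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(df$action, df$language, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (action, language) row(s); last wins")
    df <- df[!duplicated(key, fromLast = TRUE), ]
  }
  toks <- lapply(df$form, function(w) {
    t <- suppressWarnings(tokenize_ipa(table, w, policy = "skip"))
    n_chars <- stringi::stri_length(stringi::stri_trans_nfc(w))
    if (length(t) == 0L || attr(t, "n_dropped") > n_chars / 2) NULL else t
  })
  keep <- !vapply(toks, is.null, logical(1))
  n_dropped_forms <- sum(!keep)
  if (n_dropped_forms)
    warning(n_dropped_forms, " form(s) dropped as untokenizable")
  df <- df[keep, ]
  toks <- toks[keep]
  cnt <- table(df$action)
  small <- names(cnt)[cnt < min_languages]
  if (length(small))
    warning(length(small), " action(s) below the ", min_languages,
            "-language floor dropped: ", paste(small, collapse = ", "))
  sel <- !(df$action %in% small)
  df <- df[sel, ]
  toks <- toks[sel]
  if (nrow(df) == 0L) stop("word list empty after filtering")
  df$phonemes <- vapply(toks, paste, character(1), collapse = " ")
  rownames(df) <- NULL
  attr(df, "n_dropped_forms") <- n_dropped_forms
  attr(df, "n_dropped_actions") <- length(small)
  df
}

#' Classify word-list forms and tabulate per-action movement distributions
#'
#' Encodes each form into the feature subset the classifier was trained
#' on, assigns it the most likely class, and returns per-action
#' proportions of languages classified into each class. A form yielding
#' an all-zero profile is assigned the prior-maximizing class and
#' counted in attribute `n_flagged`.
#'
#' @param model an [fit_lda()] result (e.g. trained on audiovisual
#'   records with the all-features subset).
#' @param words an [ingest_wordlist()] result.
#' @param table a [load_feature_table()] result.
#' @return matrix actions x classes of proportions (rows sum to 1), with
#'   per-language assignments in attribute `assignments`.
#' @export
classify_actions <- function(model, words, table) {
  stopifnot(inherits(model, "ono_lda"))
  profs <- t(vapply(strsplit(words$phonemes, " "), function(ph) {
    p <- to_profile(to_matrix(table, ph, system = "ipa"))
    unclass(p)[model$features]
  }, numeric(length(model$features))))
  colnames(profs) <- model$features
  zero <- rowSums(profs) == 0
  pred <- as.character(predict(model, profs))
  if (any(zero)) {
    pred[zero] <- model$levels[which.max(model$prior)]
    warning(sum(zero), " all-zero profile(s) classified by priors")
  }
  tab <- table(action = words$action,
               class = factor(pred, levels = model$levels))
  out <- prop.table(as.matrix(tab), 1L)
  attr(out, "assignments") <- data.frame(action = words$action,
                                         language = words$language,
                                         class = pred,
                                         stringsAsFactors = FALSE)
  attr(out, "n_flagged") <- sum(zero)
  out
}

#' Read a human rating table
#'
#' UTF-8 TSV with columns `rater`, `action` and one percentage column per
#' movement class (`hit`, `slide`, `ring`).
#'
#' @param path TSV path or equivalent data frame.
#' @return data frame.
#' @export
read_ratings <- function(path) {
  df <- if (is.data.frame(path)) path
        else read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("rater", "action", MOVEMENTS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rating table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Compare model-derived action distributions with human ratings
#'
#' Rater percentages are renormalized to proportions per rater and
#' action, averaged across raters, and correlated (Pearson) with the
#' predicted proportions over all (action, class) cells jointly. A
#' per-class breakdown and the alternative average-then-normalize order
#' are also reported. A zero-variance side yields r = 0 by convention
#' with a warning.
#'
#' @param pred a [classify_actions()] matrix.
#' @param ratings a [read_ratings()] data frame over the same actions.
#' @return list with `r`, `p`, `n_cells`, `per_class` correlations,
#'   `rating_means` and `r_average_first`.
#' @export
compare_to_ratings <- function(pred, ratings) {
  cls <- colnames(pred)
  acts <- sort(rownames(pred))
  racts <- sort(unique(ratings$action))
  if (!identical(acts, racts))
    stop("action sets differ; only in predictions: ",
         paste(setdiff(acts, racts), collapse = ", "),
         "; only in ratings: ", paste(setdiff(racts, acts), collapse = ", "))
  rm_ <- as.matrix(ratings[, cls])
  tot <- rowSums(rm_)
  if (any(tot <= 0)) stop("rater-action row(s) with non-positive total")
  norm <- rm_ / tot
  rating_means <- apply(norm, 2L, function(col)
    tapply(col, ratings$action, mean))[acts, cls]
  # alternative order: average raw percentages first, then normalize
  raw_means <- apply(rm_, 2L, function(col)
    tapply(col, ratings$action, mean))[acts, cls]
  avg_first <- raw_means / rowSums(raw_means)

  pv <- as.vector(pred[acts, cls])
  corr_or_zero <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      warning("zero-variance side in rating comparison; r = 0 by convention")
      return(list(r = 0, p = NA_real_))
    }
    ct <- cor.test(a, b)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  main <- corr_or_zero(pv, as.vector(rating_means))
  per_class <- vapply(cls, function(cl) {
    a <- pred[acts, cl]; b <- rating_means[, cl]
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }, numeric(1))
  alt <- corr_or_zero(pv, as.vector(avg_first))
  list(r = main$r, p = main$p, n_cells = length(pv), per_class = per_class,
       rating_means = rating_means, r_average_first = alt$r)
}
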