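#' Feature matrix of a phoneme sequence
#'
#' Rows are phonemes in order, columns are features: the 12 distinctive
#' features or the 14 IPA class flags.
#'
#' @param table a [load_feature_table()] result.
#' @param phonemes character vector of inventory symbols (e.g. from
#'   [tokenize_ipa()]).
#' @param system `"distinctive"` or `"ipa"`.
#' @return binary numeric matrix, one row per phoneme.
#' @export
to_matrix <- function(table, phonemes, system = c("distinctive", "ipa")) {
  system <- match.arg(system)
  stopifnot(inherits(table, "phoneme_table"))
  if (length(phonemes) == 0L) stop("cannot build a feature matrix from zero phonemes")
  canon <- vapply(phonemes, function(s) {
    r <- resolve_symbol(table, s)
    if (is.na(r)) stop("unknown symbol '", s, "' not in phoneme inventory")
    r
  }, character(1))
  src <- if (system == "distinctive") table$distinctive else table$ipa
  m <- src[canon, , drop = FALSE]
  rownames(m) <- canon
  attr(m, "system") <- system
  attr(m, "classes") <- unname(table$class[canon])
  m
}

#' Phoneme-averaged feature profile
#'
#' Collapses a feature matrix to its column means: the relative weight of
#' each feature in the word. Values lie in \[0, 1\] and, being means of
#' binaries, value times phoneme count is an integer.
#'
#' @param m a [to_matrix()] result.
#' @return a `feature_profile`: named numeric vector with attributes
#'   `system`, `subset` (`"all"`) and `n_phonemes`.
#' @export
to_profile <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  p <- colMeans(m)
  structure(p, system = attr(m, "system"), subset = "all",
            n_phonemes = nrow(m), class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  cat(sprintf("feature profile (%s system, subset=%s, %d phoneme(s)):\n",
              attr(x, "system"), attr(x, "subset"), attr(x, "n_phonemes")))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Select a machine-learning feature subset of an IPA profile
#'
#' The machine-learning feature system uses 13 of the 14 IPA flags (voiced
#' excluded): `"all"` keeps the 13, `"consonant"` keeps the 8 place and
#' manner flags, `"vowel"` keeps the 3 heights plus round and back. The
#' subset is a column selection of the all-phoneme average; a word without
#' consonants therefore yields an all-zero consonant subset rather than
#' missing values.
#'
#' @param p a `feature_profile` computed in the IPA system (or a named
#'   vector/matrix with IPA feature columns).
#' @param subset `"all"`, `"consonant"` or `"vowel"`.
#' @return the profile restricted to the selected columns.
#' @export
subset_features <- function(p, subset = c("all", "consonant", "vowel")) {
  subset <- match.arg(subset)
  sys <- attr(p, "system")
  if (!is.null(sys) && sys != "ipa")
    stop("feature subsetting is defined for the IPA system, not '", sys, "'")
  keep <- switch(subset, all = IPA_ML_ALL, consonant = IPA_ML_CONSONANT,
                 vowel = IPA_ML_VOWEL)
  if (is.matrix(p)) {
    miss <- setdiff(keep, colnames(p))
    if (length(miss)) stop("profile lacks IPA columns: ", paste(miss, collapse = ", "))
    return(p[, keep, drop = FALSE])
  }
  miss <- setdiff(keep, names(p))
  if (length(miss)) stop("profile lacks IPA columns: ", paste(miss, collapse = ", "))
  structure(unclass(p)[keep], system = "ipa", subset = subset,
            n_phonemes = attr(p, "n_phonemes"), class = "feature_profile")
}

#' Encode one transcription record into a feature profile
#'
#' Composition of [tokenize_ipa()], [to_matrix()], [to_profile()] and
#' [subset_features()]. `subset_method = "reaverage"` is the alternative
#' reading of consonant/vowel subsetting in which the mean is taken over
#' only the phonemes of the relevant class (an empty class yields zeros).
#'
#' @param table a [load_feature_table()] result.
#' @param ipa the record's IPA string.
#' @param system `"distinctive"` or `"ipa"`.
#' @param subset `"none"` for the full feature profile (12 distinctive or
#'   14 IPA flags), or an ML subset of the IPA system: `"all"` (13,
#'   voiced excluded), `"consonant"` (8) or `"vowel"` (5).
#' @param policy tokenization policy, see [tokenize_ipa()].
#' @param subset_method `"columns"` (default; column selection of the
#'   all-phoneme mean) or `"reaverage"`.
#' @return a `feature_profile`.
#' @export
encode_record <- function(table, ipa, system = c("distinctive", "ipa"),
                          subset = "none", policy = "strict",
                          subset_method = c("columns", "reaverage")) {
  system <- match.arg(system)
  subset_method <- match.arg(subset_method)
  toks <- tokenize_ipa(table, ipa, policy = policy)
  m <- to_matrix(table, toks, system = system)
  if (system == "distinctive" || subset == "none")
    return(to_profile(m))
  if (subset_method == "reaverage" && subset != "all") {
    rows <- attr(m, "classes") == subset
    keep <- switch(subset, consonant = IPA_ML_CONSONANT, vowel = IPA_ML_VOWEL)
    if (!any(rows)) {
      p <- structure(setNames(numeric(length(keep)), keep),
                     system = "ipa", subset = subset, n_phonemes = 0L,
                     class = "feature_profile")
      return(p)
    }
    sub <- m[rows, keep, drop = FALSE]
    attr(sub, "system") <- "ipa"
    p <- to_profile(sub)
    attr(p, "subset") <- subset
    return(p)
  }
  subset_features(to_profile(m), subset)
}

#' Encode a corpus of transcription records
#'
#' Batch version of [encode_record()]: returns the record metadata columns
#' followed by one column per feature.
#'
#' @param table a [load_feature_table()] result.
#' @param records a data frame with at least an `ipa` column (typically
#'   speaker, modality, movement, shape, size, sound, ipa).
#' @inheritParams encode_record
#' @return data frame of metadata plus feature columns; attribute
#'   `features` holds the feature column names.
#' @export
encode_corpus <- function(table, records, system = c("distinctive", "ipa"),
                          subset = "none", policy = "strict",
                          subset_method = "columns") {
  system <- match.arg(system)
  stopifnot(is.data.frame(records), "ipa" %in% names(records))
  profs <- lapply(records$ipa, function(w)
    unclass(encode_record(table, w, system = system, subset = subset,
                          policy = policy, subset_method = subset_method)))
  fm <- do.call(rbind, profs)
  meta <- records[, setdiff(names(records), "ipa"), drop = FALSE]
  out <- cbind(meta, ipa = records$ipa, as.data.frame(fm), row.names = NULL)
  attr(out, "features") <- colnames(fm)
  attr(out, "system") <- system
  attr(out, "subset") <- subset
  out
}
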