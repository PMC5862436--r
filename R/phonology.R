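#' Load a phoneme feature chart
#'
#' Reads a UTF-8 CSV mapping each IPA symbol to its 12 binary distinctive
#' features, together with an absorption map for chart cells holding two
#' symbols (the second member of such a pair is absorbed into the first, so
#' that every symbol maps to a unique point in feature space). IPA
#' place/manner/height class flags may be supplied as explicit `ipa_*`
#' columns; when absent they are derived from the distinctive features via
#' [derive_ipa_from_distinctive()].
#'
#' The required columns are `symbol`, `absorbed_into` (empty for canonical
#' symbols) and the 12 distinctive features in canonical order: sonorant,
#' syllabic, consonantal, continuant, nasal, high, low, back, round,
#' anterior, coronal, voiced. A symbol is a consonant exactly when its
#' `consonantal` flag is 1.
#'
#' @param path path to the chart CSV; `NULL` loads the chart shipped with
#'   the package (`feature_chart_synthetic.csv`, a reconstruction from
#'   standard distinctive-feature analyses, not any study's deposited
#'   chart).
#' @return an object of class `phoneme_table`: a list with elements
#'   `distinctive` (canonical symbols x 12 binary matrix), `ipa`
#'   (canonical symbols x 14 binary matrix), `class` (named vector,
#'   `"vowel"` or `"consonant"`), and `absorb` (named character map from
#'   absorbed symbol to canonical symbol).
#' @export
load_feature_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_chart_synthetic.csv",
                        package = "onophon", mustWork = TRUE)
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no symbols in feature chart '", path, "'")
  need <- c("symbol", DIST_FEATURES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature chart is missing required columns: ",
         paste(miss, collapse = ", "))
  if (!"absorbed_into" %in% names(df)) df$absorbed_into <- ""
  df$absorbed_into[is.na(df$absorbed_into)] <- ""
  df$symbol <- stringi::stri_trans_nfc(df$symbol)
  df$absorbed_into <- stringi::stri_trans_nfc(df$absorbed_into)

  for (f in DIST_FEATURES) {
    bad <- which(!(df[[f]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary value '%s' in feature '%s' at row %d (symbol '%s')",
                   as.character(df[[f]][bad[1]]), f, bad[1], df$symbol[bad[1]]))
  }
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup))
    stop("duplicate symbol(s) in feature chart: ", paste(unique(dup), collapse = " "))

  canon <- df[df$absorbed_into == "", , drop = FALSE]
  absd  <- df[df$absorbed_into != "", , drop = FALSE]
  unknown_target <- setdiff(absd$absorbed_into, canon$symbol)
  if (length(unknown_target))
    stop("absorption targets not in chart: ", paste(unknown_target, collapse = " "))

  m <- as.matrix(canon[, DIST_FEATURES])
  rownames(m) <- canon$symbol
  storage.mode(m) <- "double"
  key <- apply(m, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    clash <- rownames(m)[key %in% key[duplicated(key)]]
    stop("chart not injective after absorption; symbols sharing a feature vector: ",
         paste(clash, collapse = " "))
  }

  cls <- ifelse(m[, "consonantal"] == 1, "consonant", "vowel")
  if ("class" %in% names(canon)) {
    mism <- which(canon$class != cls)
    if (length(mism))
      stop("declared class disagrees with consonantal flag for: ",
           paste(canon$symbol[mism], collapse = " "))
  }

  ipa_cols <- paste0("ipa_", IPA_FEATURES)
  if (all(ipa_cols %in% names(canon))) {
    ipa <- as.matrix(canon[, ipa_cols])
    colnames(ipa) <- IPA_FEATURES
    rownames(ipa) <- canon$symbol
    storage.mode(ipa) <- "double"
  } else {
    ipa <- t(vapply(seq_len(nrow(m)), function(i)
      derive_ipa_from_distinctive(m[i, ], cls[i]), numeric(length(IPA_FEATURES))))
    rownames(ipa) <- canon$symbol
  }

  out <- list(distinctive = m, ipa = ipa, class = setNames(cls, canon$symbol),
              absorb = setNames(absd$absorbed_into, absd$symbol),
              path = path)
  class(out) <- "phoneme_table"
  out
}

#' @export
print.phoneme_table <- function(x, ...) {
  cat("phoneme feature table:", nrow(x$distinctive), "canonical symbols (",
      sum(x$class == "consonant"), "consonants,", sum(x$class == "vowel"),
      "vowels ),", length(x$absorb), "absorbed symbols\n")
  invisible(x)
}

# resolve a symbol through the absorption map; NA if unknown
resolve_symbol <- function(table, symbol) {
  if (symbol %in% rownames(table$distinctive)) return(symbol)
  if (symbol %in% names(table$absorb)) return(unname(table$absorb[symbol]))
  NA_character_
}

#' Distinctive-feature decomposition of a phoneme
#'
#' Returns the stored binary 12-vector (sonorant ... voiced) of an IPA
#' symbol, resolving absorbed symbols to their canonical partner.
#'
#' @param table a [load_feature_table()] result.
#' @param symbol a single IPA symbol.
#' @return named numeric vector of length 12 with values in \{0, 1\}.
#' @examples
#' tab <- load_feature_table()
#' decompose_phoneme(tab, "f")  # (0,0,1,1,0,0,0,0,0,1,0,0)
#' @export
decompose_phoneme <- function(table, symbol) {
  stopifnot(inherits(table, "phoneme_table"), length(symbol) == 1L)
  s <- resolve_symbol(table, stringi::stri_trans_nfc(symbol))
  if (is.na(s)) stop("unknown symbol '", symbol, "' not in phoneme inventory")
  table$distinctive[s, ]
}

#' IPA class flags of a phoneme
#'
#' Returns the 14 binary IPA class flags (consonant place: radical, dorsal,
#' coronal, labial; consonant manner: plosive, fricative, liquid, nasal;
#' voiced; vowel height: open, mid, close; vowel round and back) of an
#' inventory symbol. Consonants carry zero vowel flags and vice versa.
#'
#' @inheritParams decompose_phoneme
#' @return named numeric vector of length 14.
#' @export
ipa_flags <- function(table, symbol) {
  stopifnot(inherits(table, "phoneme_table"), length(symbol) == 1L)
  s <- resolve_symbol(table, stringi::stri_trans_nfc(symbol))
  if (is.na(s)) stop("unknown symbol '", symbol, "' not in phoneme inventory")
  table$ipa[s, ]
}

#' Phoneme class (vowel or consonant)
#'
#' @inheritParams decompose_phoneme
#' @return `"vowel"` or `"consonant"`.
#' @export
phoneme_class <- function(table, symbol) {
  s <- resolve_symbol(table, stringi::stri_trans_nfc(symbol))
  if (is.na(s)) stop("unknown symbol '", symbol, "' not in phoneme inventory")
  unname(table$class[s])
}

#' Derive IPA class flags from a distinctive-feature vector
#'
#' Applies the published wildcard patterns linking the two feature systems.
#' Among consonants: labial = anterior and not coronal; coronal place =
#' coronal; dorsal = neither, with a high or back articulation; radical =
#' none of these. Fricative = not sonorant and continuant; plosive = not
#' sonorant and not continuant; nasal manner = nasal; liquid = sonorant and
#' not nasal. Among vowels: close = high, open = low, mid = neither; round
#' and back copied. The voiced flag is copied for both classes.
#'
#' @param v a named (or canonically ordered) binary 12-vector of
#'   distinctive features.
#' @param class `"consonant"` or `"vowel"`.
#' @return named numeric vector over the 14 IPA class flags.
#' @export
derive_ipa_from_distinctive <- function(v, class = c("consonant", "vowel")) {
  class <- match.arg(class)
  if (length(v) != 12L) stop("distinctive vector must have length 12")
  if (!all(v %in% c(0, 1))) stop("distinctive vector must be binary")
  v <- setNames(as.numeric(v), DIST_FEATURES)
  out <- setNames(numeric(length(IPA_FEATURES)), IPA_FEATURES)
  out["voiced"] <- v["voiced"]
  if (class == "consonant") {
    place <- c(labial  = v["anterior"] == 1 && v["coronal"] == 0,
               coronal = unname(v["coronal"] == 1),
               dorsal  = v["anterior"] == 0 && v["coronal"] == 0 &&
                         (v["high"] == 1 || v["back"] == 1),
               radical = v["anterior"] == 0 && v["coronal"] == 0 &&
                         v["high"] == 0 && v["back"] == 0)
    manner <- c(nasal     = unname(v["nasal"] == 1),
                liquid    = v["sonorant"] == 1 && v["nasal"] == 0,
                fricative = v["sonorant"] == 0 && v["continuant"] == 1 &&
                            v["nasal"] == 0,
                plosive   = v["sonorant"] == 0 && v["continuant"] == 0 &&
                            v["nasal"] == 0)
    if (sum(place) != 1L)
      stop("inconsistent place pattern: ", sum(place), " place classes fire")
    if (sum(manner) != 1L)
      stop("inconsistent manner pattern: ", sum(manner), " manner classes fire")
    out[names(place)[place]] <- 1
    out[names(manner)[manner]] <- 1
  } else {
    height <- c(close = unname(v["high"] == 1),
                open  = unname(v["low"] == 1),
                mid   = v["high"] == 0 && v["low"] == 0)
    if (sum(height) != 1L)
      stop("inconsistent height pattern: ", sum(height), " height classes fire")
    out[names(height)[height]] <- 1
    out["round"] <- v["round"]
    out["back"]  <- v["back"]
  }
  out
}

#' Tokenize an IPA string against the inventory
#'
#' Greedy longest-match segmentation of a word into inventory phonemes.
#' Input is normalized to Unicode NFC before lookup and absorbed symbols
#' are replaced by their canonical partner. Characters outside the
#' inventory either raise an error (`policy = "strict"`) or are dropped
#' with one aggregated warning (`policy = "skip"`); under `skip`, an
#' unknown character is first decomposed (NFD) and its base character
#' retried, so that diacritics not in the inventory are stripped rather
#' than losing the carrier phoneme.
#'
#' @param table a [load_feature_table()] result.
#' @param word non-empty character scalar.
#' @param policy `"strict"` or `"skip"`.
#' @return character vector of canonical inventory symbols, in order.
#' @examples
#' tab <- load_feature_table()
#' tokenize_ipa(tab, "fuŋ")  # f u ŋ
#' @export
tokenize_ipa <- function(table, word, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "phoneme_table"))
  if (length(word) != 1L || is.na(word) || !nzchar(word))
    stop("cannot tokenize an empty string")
  w <- stringi::stri_trans_nfc(word)
  symbols <- c(rownames(table$distinctive), names(table$absorb))
  maxlen <- max(stringi::stri_length(symbols))
  chars <- stringi::stri_sub(w, seq_len(stringi::stri_length(w)),
                             length = 1L)
  n <- length(chars)
  toks <- character(0)
  dropped <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- NA_character_
    for (len in seq(min(maxlen, n - i + 1L), 1L)) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      if (!is.na(resolve_symbol(table, cand))) { hit <- cand; break }
    }
    if (!is.na(hit)) {
      toks <- c(toks, resolve_symbol(table, hit))
      i <- i + stringi::stri_length(hit)
      next
    }
    if (policy == "strict")
      stop(sprintf("cannot tokenize '%s': unknown character '%s' at position %d",
                   word, chars[i], i))
    # skip: strip diacritics and retry the base character
    base <- stringi::stri_trans_nfd(chars[i])
    base <- stringi::stri_replace_all_regex(base, "\\p{Mn}", "")
    if (nzchar(base) && !is.na(resolve_symbol(table, base))) {
      toks <- c(toks, resolve_symbol(table, base))
    } else {
      dropped <- c(dropped, chars[i])
    }
    i <- i + 1L
  }
  if (length(dropped))
    warning(sprintf("dropped %d character(s) not in inventory while tokenizing '%s': %s",
                    length(dropped), word,
                    paste(unique(dropped), collapse = " ")))
  attr(toks, "n_dropped") <- length(dropped)
  toks
}
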