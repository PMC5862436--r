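# phoneme pools used by the generator, grouped by manner and place
SYNTH_CONSONANTS <- data.frame(
  phoneme = c("p","b","t","d","k","g",
              "f","v","s","z","ʃ","ʒ","x","h",
              "l","r","ʁ","j","w",
              "m","n","ŋ"),
  manner = c(rep("plosive", 6), rep("fricative", 8), rep("liquid", 5),
             rep("nasal", 3)),
  place = c("labial","labial","coronal","coronal","dorsal","dorsal",
            "labial","labial","coronal","coronal","coronal","coronal",
            "dorsal","radical",
            "coronal","coronal","dorsal","dorsal","dorsal",
            "labial","coronal","dorsal"),
  stringsAsFactors = FALSE)

SYNTH_VOWELS <- data.frame(
  phoneme = c("i", "e", "a", "u", "o"),
  vclass = c("front", "front", "front", "back", "back"),
  stringsAsFactors = FALSE)

MOVEMENTS <- c("hit", "slide", "ring")

# planted codes: movement -> consonant manner, condition -> vowel class
manner_target <- function(movement) {
  switch(movement,
         hit   = c(plosive = 1, fricative = 0, liquid = 0, nasal = 0),
         slide = c(plosive = 0, fricative = 1, liquid = 0, nasal = 0),
         ring  = c(plosive = 0, fricative = 0, liquid = 0.5, nasal = 0.5))
}

place_target <- function(movement) {
  switch(movement,
         hit   = c(radical = 0, dorsal = 0, coronal = 0, labial = 1),
         slide = c(radical = 0, dorsal = 0, coronal = 1, labial = 0),
         ring  = c(radical = 0, dorsal = 1, coronal = 0, labial = 0))
}

vowel_target <- function(level) {
  # spiky shapes and high-frequency sounds -> front unrounded vowels;
  # rounded shapes and low-frequency sounds -> back rounded vowels
  switch(level,
         HF = , spiky   = c(front = 1, back = 0),
         LF = , rounded = c(front = 0, back = 1))
}

#' Configuration for the synthetic onomatopoeia generator
#'
#' Defines the cohort and stimulus design (fixed to 19 speakers responding
#' to 6 audio, 12 visual and 24 audiovisual stimuli by default), the
#' CV-template law governing word length, the planted effect strengths and
#' the speaker idiosyncrasy.
#'
#' Consonant manners are drawn from a distribution interpolating between
#' uniform over the consonant pool (`beta_manner = 0`) and a deterministic
#' movement code (`beta_manner = 1`: hit = plosives, slide = fricatives,
#' ring = liquids and nasals). Vowel front/back classes interpolate
#' likewise (`beta_vowel`) toward the condition code (spiky shapes and
#' high-frequency sounds = front unrounded; rounded shapes and
#' low-frequency sounds = back rounded), driven by shape in the visual
#' modality and by sound frequency in the audio and audiovisual
#' modalities. Speaker idiosyncrasy adds one normal logit offset per
#' speaker and phoneme class with scale `sigma_speaker`.
#'
#' @param n_speakers number of speakers (default 19).
#' @param beta_manner planted movement-to-manner effect strength in
#'   \[0, 1\].
#' @param beta_vowel planted shape/sound-to-vowel effect strength in
#'   \[0, 1\].
#' @param sigma_speaker standard deviation of per-speaker class logit
#'   offsets (0 = no idiosyncrasy).
#' @param templates named probability vector over CV skeletons (word
#'   lengths 2-6 phonemes).
#' @param av_coupling if `TRUE` (the default, emulating the multisensory
#'   finding), audiovisual vowels are driven by sound frequency with an
#'   additional movement bias and the shape effect is suppressed; if
#'   `FALSE`, audiovisual vowels mix the sound and shape codes with no
#'   movement bias.
#' @param av_movement_weight weight of the movement bias on audiovisual
#'   vowels when `av_coupling` is on.
#' @param v_movement_channel `"manner"` (default: the visual modality uses
#'   the same movement-to-manner code as audio) or `"place"` (the visual
#'   modality codes movement through place of articulation instead,
#'   leaving manner uninformative).
#' @param seed integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_speakers = 19L,
                         beta_manner = 0.65,
                         beta_vowel = 0.75,
                         sigma_speaker = 0.5,
                         templates = c(CV = 0.15, CVC = 0.30, CVCV = 0.25,
                                       CVCVC = 0.20, CVCVCV = 0.10),
                         av_coupling = TRUE,
                         av_movement_weight = 0.4,
                         v_movement_channel = c("manner", "place"),
                         seed = 1L) {
  v_movement_channel <- match.arg(v_movement_channel)
  if (n_speakers < 1L) stop("n_speakers must be >= 1")
  if (beta_manner < 0 || beta_manner > 1) stop("beta_manner must lie in [0, 1]")
  if (beta_vowel < 0 || beta_vowel > 1) stop("beta_vowel must lie in [0, 1]")
  if (sigma_speaker < 0) stop("sigma_speaker must be >= 0")
  if (is.null(names(templates)) || any(!nzchar(names(templates))))
    stop("templates must be a named probability vector over CV skeletons")
  if (any(templates < 0) || abs(sum(templates) - 1) > 1e-8)
    stop("template probabilities must be non-negative and sum to 1")
  bad <- grep("^[CV]+$", names(templates), invert = TRUE, value = TRUE)
  if (length(bad)) stop("invalid CV skeleton(s): ", paste(bad, collapse = " "))
  if (av_movement_weight < 0 || av_movement_weight > 1)
    stop("av_movement_weight must lie in [0, 1]")
  structure(list(n_speakers = as.integer(n_speakers),
                 beta_manner = beta_manner, beta_vowel = beta_vowel,
                 sigma_speaker = sigma_speaker, templates = templates,
                 av_coupling = av_coupling,
                 av_movement_weight = av_movement_weight,
                 v_movement_channel = v_movement_channel,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic corpus config: %d speakers x 42 stimuli ",
                     "(6 A + 12 V + 24 AV)\n  beta_manner=%.2f beta_vowel=%.2f ",
                     "sigma_speaker=%.2f av_coupling=%s v_channel=%s seed=%d\n"),
              x$n_speakers, x$beta_manner, x$beta_vowel, x$sigma_speaker,
              x$av_coupling, x$v_movement_channel, x$seed))
  invisible(x)
}

# stimulus design: one row per stimulus, per the factorial block structure
stimulus_design <- function() {
  A <- expand.grid(movement = MOVEMENTS, sound = c("HF", "LF"),
                   stringsAsFactors = FALSE)
  A <- data.frame(modality = "A", movement = A$movement, shape = NA_character_,
                  size = NA_character_, sound = A$sound)
  V <- expand.grid(movement = MOVEMENTS, shape = c("rounded", "spiky"),
                   size = c("big", "small"), stringsAsFactors = FALSE)
  V <- data.frame(modality = "V", movement = V$movement, shape = V$shape,
                  size = V$size, sound = NA_character_)
  AV <- expand.grid(movement = MOVEMENTS, shape = c("rounded", "spiky"),
                    size = c("big", "small"), sound = c("HF", "LF"),
                    stringsAsFactors = FALSE)
  AV <- data.frame(modality = "AV", movement = AV$movement, shape = AV$shape,
                   size = AV$size, sound = AV$sound)
  rbind(A, V, AV)
}

softmax_probs <- function(p, eta) {
  l <- log(p) + eta
  l <- l - max(l[is.finite(l)])
  e <- exp(l)
  e / sum(e)
}

#' Generate a synthetic onomatopoeia corpus
#'
#' Draws one word per speaker and stimulus. Words follow the configured CV
#' templates; consonants are drawn through the planted movement code and
#' vowels through the planted shape/sound code (see [synth_config()]).
#' Fully reproducible from the configuration.
#'
#' @param cfg a [synth_config()].
#' @return a list with `records` (data frame: speaker, modality, movement,
#'   shape, size, sound, ipa) and `truth` (the planted conditional class
#'   distributions and speaker offsets).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  design <- stimulus_design()
  base_manner <- table(SYNTH_CONSONANTS$manner)[c("plosive", "fricative",
                                                  "liquid", "nasal")]
  base_manner <- as.numeric(base_manner) / nrow(SYNTH_CONSONANTS)
  names(base_manner) <- c("plosive", "fricative", "liquid", "nasal")
  base_place <- table(SYNTH_CONSONANTS$place)[c("radical", "dorsal",
                                                "coronal", "labial")]
  base_place <- as.numeric(base_place) / nrow(SYNTH_CONSONANTS)
  names(base_place) <- c("radical", "dorsal", "coronal", "labial")
  base_vowel <- table(SYNTH_VOWELS$vclass)[c("front", "back")]
  base_vowel <- as.numeric(base_vowel) / nrow(SYNTH_VOWELS)
  names(base_vowel) <- c("front", "back")

  with_seed(cfg$seed, {
    spk <- sprintf("S%02d", seq_len(cfg$n_speakers))
    eta <- lapply(spk, function(s) list(
      manner = rnorm(4, 0, cfg$sigma_speaker),
      place  = rnorm(4, 0, cfg$sigma_speaker),
      vowel  = rnorm(2, 0, cfg$sigma_speaker)))
    names(eta) <- spk

    manner_dist <- function(movement)
      (1 - cfg$beta_manner) * base_manner +
        cfg$beta_manner * manner_target(movement)
    place_dist <- function(movement)
      (1 - cfg$beta_manner) * base_place +
        cfg$beta_manner * place_target(movement)
    vowel_dist <- function(modality, movement, shape, sound) {
      target <- if (modality == "V") {
        vowel_target(shape)
      } else if (modality == "A") {
        vowel_target(sound)
      } else if (cfg$av_coupling) {
        mov_bias <- switch(movement, hit = c(front = 1, back = 0),
                           ring = c(front = 0, back = 1), slide = base_vowel)
        (1 - cfg$av_movement_weight) * vowel_target(sound) +
          cfg$av_movement_weight * mov_bias
      } else {
        0.5 * vowel_target(sound) + 0.5 * vowel_target(shape)
      }
      (1 - cfg$beta_vowel) * base_vowel + cfg$beta_vowel * target
    }

    draw_consonant <- function(modality, movement, e) {
      if (modality == "V" && cfg$v_movement_channel == "place") {
        p <- softmax_probs(place_dist(movement), e$place)
        cls <- sample(names(p), 1L, prob = p)
        pool <- SYNTH_CONSONANTS$phoneme[SYNTH_CONSONANTS$place == cls]
      } else {
        p <- softmax_probs(manner_dist(movement), e$manner)
        cls <- sample(names(p), 1L, prob = p)
        pool <- SYNTH_CONSONANTS$phoneme[SYNTH_CONSONANTS$manner == cls]
      }
      pool[sample.int(length(pool), 1L)]
    }
    draw_vowel <- function(modality, movement, shape, sound, e) {
      p <- softmax_probs(vowel_dist(modality, movement, shape, sound), e$vowel)
      cls <- sample(names(p), 1L, prob = p)
      pool <- SYNTH_VOWELS$phoneme[SYNTH_VOWELS$vclass == cls]
      pool[sample.int(length(pool), 1L)]
    }

    rows <- vector("list", cfg$n_speakers * nrow(design))
    k <- 0L
    for (s in spk) {
      e <- eta[[s]]
      for (i in seq_len(nrow(design))) {
        d <- design[i, ]
        tmpl <- names(cfg$templates)[sample.int(length(cfg$templates), 1L,
                                                prob = cfg$templates)]
        slots <- strsplit(tmpl, "")[[1]]
        word <- vapply(slots, function(sl)
          if (sl == "C") draw_consonant(d$modality, d$movement, e)
          else draw_vowel(d$modality, d$movement, d$shape, d$sound, e),
          character(1))
        k <- k + 1L
        rows[[k]] <- data.frame(speaker = s, modality = d$modality,
                                movement = d$movement, shape = d$shape,
                                size = d$size, sound = d$sound,
                                ipa = paste(word, collapse = ""),
                                stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    truth <- list(
      manner = sapply(MOVEMENTS, manner_target),
      place = sapply(MOVEMENTS, place_target),
      vowel = list(HF = vowel_target("HF"), LF = vowel_target("LF"),
                   spiky = vowel_target("spiky"),
                   rounded = vowel_target("rounded")),
      base = list(manner = base_manner, place = base_place,
                  vowel = base_vowel),
      speaker_offsets = eta, config = cfg)
    list(records = records, truth = truth)
  })
}

#' Qualitative separability bounds implied by a configuration
#'
#' States what the decoding pipeline must find on a corpus generated under
#' `cfg`: a deterministic planted code with no speaker idiosyncrasy makes
#' movement linearly separable from consonant manner proportions (phi near
#' 1), a null code gives phi consistent with chance, and phi is monotone
#' in the planted effect strength between these extremes.
#'
#' @param cfg a [synth_config()].
#' @return data frame with columns `task`, `phi_lower`, `phi_upper` and
#'   `regime`.
#' @export
expected_separability <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  bound <- function(beta, sigma) {
    if (beta == 1 && sigma == 0) c(0.95, 1, "separable")
    else if (beta == 0) c(-0.1, 0.1, "null")
    else c(0, 1, "monotone_in_beta")
  }
  mv <- bound(cfg$beta_manner, cfg$sigma_speaker)
  vw <- bound(cfg$beta_vowel, cfg$sigma_speaker)
  data.frame(task = c("movement_from_consonants", "shape_sound_from_vowels"),
             phi_lower = as.numeric(c(mv[1], vw[1])),
             phi_upper = as.numeric(c(mv[2], vw[2])),
             regime = c(mv[3], vw[3]), stringsAsFactors = FALSE)
}

#' Generate a synthetic cross-linguistic word list with human-style ratings
#'
#' Emulates a cross-linguistic onomatopoeia table: each action has a true
#' movement mixture (hit/slide/ring proportions); each language contributes
#' one form whose consonants follow the planted movement-to-manner code at
#' strength `beta`. Raters report noisy percentages around the true
#' mixture.
#'
#' @param actions named list of true movement mixtures (length-3 numeric,
#'   hit/slide/ring, summing to 1); default is a small set of single- and
#'   mixed-movement actions.
#' @param n_languages languages per action.
#' @param n_raters number of raters.
#' @param beta strength of the movement-to-manner code in the generated
#'   forms.
#' @param rating_sd s.d. of the rating noise on the percentage scale.
#' @param seed integer seed.
#' @return list with `words` (action, language, form), `ratings` (rater,
#'   action, hit, slide, ring percentages) and `truth` (the mixture
#'   matrix).
#' @export
generate_wordlist <- function(actions = NULL, n_languages = 12L,
                              n_raters = 20L, beta = 0.9, rating_sd = 8,
                              seed = 1L) {
  if (is.null(actions)) {
    actions <- list(
      crash            = c(hit = 1, slide = 0, ring = 0),
      knock            = c(hit = 1, slide = 0, ring = 0),
      telephone        = c(hit = 0, slide = 0, ring = 1),
      doorbell         = c(hit = 0, slide = 0, ring = 1),
      zipper           = c(hit = 0, slide = 1, ring = 0),
      skid             = c(hit = 0.2, slide = 0.8, ring = 0),
      falling_strike   = c(hit = 0.5, slide = 0.5, ring = 0),
      wet_strike       = c(hit = 1/3, slide = 1/3, ring = 1/3))
  }
  stopifnot(all(vapply(actions, length, 1L) == 3L))
  for (a in names(actions))
    if (abs(sum(actions[[a]]) - 1) > 1e-8)
      stop("action mixture '", a, "' does not sum to 1")
  with_seed(seed, {
    base_manner <- table(SYNTH_CONSONANTS$manner)[c("plosive", "fricative",
                                                    "liquid", "nasal")]
    base_manner <- setNames(as.numeric(base_manner) / nrow(SYNTH_CONSONANTS),
                            c("plosive", "fricative", "liquid", "nasal"))
    tmpl <- c(CV = 0.15, CVC = 0.35, CVCV = 0.3, CVCVC = 0.2)
    words <- do.call(rbind, lapply(names(actions), function(a) {
      mov <- sample(MOVEMENTS, n_languages, replace = TRUE,
                    prob = actions[[a]][MOVEMENTS])
      forms <- vapply(mov, function(mv) {
        sk <- strsplit(names(tmpl)[sample.int(length(tmpl), 1L, prob = tmpl)],
                       "")[[1]]
        p <- (1 - beta) * base_manner + beta * manner_target(mv)
        paste(vapply(sk, function(sl) {
          if (sl == "C") {
            cls <- sample(names(p), 1L, prob = p)
            pool <- SYNTH_CONSONANTS$phoneme[SYNTH_CONSONANTS$manner == cls]
            pool[sample.int(length(pool), 1L)]
          } else {
            SYNTH_VOWELS$phoneme[sample.int(nrow(SYNTH_VOWELS), 1L)]
          }
        }, character(1)), collapse = "")
      }, character(1))
      data.frame(action = a, language = sprintf("L%02d", seq_len(n_languages)),
                 form = forms, stringsAsFactors = FALSE)
    }))
    truth <- t(vapply(actions, function(x) x[MOVEMENTS], numeric(3)))
    colnames(truth) <- MOVEMENTS
    ratings <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      m <- pmax(truth * 100 + matrix(rnorm(length(truth), 0, rating_sd),
                                     nrow(truth)), 0)
      data.frame(rater = sprintf("R%02d", r), action = rownames(truth),
                 hit = m[, "hit"], slide = m[, "slide"], ring = m[, "ring"],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    list(words = words, ratings = ratings, truth = truth)
  })
}
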