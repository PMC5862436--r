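#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (here, the number of phonological
#'   dimensions screened).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.01, 26)          # 3.846e-4
#' signif(bonferroni_threshold(0.01, 26), 2)  # displayed as 0.00038
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (length(m) != 1L || m < 1) stop("m must be a positive count")
  alpha / m
}

# factors analysed per modality
MODALITY_FACTORS <- list(A = c("movement", "sound"),
                         V = c("movement", "shape"),
                         AV = c("movement", "sound", "shape"))

# encode records in one or both feature systems; returns list of
# (system, feature matrix) pairs sharing the records' metadata rows
encode_systems <- function(table, records, system) {
  systems <- switch(system, both = c("distinctive", "ipa"), system)
  lapply(setNames(systems, systems), function(sys) {
    enc <- encode_corpus(table, records, system = sys)
    list(data = enc, features = attr(enc, "features"))
  })
}

# repeated-measures p-value: one-way ANOVA on per-speaker condition means
# with subjects as the error stratum
rm_anova_p <- function(value, level, speaker) {
  cell <- aggregate(value, list(speaker = speaker, level = level), mean)
  cell$level <- factor(cell$level)
  cell$speaker <- factor(cell$speaker)
  if (sd(cell$x) == 0) return(c(F = NA_real_, p = NA_real_))
  fit <- aov(x ~ level + Error(speaker), data = cell)
  tab <- summary(fit)[["Error: Within"]][[1]]
  i <- which(trimws(rownames(tab)) == "level")
  c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
}

mixed_anova_p <- function(value, level, speaker) {
  if (!requireNamespace("lmerTest", quietly = TRUE))
    stop("method = 'mixed' requires the lmerTest package")
  d <- data.frame(value = value, level = factor(level),
                  speaker = factor(speaker))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ level + (1 | speaker), data = d)))
  a <- suppressWarnings(stats::anova(fit))
  c(F = a["level", "F value"], p = a["level", "Pr(>F)"])
}

#' Per-feature ANOVA screening of a corpus
#'
#' Runs one ANOVA per phonological feature, factor and modality, with
#' subjects as random factor: by default a repeated-measures analysis on
#' per-speaker condition means (`method = "rm"`), alternatively a mixed
#' model with random speaker intercepts on per-trial profiles
#' (`method = "mixed"`, requires lmerTest). Factors per modality: A uses
#' movement and sound, V movement and shape, AV movement, sound and
#' shape. P-values are compared against the Bonferroni threshold
#' `alpha / m` where `m` counts the features screened jointly across
#' systems (26 when both the 12 distinctive and 14 IPA features are
#' used).
#'
#' @param table a [load_feature_table()] result.
#' @param records transcription records (all modalities).
#' @param system `"both"` (default), `"distinctive"` or `"ipa"`.
#' @param alpha family-wise level before correction.
#' @param method `"rm"` or `"mixed"`.
#' @return data frame of class `anova_screen` with columns modality,
#'   system, feature, factor, F, p, significant; attributes `threshold`
#'   and `m`.
#' @export
run_anova_screen <- function(table, records, system = c("both", "distinctive",
                                                        "ipa"),
                             alpha = 0.01, method = c("rm", "mixed")) {
  system <- match.arg(system)
  method <- match.arg(method)
  if (length(unique(records$speaker)) < 2L)
    stop("ANOVA screening needs at least 2 speakers")
  encs <- encode_systems(table, records, system)
  m <- sum(vapply(encs, function(e) length(e$features), 1L))
  thr <- bonferroni_threshold(alpha, m)
  pfun <- if (method == "rm") rm_anova_p else mixed_anova_p

  rows <- list()
  for (mod in intersect(names(MODALITY_FACTORS), unique(records$modality))) {
    idx <- records$modality == mod
    for (fac in MODALITY_FACTORS[[mod]]) {
      lev <- records[[fac]][idx]
      if (length(unique(lev[!is.na(lev)])) < 2L)
        stop("factor '", fac, "' is constant within modality ", mod)
      for (sys in names(encs)) {
        enc <- encs[[sys]]$data[idx, ]
        for (f in encs[[sys]]$features) {
          st <- pfun(enc[[f]], lev, enc$speaker)
          rows[[length(rows) + 1L]] <- data.frame(
            modality = mod, system = sys, feature = f, factor = fac,
            F = unname(st["F"]), p = unname(st["p"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("anova_screen", "data.frame")
  out
}

#' @export
print.anova_screen <- function(x, ...) {
  cat(sprintf("per-feature ANOVA screen: %d tests, threshold p < %.2g (= %.2g/%d), %d significant\n",
              nrow(x), attr(x, "threshold"), attr(x, "alpha"), attr(x, "m"),
              sum(x$significant, na.rm = TRUE)))
  NextMethod()
}

#' Deviation patterns of condition-level profiles
#'
#' For one modality and one stimulus factor, computes the per-speaker
#' condition-level mean profiles in the IPA system, averages them into
#' condition-level means, and labels each (level, feature) cell `"+"` /
#' `"-"` / `"0"` according to whether the level mean lies more than
#' `k_sd` standard deviations above / below the modality-wide mean of
#' that feature.
#'
#' The standardizing unit is selectable. The default, `"sem"`, divides
#' the deviation by the standard error of the level mean across speakers
#' (the uncertainty of the plotted cell), under which a strong planted
#' effect exceeds 3 s.d. comfortably. `"speaker"` divides by the s.d.
#' over all per-speaker condition-level means in the modality and
#' `"trial"` by the s.d. over raw per-record profiles; both of these
#' bound |z| near sqrt(2) on a 3-level factor however strong the effect,
#' so they suit small `k_sd` only. A zero-s.d. feature is labelled `"0"`
#' with a warning; `k_sd = 0` degenerates to sign-of-deviation labels.
#'
#' @param table a [load_feature_table()] result.
#' @param records transcription records.
#' @param modality modality to analyse.
#' @param factor_name grouping factor (`"movement"`, `"shape"`, `"sound"`).
#' @param k_sd deviation threshold in s.d. units.
#' @param unit `"sem"`, `"speaker"` or `"trial"`.
#' @return character matrix levels x IPA features of labels, with the
#'   underlying z-scores in attribute `z`.
#' @export
deviation_patterns <- function(table, records, modality, factor_name,
                               k_sd = 3, unit = c("sem", "speaker", "trial")) {
  unit <- match.arg(unit)
  idx <- records$modality == modality
  if (!any(idx)) stop("no records in modality ", modality)
  recs <- records[idx, ]
  lev <- recs[[factor_name]]
  if (anyNA(lev)) stop("factor '", factor_name, "' undefined in modality ",
                       modality)
  enc <- encode_corpus(table, recs, system = "ipa")
  feats <- attr(enc, "features")
  base <- if (unit == "trial") {
    cbind(data.frame(level = lev), enc[, feats])
  } else {
    aggregate(enc[, feats], list(speaker = enc$speaker, level = lev), mean)
  }
  mu <- colMeans(base[, feats, drop = FALSE])
  levmeans <- aggregate(base[, feats, drop = FALSE],
                        list(level = base$level), mean)
  dev <- sweep(as.matrix(levmeans[, feats]), 2L, mu)
  rownames(dev) <- levmeans$level
  if (unit == "sem") {
    # per-level standard error of the mean across speakers
    sc <- t(vapply(levmeans$level, function(l) {
      b <- base[base$level == l, feats, drop = FALSE]
      vapply(b, sd, numeric(1)) / sqrt(nrow(b))
    }, numeric(length(feats))))
  } else {
    sc <- matrix(vapply(base[, feats, drop = FALSE], sd, numeric(1)),
                 nrow(dev), length(feats), byrow = TRUE)
  }
  zero <- sc == 0
  if (any(zero)) {
    warning("zero-s.d. cell(s) labelled 0 for feature(s): ",
            paste(unique(feats[colSums(zero) > 0]), collapse = ", "))
    sc[zero] <- Inf
  }
  z <- dev / sc
  lab <- matrix("0", nrow(z), ncol(z), dimnames = dimnames(z))
  lab[z > k_sd] <- "+"
  lab[z < -k_sd] <- "-"
  attr(lab, "z") <- z
  attr(lab, "k_sd") <- k_sd
  attr(lab, "unit") <- unit
  lab
}

#' Pairwise correlations between phonological features
#'
#' Pearson correlations between the feature columns of the encoded
#' per-record profiles, with pairwise p-values. In the combined system
#' the 12 distinctive features are prefixed `d_` and the 14 IPA features
#' `i_`. Constant columns yield `NA` correlations with a warning.
#'
#' @param table a [load_feature_table()] result.
#' @param records transcription records (at least 3).
#' @param system `"both"`, `"distinctive"` or `"ipa"`.
#' @return list with symmetric unit-diagonal matrix `r`, p-value matrix
#'   `p` and `n`.
#' @export
feature_correlations <- function(table, records,
                                 system = c("both", "distinctive", "ipa")) {
  system <- match.arg(system)
  if (nrow(records) < 3L) stop("need at least 3 records")
  encs <- encode_systems(table, records, system)
  mats <- lapply(names(encs), function(sys) {
    m <- as.matrix(encs[[sys]]$data[, encs[[sys]]$features, drop = FALSE])
    if (length(encs) > 1L)
      colnames(m) <- paste0(substr(sys, 1, 1), "_", colnames(m))
    m
  })
  X <- do.call(cbind, mats)
  const <- apply(X, 2L, sd) == 0
  if (any(const))
    warning("constant feature column(s), correlations undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  p <- ncol(X)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  pv <- r
  diag(r) <- 1
  diag(pv) <- 0
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(cor.test(X[, i], X[, j]))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(r = r, p = pv, n = nrow(X))
}
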