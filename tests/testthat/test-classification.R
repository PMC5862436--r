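test_that("speaker folds partition speakers with near-equal sizes", {
  spk <- sprintf("S%02d", 1:19)
  folds <- speaker_grouped_folds(spk, 10, seed = 1)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), spk)
  expect_equal(sum(lengths(folds)), 19)          # each speaker exactly once
  expect_setequal(unique(lengths(folds)), c(1, 2))
  expect_equal(sort(table(lengths(folds)), decreasing = TRUE),
               sort(c(`2` = 9, `1` = 1), decreasing = TRUE),
               ignore_attr = TRUE)
  # leave-one-speaker-out and determinism
  loso <- speaker_grouped_folds(spk, 19, seed = 2)
  expect_true(all(lengths(loso) == 1))
  expect_identical(speaker_grouped_folds(spk, 10, seed = 7),
                   speaker_grouped_folds(spk, 10, seed = 7))
  expect_error(speaker_grouped_folds(spk, 20), "exceed")
})

test_that("the regularized discriminant separates well-separated clouds", {
  cl <- make_clouds()
  fit <- fit_lda(cl$x, cl$y)
  expect_s3_class(fit, "ono_lda")
  expect_equal(as.character(predict(fit, cl$x)), as.character(cl$y))
  expect_equal(dim(coef(fit)), c(4, 2))
  post <- predict(fit, cl$x, type = "posterior")
  expect_equal(rowSums(post), rep(1, nrow(cl$x)), ignore_attr = TRUE)
  expect_error(fit_lda(cl$x, rep("a", nrow(cl$x))), "2 classes")
  expect_error(fit_lda(cl$x[1:3, ], factor(c("a", "a", "b"))), "fewer than 2")
})

test_that("duplicated feature columns survive via shrinkage", {
  cl <- make_clouds()
  xdup <- cbind(cl$x, f_dup = cl$x[, 1], f_const = 0)
  fit <- fit_lda(xdup, cl$y)
  expect_equal(as.character(predict(fit, xdup)), as.character(cl$y))
})

test_that("predictions agree with the classical discriminant on well-conditioned data", {
  skip_if_not_installed("MASS")
  cl <- make_clouds(n = 60, p = 3, sep = 2, seed = 9)
  ours <- predict(fit_lda(cl$x, cl$y, shrinkage = 0), cl$x)
  ref <- predict(MASS::lda(cl$x, cl$y), cl$x)$class
  expect_gt(mean(as.character(ours) == as.character(ref)), 0.99)
})

test_that("shuffled labels yield chance-level test accuracy", {
  set.seed(13)
  x <- matrix(rnorm(400 * 5), 400)
  colnames(x) <- paste0("f", 1:5)
  y <- factor(sample(rep(c("a", "b"), each = 200)))
  fit <- fit_lda(x[1:300, ], y[1:300])
  acc <- mean(predict(fit, x[301:400, ]) == y[301:400])
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("the binary Matthews coefficient matches its closed form", {
  expect_equal(phi_binary(5, 0, 5, 0), 1)
  expect_equal(phi_binary(0, 5, 0, 5), -1)
  expect_equal(phi_binary(6, 2, 3, 1), 16 / sqrt(8 * 7 * 5 * 4))
  expect_equal(phi_binary(0, 0, 0, 0), 0)   # degenerate margins
  expect_equal(phi_binary(3, 0, 0, 0), 0)
  # independent oracle: phi of a 2x2 table is the Pearson correlation of
  # the underlying binary label vectors
  set.seed(101)
  for (i in 1:200) {
    cm <- matrix(rpois(4, 6) + 1, 2)
    truth <- rep(c(1, 1, 0, 0), c(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2]))
    pred <- rep(c(1, 0, 1, 0), c(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2]))
    expect_equal(phi_binary(cm[1, 1], cm[2, 1], cm[2, 2], cm[1, 2]),
                 cor(truth, pred), tolerance = 1e-12)
  }
})

test_that("macro averaging reduces to the binary coefficient for 2 classes", {
  set.seed(7)
  for (i in 1:100) {
    cm <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(phi_macro(cm),
                 phi_binary(cm[1, 1], cm[2, 1], cm[2, 2], cm[1, 2]),
                 tolerance = 1e-12)
  }
  # three classes with per-class phi (1, 0, -1) average to 0
  phis <- c(phi_binary(5, 0, 10, 0), phi_binary(0, 0, 0, 0),
            phi_binary(0, 5, 0, 10))
  expect_equal(mean(phis), 0)
})

test_that("macro phi of uniformly random predictions concentrates near 0", {
  set.seed(23)
  y <- factor(sample(c("a", "b", "c"), 1e4, replace = TRUE))
  pred <- factor(sample(c("a", "b", "c"), 1e4, replace = TRUE))
  expect_lt(abs(phi_macro(table(y, pred))), 0.05)
})

test_that("within-modality decoding recovers a separable planted code", {
  corp <- generate_corpus(synth_config(beta_manner = 1, sigma_speaker = 0,
                                       seed = 31L))
  res <- decode_within(ono_table, corp$records, "movement", modality = "AV",
                       subset = "consonant", reps = 10, seed = 5)
  expect_s3_class(res, "ono_decoding")
  expect_gte(res$phi, 0.95)
  # single-repetition confusion rows are proportions
  r1 <- decode_within(ono_table, corp$records, "movement", modality = "A",
                      subset = "consonant", reps = 1, seed = 5)
  expect_equal(rowSums(r1$confusion), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(r1$phi_iqr, 0)
})

test_that("a null corpus decodes inside the permutation band", {
  corp <- generate_corpus(synth_config(beta_manner = 0, beta_vowel = 0,
                                       seed = 32L))
  rec <- corp$records[corp$records$modality == "AV", ]
  res <- decode_within(ono_table, rec, "movement", subset = "consonant",
                       reps = 10, seed = 6)
  # permutation null of macro phi at this n
  enc <- encode_corpus(ono_table, rec, system = "ipa", subset = "consonant")
  X <- as.matrix(enc[, attr(enc, "features")])
  set.seed(60)
  null <- replicate(100, {
    sh <- rec
    sh$movement <- sample(sh$movement)
    d <- decode_within(ono_table, sh, "movement", subset = "consonant",
                       reps = 1)
    d$phi
  })
  band <- quantile(null, c(0.025, 0.975))
  expect_gte(res$phi, band[[1]])
  expect_lte(res$phi, band[[2]])
})

test_that("decoding is deterministic given a seed and logs its manifest", {
  corp <- small_corpus(seed = 33L)
  a <- decode_within(ono_table, corp$records, "movement", modality = "A",
                     subset = "all", reps = 5, seed = 77)
  b <- decode_within(ono_table, corp$records, "movement", modality = "A",
                     subset = "all", reps = 5, seed = 77)
  expect_identical(a$phi_reps, b$phi_reps)
  expect_identical(a$confusion, b$confusion)
  expect_equal(a$manifest$reps, 5)
  expect_equal(a$manifest$seed, 77)
  expect_equal(a$manifest$subset, "all")
  expect_equal(sort(a$manifest$classes), sort(unique(corp$records$movement)))
})

test_that("cross-modality transfer mirrors a planted code asymmetry", {
  # audio and audiovisual share the movement-to-manner code; the visual
  # modality codes movement through place instead
  corp <- generate_corpus(synth_config(beta_manner = 0.9, sigma_speaker = 0.3,
                                       v_movement_channel = "place",
                                       seed = 34L))
  good <- decode_cross(ono_table, corp$records, "movement", "A", "AV",
                       subset = "consonant", reps = 10, seed = 8)
  poor <- decode_cross(ono_table, corp$records, "movement", "A", "V",
                       subset = "consonant", reps = 10, seed = 8)
  expect_gt(good$phi, 0.8)
  # transfer to V is degraded but not nil: place and manner stay correlated
  # through the phoneme inventory, so an "unrelated" code cannot reach 0
  expect_lt(poor$phi, 0.55)
  expect_gt(good$phi, poor$phi + 0.3)
  # within-V decoding still works through place features
  vv <- decode_within(ono_table, corp$records, "movement", modality = "V",
                      subset = "consonant", reps = 10, seed = 8)
  expect_gt(vv$phi, 0.8)
  # deterministic given seed
  again <- decode_cross(ono_table, corp$records, "movement", "A", "V",
                        subset = "consonant", reps = 10, seed = 8)
  expect_identical(poor$phi_reps, again$phi_reps)
})

test_that("cross-modality decoding validates its class structure", {
  corp <- small_corpus(seed = 35L)
  expect_error(decode_cross(ono_table, corp$records, "sound", "A", "V",
                            reps = 2, seed = 1))
  expect_error(decode_within(ono_table, corp$records, "movement",
                             reps = 2), "several modalities")
})
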