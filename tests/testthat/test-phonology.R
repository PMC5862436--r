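test_that("chart loads and stores the published /f/ decomposition", {
  expect_s3_class(ono_table, "phoneme_table")
  f <- decompose_phoneme(ono_table, "f")
  expect_identical(names(f), c("sonorant", "syllabic", "consonantal",
                               "continuant", "nasal", "high", "low", "back",
                               "round", "anterior", "coronal", "voiced"))
  expect_equal(unname(f), c(0, 0, 1, 1, 0, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(paste(f, collapse = ""), "001100000100")
  # determinism: identical on repeated lookup
  expect_identical(f, decompose_phoneme(ono_table, "f"))
})

test_that("cardinal vowel /u/ carries the expected features in both systems", {
  u <- decompose_phoneme(ono_table, "u")
  expect_equal(unname(u[c("consonantal", "syllabic", "high", "back", "round")]),
               c(0, 1, 1, 1, 1))
  fl <- ipa_flags(ono_table, "u")
  expect_equal(unname(fl[c("close", "back", "round")]), c(1, 1, 1))
  expect_true(all(fl[c("radical", "dorsal", "coronal", "labial",
                       "plosive", "fricative", "liquid", "nasal")] == 0))
})

test_that("/f/ is a labial fricative non-voiced consonant in IPA flags", {
  fl <- ipa_flags(ono_table, "f")
  expect_equal(unname(fl[c("labial", "fricative", "voiced")]), c(1, 1, 0))
  expect_true(all(fl[c("open", "mid", "close", "round", "back")] == 0))
})

test_that("every inventory symbol is exactly one of vowel/consonant and flags are exclusive", {
  syms <- rownames(ono_table$distinctive)
  cls <- vapply(syms, phoneme_class, character(1), table = ono_table)
  expect_true(all(cls %in% c("vowel", "consonant")))
  expect_equal(sum(cls == "vowel") + sum(cls == "consonant"), length(syms))
  for (s in syms) {
    fl <- ipa_flags(ono_table, s)
    cons_flags <- sum(fl[c("radical", "dorsal", "coronal", "labial",
                           "plosive", "fricative", "liquid", "nasal")])
    vow_flags <- sum(fl[c("open", "mid", "close", "round", "back")])
    if (cls[s] == "consonant") {
      expect_equal(cons_flags, 2)  # one place + one manner
      expect_equal(vow_flags, 0)
    } else {
      expect_equal(cons_flags, 0)
      expect_equal(sum(fl[c("open", "mid", "close")]), 1)  # one height
    }
  }
})

test_that("distinctive-to-IPA derivation matches the stored chart for every symbol", {
  syms <- rownames(ono_table$distinctive)
  for (s in syms) {
    derived <- derive_ipa_from_distinctive(ono_table$distinctive[s, ],
                                           unname(ono_table$class[s]))
    expect_equal(derived, ipa_flags(ono_table, s), info = s)
  }
})

test_that("derivation applies the published wildcard patterns and rejects nonsense", {
  f <- derive_ipa_from_distinctive(c(0,0,1,1,0,0,0,0,0,1,0,0), "consonant")
  expect_equal(unname(f[c("labial", "fricative", "voiced")]), c(1, 1, 0))
  # all-zero vowel: mid height, no consonant flag
  z <- derive_ipa_from_distinctive(rep(0, 12), "vowel")
  expect_equal(unname(z["mid"]), 1)
  expect_true(all(z[c("radical", "dorsal", "coronal", "labial",
                      "plosive", "fricative", "liquid", "nasal")] == 0))
  # high + low simultaneously -> two heights fire
  v <- rep(0, 12); v[6] <- 1; v[7] <- 1
  expect_error(derive_ipa_from_distinctive(v, "vowel"), "height")
  expect_error(derive_ipa_from_distinctive(rep(0, 11), "consonant"), "length 12")
  expect_error(derive_ipa_from_distinctive(c(rep(0, 11), 2), "vowel"), "binary")
})

test_that("tokenization segments fuŋ and honours strict/skip policies", {
  expect_identical(as.character(tokenize_ipa(ono_table, "fuŋ")),
                   c("f", "u", "ŋ"))
  expect_error(tokenize_ipa(ono_table, ""), "empty")
  expect_error(tokenize_ipa(ono_table, "fu7", policy = "strict"),
               "position 3")
  expect_warning(t2 <- tokenize_ipa(ono_table, "f7ŋ", policy = "skip"),
                 "dropped 1")
  expect_identical(as.character(t2), c("f", "ŋ"))
})

test_that("absorbed symbols resolve to their canonical partner", {
  expect_identical(as.character(tokenize_ipa(ono_table, "ɛ")), "e")
  expect_equal(decompose_phoneme(ono_table, "ɔ"),
               decompose_phoneme(ono_table, "o"))
  # precomposed accented orthography keeps its carrier vowel under skip
  expect_identical(as.character(tokenize_ipa(ono_table, "bé", policy = "skip")),
                   c("b", "e"))
})

test_that("tokenizing a concatenation equals concatenating token lists", {
  words <- c("fuŋ", "plask", "tok", "ʃʁii")
  for (i in seq_along(words)) for (j in seq_along(words)) {
    expect_identical(
      as.character(tokenize_ipa(ono_table, paste0(words[i], words[j]))),
      c(as.character(tokenize_ipa(ono_table, words[i])),
        as.character(tokenize_ipa(ono_table, words[j]))))
  }
})

test_that("malformed charts are rejected with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("symbol", "absorbed_into", "sonorant", "syllabic",
                 "consonantal", "continuant", "nasal", "high", "low", "back",
                 "round", "anterior", "coronal", "voiced"), collapse = ",")
  writeLines(hdr, tmp)
  expect_error(load_feature_table(tmp), "no symbols")
  writeLines(c(hdr, "f,,0,0,1,1,0,0,0,0,0,2,0,0"), tmp)
  expect_error(load_feature_table(tmp), "non-binary")
  writeLines(c(hdr, "f,,0,0,1,1,0,0,0,0,0,1,0,0",
               "f,,0,0,1,1,0,0,0,0,0,1,0,0"), tmp)
  expect_error(load_feature_table(tmp), "duplicate")
  # two distinct symbols sharing a feature vector break injectivity
  writeLines(c(hdr, "f,,0,0,1,1,0,0,0,0,0,1,0,0",
               "s,,0,0,1,1,0,0,0,0,0,1,0,0"), tmp)
  expect_error(load_feature_table(tmp), "injective")
  expect_error(decompose_phoneme(ono_table, "7"), "7")
})
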