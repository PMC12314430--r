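test_that("sonority_default follows the anchored 0-9 scale", {
  expect_equal(sonority_default(c("voiceless_stop", "lateral")), 2.5) # /pl/
  expect_equal(sonority_default("voiceless_stop"), 0)                 # /t/
  expect_equal(sonority_default(character(0), "open_vowel"), 9)
  expect_equal(sonority_default(c("voiceless_fricative", "rhotic")), 4)
  expect_error(sonority_default("click"), "click")
  expect_error(sonority_default(character(0)), "nucleus_class")
  # custom table override
  expect_equal(sonority_default("nasal", table = c(nasal = 4.5)), 4.5)
})

test_that("relative_intensity is ~1 for average nuclei, flags silence", {
  rate <- 44100
  # uniform-loudness sentence: every nucleus has relative intensity 1
  w <- rt_wave(0.5 * sin(2 * pi * 220 * (0:(rate - 1)) / rate), rate)
  ri <- relative_intensity(w, c(0.3, 0.5))
  expect_false(ri$flagged)
  expect_equal(ri$value, 1, tolerance = 1e-3)

  # louder nucleus -> ratio above 1
  x <- 0.2 * sin(2 * pi * 220 * (0:(rate - 1)) / rate)
  i <- floor(0.3 * rate):floor(0.5 * rate)
  x[i] <- x[i] * 2                               # +6 dB segment
  ri2 <- relative_intensity(rt_wave(x, rate), c(0.32, 0.48))
  expect_gt(ri2$value, 1)

  # digital silence nucleus -> measurement-failure flag
  x[i] <- 0
  ri3 <- relative_intensity(rt_wave(x, rate), c(0.32, 0.48))
  expect_true(ri3$flagged)
  expect_true(is.na(ri3$value))
})

make_corpus <- function(cx4 = 3L) {
  specs <- list(
    syllable_spec(0.025, "none", 0.15, sonority = 9),
    syllable_spec(0.040, "sonorant", 0.12, onset_complexity = 1,
                  sonority = 4),
    syllable_spec(0.060, "obstruent", 0.10, onset_complexity = 2,
                  sonority = 1, weight = "strong"),
    syllable_spec(0.030, "fricative", 0.14, onset_complexity = cx4,
                  sonority = 2))
  syn <- synth_sentence(specs, gap_s = 0.06, rate_hz = 22050, seed = 5)
  ch <- energy_chain(syn$wave)
  iv <- syn$annotation[, c("sentence_id", "syllable_idx", "start_s",
                           "end_s")]
  rises <- rise_table(ch$smoothed, ch$difference, iv)
  list(syn = syn, rises = rises)
}

test_that("build_feature_table joins, recodes and applies exclusions", {
  cp <- make_corpus(cx4 = 3L)
  ft <- build_feature_table(cp$syn$annotation, cp$rises, cp$syn$wave)
  excl <- attr(ft, "exclusions")
  # exactly the 3-consonant-onset row dropped
  expect_equal(nrow(ft), 3L)
  expect_equal(excl$syllable_idx, 4L)
  expect_equal(excl$reason, "onset_complexity_3")
  expect_s3_class(ft$onset_complexity, "factor")
  expect_equal(levels(ft$onset_complexity), c("0", "1", "2"))
  expect_equal(levels(ft$weight), c("weak", "strong"))
  expect_true(all(is.finite(ft$rel_intensity)))
  expect_equal(ft$nucleus_dur_s, c(0.15, 0.12, 0.10), tolerance = 1e-9)

  # no failures -> row count unchanged
  cp2 <- make_corpus(cx4 = 2L)
  ft2 <- build_feature_table(cp2$syn$annotation, cp2$rises, cp2$syn$wave)
  expect_equal(nrow(ft2), 4L)
  expect_equal(nrow(attr(ft2, "exclusions")), 0L)

  # exclusion filters are idempotent: rebuilding from retained rows is a
  # no-op
  keep_ann <- cp$syn$annotation[cp$syn$annotation$syllable_idx %in%
                                  ft$syllable_idx, ]
  ft3 <- build_feature_table(keep_ann, cp$rises, cp$syn$wave)
  expect_equal(nrow(ft3), nrow(ft))

  # join mismatch -> error naming the orphan rows
  expect_error(build_feature_table(cp$syn$annotation, cp$rises[-2, ],
                                   cp$syn$wave), "s1:2")
})
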