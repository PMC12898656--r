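lm <- label_map(silent_labels = "sil", filled_labels = c("fp", "hes"))

write_tmp_ctm <- function(lines) {
  f <- withr::local_tempfile(fileext = ".ctm",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("CTM parsing maps labels to categories and groups utterances", {
  f <- write_tmp_ctm(c("u1 1 0.00 0.30 a",
                       "u1 1 0.30 0.20 sil",
                       "u1 1 0.50 0.25 b"))
  tls <- read_ctm(f, lm)
  expect_length(tls, 1L)
  expect_equal(tls[[1]]$tokens$category,
               c("phone", "silent_pause", "phone"))
  expect_false(tls[[1]]$normalized)

  ## interleaved utterance ids: grouped and internally time-sorted
  f2 <- write_tmp_ctm(c("u2 1 0.50 0.10 c",
                        "u1 1 0.00 0.30 a",
                        "u2 1 0.00 0.40 b",
                        "u1 1 0.40 0.20 sil",
                        "# comment line",
                        "u2 1 0.90 0.10 fp",
                        "u1 1 0.60 0.10 d"))
  tls2 <- read_ctm(f2, lm)
  expect_length(tls2, 2L)
  expect_equal(vapply(tls2, `[[`, "", "subject_id"), c("u2", "u1"))
  for (tl in tls2) {
    expect_true(all(diff(tl$tokens$start) > 0))
  }
  expect_equal(tls2[[1]]$tokens$category,
               c("phone", "phone", "filled_pause"))
})

test_that("malformed CTM input is rejected with line numbers", {
  expect_error(read_ctm(write_tmp_ctm("u1 1 0.0 0.0 a"), lm),
               "non-positive")
  expect_error(read_ctm(write_tmp_ctm("u1 1 0.0 x a"), lm),
               "unparsable")
  expect_error(read_ctm(write_tmp_ctm("u1 1 0.0"), lm), "5")
  ## overlap within an utterance
  f <- write_tmp_ctm(c("u1 1 0.00 0.50 a", "u1 1 0.30 0.30 b"))
  expect_error(read_ctm(f, lm), "overlap")
})

test_that("CTM round-trip preserves labels, categories and times to 3 dp", {
  set.seed(41)
  tls <- lapply(1:3, function(i) {
    tl <- random_timeline(8L, subject_id = paste0("s", i))
    tl$normalized <- FALSE
    tl
  })
  f <- withr::local_tempfile(fileext = ".ctm")
  write_ctm(tls, f)
  back <- read_ctm(f, lm)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$tokens$label, tls[[i]]$tokens$label)
    expect_equal(back[[i]]$tokens$category, tls[[i]]$tokens$category)
    expect_equal(back[[i]]$tokens$start, round(tls[[i]]$tokens$start, 3),
                 tolerance = 2e-3)
  }
  ## times serialized at 3 decimals exactly
  f2 <- withr::local_tempfile(fileext = ".ctm")
  tok <- data.frame(label = "a", category = "phone",
                    start = 0.12345, end = 1.23456)
  write_ctm(speech_timeline("x", tok), f2)
  expect_match(readLines(f2), "^x 1 0\\.123 1\\.112 a$")
  back2 <- read_ctm(f2, lm)[[1]]
  expect_equal(back2$tokens$start, 0.123)
  expect_equal(back2$tokens$end, 1.235)

  f3 <- withr::local_tempfile(fileext = ".ctm")
  write_ctm(list(), f3)
  expect_identical(readLines(f3), character(0))
  expect_length(read_ctm(f3, lm), 0L)
})

test_that("TextGrid interval tiers are read in long and short formats", {
  long <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 1.4", "tiers? <exists>", "size = 2", "item []:",
    "    item [1]:", '        class = "IntervalTier"',
    '        name = "phones"', "        xmin = 0", "        xmax = 1.4",
    "        intervals: size = 3",
    "        intervals [1]:", "            xmin = 0",
    "            xmax = 0.5", '            text = "a"',
    "        intervals [2]:", "            xmin = 0.5",
    "            xmax = 0.9", '            text = ""',
    "        intervals [3]:", "            xmin = 0.9",
    "            xmax = 1.4", '            text = "hes"',
    "    item [2]:", '        class = "TextTier"',
    '        name = "points"', "        xmin = 0", "        xmax = 1.4",
    "        points: size = 0")
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long, f)
  tl <- read_textgrid(f, "phones", lm)
  expect_equal(tl$tokens$category,
               c("phone", "silent_pause", "filled_pause"))
  expect_equal(tl$tokens$start, c(0, 0.5, 0.9))
  expect_equal(tl$tokens$end, c(0.5, 0.9, 1.4))

  expect_error(read_textgrid(f, "words", lm), "phones")
  expect_error(read_textgrid(f, "points", lm), "interval")

  short <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", "1.4", "<exists>", "1",
             '"IntervalTier"', '"phones"', "0", "1.4", "3",
             "0", "0.5", '"a"',
             "0.5", "0.9", '""',
             "0.9", "1.4", '"hes"')
  f2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short, f2)
  tl2 <- read_textgrid(f2, "phones", lm)
  expect_equal(tl2$tokens, tl$tokens)
})

test_that("normalization merges, trims, thresholds and is idempotent", {
  ## [sil .2 | a | sil .3 | sil .2 | b | sil .5] -> [a | sil .5 | b]
  tok <- data.frame(
    label = c("sil", "a", "sil", "sil", "b", "sil"),
    category = c("silent_pause", "phone", "silent_pause", "silent_pause",
                 "phone", "silent_pause"),
    start = c(0, 0.2, 0.5, 0.8, 1.0, 1.6),
    end = c(0.2, 0.5, 0.8, 1.0, 1.6, 2.1))
  tl <- normalize_timeline(speech_timeline("s", tok), min_pause_s = 0.03)
  expect_equal(tl$tokens$category, c("phone", "silent_pause", "phone"))
  expect_equal(tl$tokens$end - tl$tokens$start, c(0.3, 0.5, 0.6))
  expect_true(tl$normalized)

  ## sub-threshold internal silence leaves the pause inventory but keeps
  ## its span: phone count and utterance length unchanged
  tok2 <- data.frame(label = c("a", "sil", "b"),
                     category = c("phone", "silent_pause", "phone"),
                     start = c(0, 0.3, 0.31), end = c(0.3, 0.31, 0.6))
  tl2 <- normalize_timeline(speech_timeline("s2", tok2),
                            min_pause_s = 0.03)
  v <- compute_tsp(tl2)
  expect_equal(v$n_phones, 2L)
  expect_equal(v$n_silent_pauses, 0L)
  expect_equal(v$tsp[["utterance_length"]], 0.6)
  expect_equal(v$tsp[["articulation_tempo"]], v$tsp[["speech_tempo"]])

  ## unlabeled gaps become silent pauses
  tok3 <- data.frame(label = c("a", "b"), category = c("phone", "phone"),
                     start = c(0, 0.5), end = c(0.2, 0.8))
  tl3 <- normalize_timeline(speech_timeline("s3", tok3))
  expect_equal(tl3$tokens$category, c("phone", "silent_pause", "phone"))

  ## idempotence on a batch of random raw timelines
  set.seed(7)
  for (i in 1:20) {
    raw <- random_timeline(sample(3:15, 1))
    raw$normalized <- FALSE
    n1 <- normalize_timeline(raw)
    n2 <- normalize_timeline(n1)
    expect_identical(n1$tokens, n2$tokens)
    ## never more pause tokens than before
    expect_lte(sum(n1$tokens$category %in% c("silent_pause", "filled_pause")),
               sum(raw$tokens$category %in% c("silent_pause", "filled_pause")))
    ## token durations fit inside the span
    expect_lte(sum(n1$tokens$end - n1$tokens$start),
               max(n1$tokens$end) - min(n1$tokens$start) + 1e-9)
  }

  ## all-silence timeline is degenerate
  tok4 <- data.frame(label = "sil", category = "silent_pause",
                     start = 0, end = 1)
  expect_error(normalize_timeline(speech_timeline("s4", tok4)),
               class = "speechtsp_degenerate_error")
})
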