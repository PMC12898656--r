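## Independent oracles and fixture builders. The oracles deliberately use
## naive loops so they share no code path with the implementation.

## Build a valid normalized timeline from category/duration vectors.
make_timeline <- function(categories, durations, subject_id = "t",
                          group = NULL, labels = NULL, start0 = 0) {
  stopifnot(length(categories) == length(durations))
  if (is.null(labels)) {
    labels <- c(phone = "p", silent_pause = "sil",
                filled_pause = "fp")[categories]
  }
  end <- start0 + cumsum(durations)
  tok <- data.frame(label = unname(labels), category = categories,
                    start = c(start0, end[-length(end)]), end = end)
  speech_timeline(subject_id, tok, group = group, normalized = TRUE)
}

## Random normalized timeline: first/last tokens are phones, no adjacent
## silent pauses, >= 1 phone.
random_timeline <- function(n_tokens, subject_id = "r", group = NULL) {
  stopifnot(n_tokens >= 1L)
  cats <- character(n_tokens)
  cats[1L] <- "phone"
  for (i in seq_len(n_tokens)[-1L]) {
    opts <- c("phone", "filled_pause")
    if (cats[i - 1L] != "silent_pause" && i < n_tokens) {
      opts <- c(opts, "silent_pause")
    }
    cats[i] <- sample(opts, 1L, prob = c(0.6, 0.2, 0.2)[seq_along(opts)])
  }
  cats[n_tokens] <- "phone"
  make_timeline(cats, runif(n_tokens, 0.05, 0.6), subject_id, group)
}

## Brute-force temporal parameters: explicit token walk, formulas written
## out one by one.
brute_force_tsp <- function(tl) {
  tok <- tl$tokens
  n_phones <- 0; n_sil <- 0; n_fil <- 0
  t_sil <- 0; t_fil <- 0
  for (i in seq_len(nrow(tok))) {
    d <- tok$end[i] - tok$start[i]
    if (tok$category[i] == "phone") n_phones <- n_phones + 1
    if (tok$category[i] == "silent_pause") {
      n_sil <- n_sil + 1; t_sil <- t_sil + d
    }
    if (tok$category[i] == "filled_pause") {
      n_fil <- n_fil + 1; t_fil <- t_fil + d
    }
  }
  U <- tok$end[nrow(tok)] - tok$start[1L]
  c(utterance_length = U,
    articulation_tempo = n_phones / (U - t_sil - t_fil),
    speech_tempo = n_phones / U,
    silent_pause_occurrence_rate = n_sil * 100 / n_phones,
    filled_pause_occurrence_rate = n_fil * 100 / n_phones,
    total_pause_occurrence_rate = (n_sil + n_fil) * 100 / n_phones,
    silent_pause_duration_rate = t_sil * 100 / U,
    filled_pause_duration_rate = t_fil * 100 / U,
    total_pause_duration_rate = (t_sil + t_fil) * 100 / U,
    silent_pause_frequency = n_sil / U,
    filled_pause_frequency = n_fil / U,
    total_pause_frequency = (n_sil + n_fil) / U,
    silent_pause_average_duration = if (n_sil > 0) t_sil / n_sil else NA_real_,
    filled_pause_average_duration = if (n_fil > 0) t_fil / n_fil else NA_real_,
    total_pause_average_duration =
      if (n_sil + n_fil > 0) (t_sil + t_fil) / (n_sil + n_fil) else NA_real_)
}

## Brute-force AUC: count all pairs.
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

## Hand-built subject parameters (bypassing sample_subject).
subject_params <- function(utterance_length, articulation_tempo,
                           silent_durations = numeric(),
                           filled_durations = numeric()) {
  p_time <- sum(silent_durations) + sum(filled_durations)
  structure(list(
    utterance_length = utterance_length,
    articulation_tempo = articulation_tempo,
    n_phones = as.integer(round(articulation_tempo *
                                  (utterance_length - p_time))),
    n_silent = length(silent_durations),
    n_filled = length(filled_durations),
    silent_durations = silent_durations,
    filled_durations = filled_durations), class = "tsp_subject_params")
}

table3_summaries <- function() {
  utils::read.csv(system.file("extdata", "group_summaries.csv",
                              package = "speechtsp"))
}
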