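## Synthetic speech-timeline cohorts.
##
## The generator is constructive: per subject a small set of free
## parameters is drawn (utterance length, articulation tempo, pause-count
## intensity and mean pause duration per scope), from which a timeline is
## built deterministically. compute_tsp() then inverts the construction
## exactly, which makes the generator a sharp oracle for the feature
## engine.

#' Log-normal parameters from mean and SD
#'
#' Standard moment inversion: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param mean,sd target mean and standard deviation (natural scale).
#' @return List with `meanlog`, `sdlog`.
#' @export
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Moments of a normal truncated to [lo, hi].
tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

## Underlying (mu, sigma) such that the [lo, hi]-truncated normal has the
## requested mean and SD. Solved numerically; the naive (mu, sigma) =
## (mean, sd) can be biased by > 1 unit when the target mean sits within
## ~2 SD of a bound.
tnorm_match <- function(mean, sd, lo, hi) {
  if (sd <= 1e-12) return(list(mu = mean, sigma = 0, lo = lo, hi = hi))
  obj <- function(par) {
    m <- tnorm_moments(par[1L], exp(par[2L]), lo, hi)
    (m[["mean"]] - mean)^2 / sd^2 + (m[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]), lo = lo, hi = hi)
}

## Inverse-CDF sampler for the truncated normal (exact, no rejection).
## `u` is a uniform draw, so correlated draws can be fed through it.
qtnorm <- function(u, tn) {
  if (tn$sigma <= 0) return(rep(tn$mu, length(u)))
  pa <- pnorm((tn$lo - tn$mu) / tn$sigma)
  pb <- pnorm((tn$hi - tn$mu) / tn$sigma)
  tn$mu + tn$sigma * qnorm(pa + u * (pb - pa))
}

#' Generator configuration for one group
#'
#' Free per-subject parameters and their sampling laws:
#' \itemize{
#'   \item utterance length and articulation tempo: truncated normals,
#'     moment-matched so the truncated distribution (not the untruncated
#'     one) has the requested mean/SD;
#'   \item pause-count intensity per scope (expected pauses per 100
#'     phones): gamma-mixed Poisson — the subject draws a latent rate
#'     from a gamma law, then counts are Poisson with intensity
#'     rate/100 × phone count. The latent gamma SD is chosen so the
#'     *total* occurrence-rate SD (latent + Poisson) matches the target;
#'   \item mean pause duration per scope: log-normal subject-level
#'     location; individual pauses are log-normal around it with
#'     within-subject coefficient of variation `within_cv`. The
#'     subject-level SD is likewise deflated so the subject-average
#'     duration has the requested SD;
#'   \item count intensity and mean duration of a scope are coupled by a
#'     Gaussian copula whose correlation is calibrated in closed form
#'     from the scope's target duration rate (see the methods vignette;
#'     printed group moments are not attainable under independence).
#' }
#'
#' @param name group label.
#' @param utterance_length_mean,utterance_length_sd seconds.
#' @param articulation_tempo_mean,articulation_tempo_sd phones/s.
#' @param silent_rate_mean,silent_rate_sd occurrence-rate targets
#'   (pauses per 100 phones) for silent pauses.
#' @param filled_rate_mean,filled_rate_sd same for filled pauses.
#' @param silent_dur_mean,silent_dur_sd subject-average silent-pause
#'   duration targets (s).
#' @param filled_dur_mean,filled_dur_sd same for filled pauses.
#' @param silent_duration_rate,filled_duration_rate,total_duration_rate
#'   target duration rates (%), used only to calibrate the count-duration
#'   copula; `NULL` means independence.
#' @param within_cv within-subject coefficient of variation of individual
#'   pause durations (default 0.6; affects no group mean).
#' @param count_family `"poisson"` (default) or `"fixed"` (deterministic
#'   rounded counts, for degenerate test configs).
#' @param utterance_length_bounds,articulation_tempo_bounds physiological
#'   truncation bounds.
#' @param min_pause_s minimum pause duration the generator emits.
#' @return An object of class `tsp_group_config`.
#' @seealso [default_configs()], [sample_subject()], [simulate_cohort()]
#' @export
group_config <- function(name,
                         utterance_length_mean, utterance_length_sd,
                         articulation_tempo_mean, articulation_tempo_sd,
                         silent_rate_mean, silent_rate_sd,
                         filled_rate_mean, filled_rate_sd,
                         silent_dur_mean, silent_dur_sd,
                         filled_dur_mean, filled_dur_sd,
                         silent_duration_rate = NULL,
                         filled_duration_rate = NULL,
                         total_duration_rate = NULL,
                         within_cv = 0.6,
                         count_family = c("poisson", "fixed"),
                         utterance_length_bounds = c(15, 600),
                         articulation_tempo_bounds = c(6, 25),
                         min_pause_s = 0.03) {
  count_family <- match.arg(count_family)
  stopifnot(utterance_length_sd >= 0, articulation_tempo_sd >= 0,
            silent_rate_sd >= 0, filled_rate_sd >= 0,
            silent_dur_sd >= 0, filled_dur_sd >= 0, within_cv >= 0)

  ## expected articulation fraction and phone count, used for variance
  ## decomposition; the total duration-rate target (or the sum of the
  ## scope targets, or the independent product) supplies it
  dr_tot <- total_duration_rate
  if (is.null(dr_tot) &&
      !(is.null(silent_duration_rate) && is.null(filled_duration_rate))) {
    dr_tot <- sum(c(silent_duration_rate, filled_duration_rate))
  }
  if (is.null(dr_tot) || is.na(dr_tot) || dr_tot <= 0) {
    dr_tot <- articulation_tempo_mean *
      (silent_rate_mean * silent_dur_mean +
         filled_rate_mean * filled_dur_mean) / 100
    dr_tot <- 100 * dr_tot / (1 + dr_tot)          # self-consistent fixed point
  }
  art_frac <- 1 - dr_tot / 100
  n_p_bar <- max(articulation_tempo_mean * utterance_length_mean * art_frac, 20)

  scope_cfg <- function(rate_mean, rate_sd, dur_mean, dur_sd, dr_target) {
    ## latent gamma SD: strip the Poisson component of the occurrence-rate
    ## variance (Var(100 n / n_p | R) = 100 R / n_p)
    pois_var <- if (count_family == "poisson") 100 * rate_mean / n_p_bar else 0
    lat_var <- max(rate_sd^2 - pois_var, 0)
    lat_sd <- sqrt(lat_var)
    ## latent duration SD: strip the within-subject component of the
    ## subject-average variance (approx w^2 (m^2 + s^2) / lambda)
    lambda <- max(rate_mean / 100 * n_p_bar, 1)
    w2l <- within_cv^2 / lambda
    dlat_var <- max((dur_sd^2 - w2l * dur_mean^2) / (1 + w2l), 0)
    dlat_sd <- sqrt(dlat_var)
    ## copula correlation from the duration-rate target:
    ## DR_scope = rate x dur x speech_tempo / 100 x 100 holds per subject,
    ## so E[rate x dur] = DR_target / (AT_mean x art_frac) pins Cov(R, D)
    rho <- 0
    if (!is.null(dr_target) && lat_sd > 1e-9 && dlat_sd > 1e-9) {
      need_cov <- dr_target / (articulation_tempo_mean * art_frac) -
        rate_mean * dur_mean
      rho <- max(-0.95, min(0.95, need_cov / (lat_sd * dlat_sd)))
    }
    dp <- lnorm_params(dur_mean, dlat_sd)
    list(rate_mean = rate_mean, rate_sd = lat_sd,
         gamma_shape = if (lat_sd > 1e-9) (rate_mean / lat_sd)^2 else Inf,
         gamma_rate = if (lat_sd > 1e-9) rate_mean / lat_sd^2 else Inf,
         dur_meanlog = dp$meanlog, dur_sdlog = dp$sdlog,
         dur_mean = dur_mean, rho = rho)
  }

  structure(list(
    name = as.character(name),
    u = tnorm_match(utterance_length_mean, utterance_length_sd,
                    utterance_length_bounds[1L], utterance_length_bounds[2L]),
    at = tnorm_match(articulation_tempo_mean, articulation_tempo_sd,
                     articulation_tempo_bounds[1L],
                     articulation_tempo_bounds[2L]),
    silent = scope_cfg(silent_rate_mean, silent_rate_sd,
                       silent_dur_mean, silent_dur_sd, silent_duration_rate),
    filled = scope_cfg(filled_rate_mean, filled_rate_sd,
                       filled_dur_mean, filled_dur_sd, filled_duration_rate),
    within_cv = within_cv, count_family = count_family,
    min_pause_s = min_pause_s,
    targets = list(utterance_length = utterance_length_mean,
                   articulation_tempo = articulation_tempo_mean,
                   silent_rate = silent_rate_mean,
                   filled_rate = filled_rate_mean,
                   silent_dur = silent_dur_mean,
                   filled_dur = filled_dur_mean)),
    class = "tsp_group_config")
}

#' Default group configurations for a case-control speech cohort
#'
#' Two configurations — `control` and `aud` (alcohol use disorder) —
#' whose free-parameter targets are the published group means and SDs of
#' the temporal speech parameters for 31 controls and 34 AUD patients:
#' utterance length, articulation tempo, silent/filled pause occurrence
#' rates and average durations, with the duration-rate rows used to
#' calibrate the count-duration coupling. Derived parameters (speech
#' tempo, duration rates, frequencies) are not set directly but emerge
#' near their published values.
#'
#' @return Named list of two [group_config()] objects.
#' @export
default_configs <- function() {
  list(
    control = group_config(
      "control",
      utterance_length_mean = 84.052, utterance_length_sd = 34.760,
      articulation_tempo_mean = 14.743, articulation_tempo_sd = 1.544,
      silent_rate_mean = 4.850, silent_rate_sd = 1.628,
      filled_rate_mean = 1.512, filled_rate_sd = 0.897,
      silent_dur_mean = 0.641, silent_dur_sd = 0.155,
      filled_dur_mean = 0.243, filled_dur_sd = 0.078,
      silent_duration_rate = 30.538, filled_duration_rate = 3.798,
      total_duration_rate = 34.336),
    aud = group_config(
      "aud",
      utterance_length_mean = 77.569, utterance_length_sd = 44.481,
      articulation_tempo_mean = 14.551, articulation_tempo_sd = 1.186,
      silent_rate_mean = 5.243, silent_rate_sd = 1.907,
      filled_rate_mean = 2.831, filled_rate_sd = 1.695,
      silent_dur_mean = 0.983, silent_dur_sd = 0.488,
      filled_dur_mean = 0.246, filled_dur_sd = 0.090,
      silent_duration_rate = 39.112, filled_duration_rate = 6.914,
      total_duration_rate = 46.025)
  )
}

#' Draw the free parameters of one synthetic subject
#'
#' Sampling order (chosen so every free temporal parameter is unbiased in
#' expectation): draw utterance length, articulation tempo and the
#' copula-coupled (rate, duration) pairs; fix the phone count from the
#' self-consistency equation `n_p = AT x U / (1 + AT x sum(rate x dur)/100)`
#' *before* drawing Poisson counts; draw counts and individual pause
#' durations; finally re-derive the realized utterance length as
#' `n_p / AT + pause time`. Draws violating the structural constraints
#' (pauses must fit between distinct internal phone boundaries; every
#' pause at least `min_pause_s`) are rejected and redrawn.
#'
#' @param config a [group_config()].
#' @param seed optional integer; if given, seeds the RNG first (otherwise
#'   the current RNG stream is used).
#' @param max_attempts rejection budget before erroring.
#' @return An object of class `tsp_subject_params`: utterance length,
#'   articulation tempo, phone count, pause counts and duration vectors.
#' @export
sample_subject <- function(config, seed = NULL, max_attempts = 100L) {
  stopifnot(inherits(config, "tsp_group_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- config$within_cv
  sdl <- sqrt(log(1 + w^2))

  draw_scope <- function(sc, n_p) {
    lam <- sc$rate_draw / 100 * n_p
    n <- if (config$count_family == "poisson") rpois(1L, lam) else
      as.integer(round(lam))
    if (n == 0L) return(list(n = 0L, dur = numeric()))
    ml <- log(sc$dur_draw) - sdl^2 / 2
    dur <- rlnorm(n, ml, sdl)
    for (tries in 1:20) {
      bad <- dur < config$min_pause_s
      if (!any(bad)) break
      dur[bad] <- rlnorm(sum(bad), ml, sdl)
    }
    dur[dur < config$min_pause_s] <- config$min_pause_s
    list(n = n, dur = dur)
  }

  for (attempt in seq_len(max_attempts)) {
    u0 <- qtnorm(runif(1L), config$u)
    at <- qtnorm(runif(1L), config$at)
    cop <- function(sc) {
      z1 <- rnorm(1L); z2 <- sc$rho * z1 + sqrt(1 - sc$rho^2) * rnorm(1L)
      r <- if (is.finite(sc$gamma_shape))
        qgamma(pnorm(z1), shape = sc$gamma_shape, rate = sc$gamma_rate)
      else sc$rate_mean
      d <- if (sc$dur_sdlog > 0) qlnorm(pnorm(z2), sc$dur_meanlog, sc$dur_sdlog)
      else sc$dur_mean
      c(sc, list(rate_draw = r, dur_draw = d))
    }
    sil <- cop(config$silent); fil <- cop(config$filled)
    ci <- at * (sil$rate_draw * sil$dur_draw +
                  fil$rate_draw * fil$dur_draw) / 100
    n_p <- max(1L, as.integer(round(at * u0 / (1 + ci))))
    ds <- draw_scope(sil, n_p)
    df <- draw_scope(fil, n_p)
    if (ds$n + df$n > n_p - 1L) next
    p_time <- sum(ds$dur) + sum(df$dur)
    u <- n_p / at + p_time
    return(structure(list(
      utterance_length = u, articulation_tempo = at,
      n_phones = n_p, n_silent = ds$n, n_filled = df$n,
      silent_durations = ds$dur, filled_durations = df$dur),
      class = "tsp_subject_params"))
  }
  stop_speechtsp(sprintf(
    "group '%s': no valid subject parameters after %d attempts (config likely unsatisfiable)",
    config$name, max_attempts), "speechtsp_generator_error")
}

#' @export
print.tsp_subject_params <- function(x, ...) {
  cat(sprintf(
    "Subject parameters: %.1f s, %.2f phones/s, %d phones, %d silent + %d filled pauses\n",
    x$utterance_length, x$articulation_tempo, x$n_phones,
    x$n_silent, x$n_filled))
  invisible(x)
}

#' Build a timeline from subject parameters
#'
#' Deterministic construction up to pause placement: `n_phones` phones of
#' equal duration, with the sampled pauses inserted at distinct,
#' uniformly chosen internal phone boundaries (never before the first or
#' after the last phone), so the output is already normalized. The
#' timeline inverts exactly under [compute_tsp()]: every temporal
#' parameter implied by `params` is reproduced to floating-point
#' precision.
#'
#' @param params a [sample_subject()] result (or hand-built
#'   `tsp_subject_params`).
#' @param subject_id,group identifiers for the resulting timeline.
#' @param seed optional integer seed for the placement draw.
#' @return A normalized [speech_timeline()].
#' @export
construct_timeline <- function(params, subject_id = "synthetic",
                               group = NULL, seed = NULL) {
  stopifnot(inherits(params, "tsp_subject_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_p <- params$n_phones
  p_time <- sum(params$silent_durations) + sum(params$filled_durations)
  if (p_time >= params$utterance_length) {
    stop_speechtsp("pause time exceeds utterance length",
                   "speechtsp_generator_error")
  }
  if (n_p < 1L) {
    stop_speechtsp("subject has no phones", "speechtsp_generator_error")
  }
  k <- params$n_silent + params$n_filled
  if (k > n_p - 1L) {
    stop_speechtsp(sprintf(
      "%d pauses cannot occupy %d internal boundaries", k, n_p - 1L),
      "speechtsp_generator_error")
  }
  phone_dur <- (params$utterance_length - p_time) / n_p
  pos <- if (k > 0L) sort(sample.int(n_p - 1L, k)) else integer()
  pcat <- sample(c(rep("silent_pause", params$n_silent),
                   rep("filled_pause", params$n_filled)))
  pdur <- numeric(k)
  pdur[pcat == "silent_pause"] <- params$silent_durations
  pdur[pcat == "filled_pause"] <- params$filled_durations

  key <- c(seq_len(n_p), pos)
  tie <- c(rep(0L, n_p), rep(1L, k))
  cat_all <- c(rep("phone", n_p), pcat)
  dur_all <- c(rep(phone_dur, n_p), pdur)
  lab_all <- c(rep("p", n_p),
               ifelse(pcat == "silent_pause", "sil", "fp"))
  o <- order(key, tie)
  dur_o <- dur_all[o]
  end <- cumsum(dur_o)
  tok <- data.frame(label = lab_all[o], category = cat_all[o],
                    start = c(0, end[-length(end)]), end = end)
  speech_timeline(subject_id, tok, group = group, normalized = TRUE)
}

#' Cohort specification
#'
#' @param n_per_group named integer vector, e.g.
#'   `c(control = 31, aud = 34)` (the default; counts must be >= 2).
#' @param configs named list of [group_config()] objects covering every
#'   group in `n_per_group`; defaults to [default_configs()].
#' @param seed master seed; per-subject substreams are derived by stable
#'   hashing of (seed, group, index), so cohorts are reproducible under
#'   reordering.
#' @return An object of class `tsp_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 31L, aud = 34L),
                        configs = default_configs(), seed = 1L) {
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 2))
  missing_cfg <- setdiff(names(n_per_group), names(configs))
  if (length(missing_cfg) > 0L) {
    stop_speechtsp(sprintf("no generator config for group(s): %s",
                           paste(missing_cfg, collapse = ", ")),
                   "speechtsp_validation_error")
  }
  structure(list(n_per_group = n_per_group, configs = configs,
                 seed = as.integer(seed)),
            class = "tsp_cohort_spec")
}

#' Simulate a cohort of speech timelines
#'
#' Draws `n_per_group` subjects per group via [sample_subject()] /
#' [construct_timeline()] and computes their feature table. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param return_timelines keep the timelines in the result (`TRUE`,
#'   default) or only the feature table (`FALSE`, for large cohorts).
#' @return An object of class `tsp_cohort`: list with `features` (a
#'   `tsp_feature_table`) and `timelines` (list or `NULL`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(c(control = 3, aud = 3), seed = 7))
#' coh$features
#' @export
simulate_cohort <- function(spec = cohort_spec(), return_timelines = TRUE) {
  stopifnot(inherits(spec, "tsp_cohort_spec"))
  groups <- names(spec$n_per_group)
  timelines <- list()
  rows <- vector("list", sum(spec$n_per_group))
  r <- 0L
  for (g in groups) {
    cfg <- spec$configs[[g]]
    for (i in seq_len(spec$n_per_group[[g]])) {
      set.seed(subject_seed(spec$seed, g, i))
      p <- sample_subject(cfg)
      tl <- construct_timeline(p, subject_id = sprintf("%s_%04d", g, i),
                               group = g)
      r <- r + 1L
      rows[[r]] <- tl
      if (return_timelines) timelines[[tl$subject_id]] <- tl
    }
  }
  ft <- build_feature_table(rows)
  structure(list(features = ft,
                 timelines = if (return_timelines) timelines else NULL,
                 spec = spec),
            class = "tsp_cohort")
}

#' @export
print.tsp_cohort <- function(x, ...) {
  tab <- table(x$features$group)
  cat("Synthetic speech cohort:",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
            collapse = ", "),
      sprintf("(seed %d)\n", x$spec$seed))
  invisible(x)
}
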