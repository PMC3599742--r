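#' Synthetic RR-interval generators
#'
#' Seeded generators of labelled RR-interval records emulating the
#' qualitative heart-rate-variability signatures of five physiological
#' groups: uniform white noise (WNU), atrial fibrillation (AF, serially
#' uncorrelated high-variance intervals), congestive heart failure (CHF,
#' suppressed variability punctuated by rare large jumps), healthy young and
#' elderly subjects (HY/HE, respiratory sinus arrhythmia of different
#' amplitude over correlated noise) and obstructive sleep apnea (slow cyclic
#' bradycardia--tachycardia oscillation). These are minimal statistical
#' surrogates — not physiological models — intended to give the analysis
#' pipeline a separable multi-class corpus without clinical data. All
#' generators are deterministic given `seed` and emit strictly positive
#' intervals (values outside `[200, 2500]` ms are clipped, with the count
#' recorded in attribute `"clipped"` where applicable).
#'
#' @param length Number of intervals to generate (>= 2).
#' @param seed Integer seed.
#' @param record_id Record identifier.
#' @name synthetic_generators
NULL

check_length <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 2L) stop("`length` must be >= 2", call. = FALSE)
  length
}

clip_intervals <- function(x, lo = 200, hi = 2500) {
  clipped <- sum(x < lo | x > hi)
  x <- pmin(pmax(x, lo), hi)
  attr(x, "clipped") <- clipped
  x
}

#' @param low,high Uniform range in ms, `0 < low < high`.
#' @rdname synthetic_generators
#' @export
generate_wnu <- function(length, low = 600, high = 1400, seed = 1L,
                         record_id = "WNU") {
  length <- check_length(length)
  if (low <= 0) stop("`low` must be positive", call. = FALSE)
  if (high <= low) stop("`high` must exceed `low`", call. = FALSE)
  x <- withr::with_seed(seed, stats::runif(length, low, high))
  rr_record(record_id, x, label = "WNU")
}

# shared engine: mean + sinusoid + AR(1) noise, clipped
sinus_ar1 <- function(length, mean_rr, amplitude, period_beats, ar_coeff,
                      noise_sd, seed) {
  stopifnot(period_beats > 0, abs(ar_coeff) < 1, noise_sd >= 0, amplitude >= 0)
  osc <- amplitude * sin(2 * pi * seq_len(length) / period_beats)
  noise <- withr::with_seed(seed, {
    innov <- stats::rnorm(length, 0, noise_sd)
    as.numeric(stats::filter(innov, ar_coeff, method = "recursive"))
  })
  clip_intervals(mean_rr + osc + noise)
}

#' @param mean_rr Mean RR interval, ms.
#' @param osc_amplitude Respiratory sinus arrhythmia amplitude, ms.
#' @param osc_period_beats Oscillation period in beats (breathing period over
#'   mean RR; around 5 beats for a resting adult).
#' @param ar_coeff AR(1) coefficient of the noise component, in (-1, 1).
#' @param noise_sd Innovation standard deviation of the AR(1) noise, ms.
#' @param label Class label for the record.
#' @rdname synthetic_generators
#' @export
generate_healthy <- function(length, mean_rr = 800, osc_amplitude = 60,
                             osc_period_beats = 5, ar_coeff = 0.8,
                             noise_sd = 8, seed = 1L, record_id = "HY",
                             label = "HY") {
  length <- check_length(length)
  x <- sinus_ar1(length, mean_rr, osc_amplitude, osc_period_beats,
                 ar_coeff, noise_sd, seed)
  r <- rr_record(record_id, x, label = label)
  attr(r, "clipped") <- attr(x, "clipped")
  r
}

#' @param sd Interval standard deviation, ms (AF preset 180 at mean 700:
#'   serially uncorrelated, high-entropy differences).
#' @rdname synthetic_generators
#' @export
generate_af <- function(length, mean_rr = 700, sd = 180, seed = 1L,
                        record_id = "AF") {
  length <- check_length(length)
  stopifnot(sd >= 0)
  x <- withr::with_seed(seed, stats::rnorm(length, mean_rr, sd))
  x <- clip_intervals(x)
  r <- rr_record(record_id, x, label = "AF")
  attr(r, "clipped") <- attr(x, "clipped")
  r
}

#' @param base_sd Innovation sd of the low-variability AR(1) baseline, ms.
#' @param jump_prob Per-beat probability of an erratic jump.
#' @param jump_scale Jump magnitude, ms (sign random).
#' @rdname synthetic_generators
#' @export
generate_chf <- function(length, mean_rr = 750, base_sd = 8, ar_coeff = 0.9,
                         jump_prob = 0.02, jump_scale = 150, seed = 1L,
                         record_id = "CHF") {
  length <- check_length(length)
  stopifnot(jump_prob >= 0, jump_prob <= 1, jump_scale >= 0, base_sd >= 0)
  x <- withr::with_seed(seed, {
    innov <- stats::rnorm(length, 0, base_sd)
    base <- as.numeric(stats::filter(innov, ar_coeff, method = "recursive"))
    jumps <- stats::rbinom(length, 1L, jump_prob) *
      sample(c(-1, 1), length, replace = TRUE) * jump_scale
    mean_rr + base + jumps
  })
  x <- clip_intervals(x)
  r <- rr_record(record_id, x, label = "CHF")
  attr(r, "clipped") <- attr(x, "clipped")
  r
}

#' @param cycle_amplitude Amplitude of the apneic bradycardia--tachycardia
#'   cycle, ms.
#' @param cycle_period_beats Cycle period in beats (typically 25--100: a
#'   30--60 s respiratory event cycle at about 1 beat per second).
#' @rdname synthetic_generators
#' @export
generate_apnea <- function(length, mean_rr = 900, cycle_amplitude = 150,
                           cycle_period_beats = 40, ar_coeff = 0.7,
                           noise_sd = 8, seed = 1L, record_id = "APNEA") {
  length <- check_length(length)
  x <- sinus_ar1(length, mean_rr, cycle_amplitude, cycle_period_beats,
                 ar_coeff, noise_sd, seed)
  r <- rr_record(record_id, x, label = "APNEA")
  attr(r, "clipped") <- attr(x, "clipped")
  r
}

#' Specification of one synthetic class
#'
#' @param name Class label.
#' @param n_records Number of records to generate.
#' @param length Intervals per record (>= 100 for presets).
#' @param generator One of `"wnu"`, `"af"`, `"chf"`, `"healthy"`, `"apnea"`.
#' @param params Named list of generator parameters overriding defaults.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(name, n_records, length, generator, params = list()) {
  stopifnot(is.character(name), n_records >= 1L, length >= 2L)
  generator <- match.arg(generator, c("wnu", "af", "chf", "healthy", "apnea"))
  structure(
    list(name = name, n_records = as.integer(n_records),
         length = as.integer(length), generator = generator, params = params),
    class = "class_spec"
  )
}

#' Generate a labelled multi-class synthetic corpus
#'
#' Generates `n_records` records per class specification. Each record gets
#' its own seed derived from the master seed by the fixed rule
#' `seed + record index` (records numbered consecutively across the corpus),
#' so the corpus is reproducible record by record.
#'
#' @param specs A list of [class_spec()] objects, or a preset name
#'   (`"study1"`: AF 9, CHF 43, HE 20, HY 20, WNU 50 — 142 records;
#'   `"study2"`: APNEA, HE, HY, WNU with 20 each — 80 records).
#' @param seed Master integer seed.
#' @param length Intervals per record when `specs` is a preset name
#'   (default 2000; presets scale record length down from hours-long
#'   clinical recordings to keep analyses fast).
#' @return An [rr_corpus()].
#' @export
#' @examples
#' corpus <- generate_study("study2", seed = 7, length = 300)
#' table(corpus_labels(corpus))
generate_study <- function(specs, seed = 1L, length = 2000L) {
  if (is.character(specs)) specs <- study_preset(specs, length = length)
  ok <- vapply(specs, inherits, logical(1), what = "class_spec")
  if (!all(ok)) stop("`specs` must be class_spec objects or a preset name",
                     call. = FALSE)
  records <- list()
  idx <- 0L
  for (sp in specs) {
    for (j in seq_len(sp$n_records)) {
      idx <- idx + 1L
      rid <- sprintf("%s_%03d", sp$name, j)
      rseed <- as.integer(seed) + idx
      gen <- switch(sp$generator,
                    wnu = generate_wnu,
                    af = generate_af,
                    chf = generate_chf,
                    healthy = generate_healthy,
                    apnea = generate_apnea)
      args <- c(list(length = sp$length, seed = rseed, record_id = rid),
                sp$params)
      rec <- do.call(gen, args)
      rec$label <- sp$name
      records[[idx]] <- rec
    }
  }
  rr_corpus(records)
}

#' Preset class structures for the two study designs
#'
#' `"study1"` is a five-class design (AF 9, CHF 43, HE 20, HY 20, WNU 50;
#' 142 records); `"study2"` a four-class design (APNEA, HE, HY, WNU; 20
#' each, 80 records). HE uses an attenuated oscillation relative to HY,
#' reflecting the reduced respiratory sinus arrhythmia of elderly subjects.
#'
#' @param preset `"study1"` or `"study2"`.
#' @param length Intervals per record.
#' @return A list of [class_spec()] objects.
#' @export
study_preset <- function(preset = c("study1", "study2"), length = 2000L) {
  preset <- match.arg(preset)
  hy <- list(mean_rr = 800, osc_amplitude = 60, osc_period_beats = 5,
             ar_coeff = 0.8, noise_sd = 8, label = "HY")
  he <- list(mean_rr = 850, osc_amplitude = 25, osc_period_beats = 7,
             ar_coeff = 0.6, noise_sd = 5, label = "HE")
  if (preset == "study1") {
    list(class_spec("AF", 9L, length, "af"),
         class_spec("CHF", 43L, length, "chf"),
         class_spec("HE", 20L, length, "healthy", he),
         class_spec("HY", 20L, length, "healthy", hy),
         class_spec("WNU", 50L, length, "wnu"))
  } else {
    list(class_spec("APNEA", 20L, length, "apnea"),
         class_spec("HE", 20L, length, "healthy", he),
         class_spec("HY", 20L, length, "healthy", hy),
         class_spec("WNU", 20L, length, "wnu"))
  }
}
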