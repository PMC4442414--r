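#' @title Stimulus paradigms
#' @description Generators for the sampled stimulus u(t) driving the Balloon
#'   model. All paradigms are built on a uniform grid of spacing `te`
#'   (seconds); a sample at time t takes the value of the phase containing t,
#'   phases being half-open intervals `[start, end)`. Construction is done in
#'   integer sample counts so boundaries are exact.
#' @name stimulus
NULL

new_stimulus <- function(u, te, paradigm, meta) {
  n <- length(u)
  out <- tibble::tibble(time = (seq_len(n) - 1) * te, u = as.numeric(u))
  structure(out, te = te, paradigm = paradigm, meta = meta,
            class = c("bm_stimulus", class(out)))
}

#' @export
print.bm_stimulus <- function(x, ...) {
  cat(sprintf("<bm_stimulus: %s paradigm, %d samples, te = %g s, %.6g s total>\n",
              attr(x, "paradigm"), nrow(x), attr(x, "te"),
              nrow(x) * attr(x, "te")))
  NextMethod()
}

n_samples <- function(dur, te) {
  n <- as.integer(round(dur / te))
  if (abs(n * te - dur) > te / 2) {
    abort("duration is not commensurate with the sampling interval")
  }
  n
}

#' Block (boxcar) paradigm
#'
#' Alternating OFF/ON boxcar stimulus, OFF phase first. The reference design
#' is 30 s OFF / 30 s ON at amplitude 1, sampled at 0.01 s, repeated for
#' 5 cycles (300 s).
#'
#' @param off_s OFF (rest) duration per cycle, seconds (> 0).
#' @param on_s ON (task) duration per cycle, seconds (>= 0; 0 gives an
#'   all-zero stimulus).
#' @param amplitude stimulus value during ON phases.
#' @param cycles number of OFF+ON cycles (>= 1).
#' @param te sampling interval, seconds.
#' @return A `bm_stimulus` tibble with columns `time`, `u`.
#' @examples
#' stim <- stim_block() # the reference 5-cycle block design
#' nrow(stim) # 30000 samples
#' @export
stim_block <- function(off_s = 30, on_s = 30, amplitude = 1, cycles = 5,
                       te = 0.01) {
  if (te <= 0 || off_s <= 0 || on_s < 0 || cycles < 1) {
    abort("need te > 0, off_s > 0, on_s >= 0, cycles >= 1")
  }
  if (te > off_s || (on_s > 0 && te > on_s)) {
    abort("te must not exceed a phase duration")
  }
  n_off <- n_samples(off_s, te)
  n_on <- n_samples(on_s, te)
  u <- rep(rep(c(0, amplitude), times = c(n_off, n_on)), as.integer(cycles))
  new_stimulus(u, te, "block",
               list(off_s = off_s, on_s = on_s, amplitude = amplitude,
                    cycles = as.integer(cycles), te = te))
}

#' Event-related paradigm
#'
#' Brief (typically 1-2 s) boxcar events at given onset times inside a total
#' window. Overlapping events saturate at `amplitude` (the stimulus is an OR
#' of boxcars, not a sum).
#'
#' @param event_s event duration, seconds.
#' @param onsets non-decreasing onset times, seconds, inside `[0, total_s)`;
#'   every event must end by `total_s`.
#' @param amplitude stimulus value during events.
#' @param total_s total duration, seconds.
#' @param te sampling interval, seconds.
#' @return A `bm_stimulus` tibble.
#' @examples
#' stim_event(1, onsets = c(10, 20), total_s = 60)
#' @export
stim_event <- function(event_s = 1, onsets = numeric(), amplitude = 1,
                       total_s = 60, te = 0.01) {
  if (te <= 0 || event_s <= 0 || total_s <= 0) {
    abort("need te, event_s, total_s > 0")
  }
  if (length(onsets) && is.unsorted(onsets)) abort("onsets must be non-decreasing")
  if (any(onsets < 0 | onsets >= total_s)) abort("onsets must lie in [0, total_s)")
  if (any(onsets + event_s > total_s + te / 2)) {
    abort("every event must fit inside total_s")
  }
  n <- n_samples(total_s, te)
  active <- logical(n)
  n_ev <- n_samples(event_s, te)
  for (on in onsets) {
    i0 <- as.integer(round(on / te)) + 1L
    active[i0:min(n, i0 + n_ev - 1L)] <- TRUE
  }
  new_stimulus(amplitude * active, te, "event_related",
               list(event_s = event_s, onsets = as.numeric(onsets),
                    amplitude = amplitude, total_s = total_s, te = te))
}

#' Mixed paradigm
#'
#' Bursts of closely spaced events separated by long rest periods, combining
#' block-like sustained structure with event-like transients. Each burst of
#' `events_per_burst` events (gaps of `intra_gap_s` between them) is preceded
#' by a rest block of `rest_s`.
#'
#' @param event_s single event duration, seconds.
#' @param events_per_burst events per burst (>= 1).
#' @param intra_gap_s gap between events within a burst, seconds.
#' @param rest_s rest period before each burst, seconds.
#' @param bursts number of bursts (>= 1).
#' @param amplitude stimulus value during events.
#' @param te sampling interval, seconds.
#' @return A `bm_stimulus` tibble.
#' @export
stim_mixed <- function(event_s = 1, events_per_burst = 3, intra_gap_s = 1,
                       rest_s = 30, bursts = 2, amplitude = 1, te = 0.01) {
  if (te <= 0 || event_s <= 0 || intra_gap_s <= 0 || rest_s <= 0 ||
      events_per_burst < 1 || bursts < 1) {
    abort("all durations must be positive; counts must be >= 1")
  }
  span <- events_per_burst * event_s + (events_per_burst - 1) * intra_gap_s
  onsets <- unlist(lapply(seq_len(bursts) - 1L, function(b) {
    start <- b * (rest_s + span) + rest_s
    start + (seq_len(events_per_burst) - 1L) * (event_s + intra_gap_s)
  }))
  total_s <- bursts * (rest_s + span)
  out <- stim_event(event_s, onsets, amplitude, total_s, te)
  attr(out, "paradigm") <- "mixed"
  attr(out, "meta") <- list(event_s = event_s,
                            events_per_burst = as.integer(events_per_burst),
                            intra_gap_s = intra_gap_s, rest_s = rest_s,
                            bursts = as.integer(bursts), amplitude = amplitude,
                            te = te)
  out
}

#' Add Gaussian measurement noise to a BOLD series
#'
#' Test-fixture helper: perturbs the `y` column with independent zero-mean
#' Gaussian noise. Deterministic for a fixed seed; the global RNG state is
#' left untouched.
#'
#' @param data a data frame with a numeric `y` column (e.g. a [simulate_bold()]
#'   result).
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return `data` with `y` replaced by the noisy series.
#' @export
bm_add_noise <- function(data, sigma, seed) {
  stopifnot(is.data.frame(data), "y" %in% names(data))
  if (!is.numeric(sigma) || sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(data)
  noise <- withr::with_seed(as.integer(seed), rnorm(nrow(data), 0, sigma))
  data$y <- data$y + noise
  data
}

#' Write / read a stimulus as delimited text
#'
#' Two-column tab-separated file (`time_s`, `u`) with a one-line header and a
#' JSON sidecar (`<path>.json`) holding the paradigm metadata.
#'
#' @param stim a `bm_stimulus`.
#' @param path output file path.
#' @return `path`, invisibly (write) or a `bm_stimulus` (read).
#' @export
bm_write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "bm_stimulus"))
  df <- data.frame(time_s = fmt17(stim$time), u = fmt17(stim$u))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(paradigm = attr(stim, "paradigm"), te = attr(stim, "te"),
         meta = attr(stim, "meta")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bm_write_stimulus
#' @export
bm_read_stimulus <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(paradigm = "custom", te = diff(df$time_s[1:2]), meta = list())
  new_stimulus(df$u, meta$te, meta$paradigm, meta$meta)
}

# fixed 17-significant-digit formatting so written tables are byte-stable
fmt17 <- function(x) sprintf("%.17g", x)
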