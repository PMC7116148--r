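# Synthetic LFP for SWR detection: pink-noise background on a detection
# and a reference channel sharing a common-mode component, with a
# ripple-band oscillatory burst inside each ground-truth SWR interval on
# the detection channel only.

pink_noise <- function(n, rate) {
  x <- fft(rnorm(n))
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)            # two-sided spectrum
  scale <- 1 / sqrt(pmax(f, 1))     # 1/f power below flattened at 1 Hz
  y <- Re(fft(x * scale, inverse = TRUE)) / n
  y / sd(y)
}

bandpass_filter <- function(x, rate, band) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Generate a synthetic LFP trace with planted ripple bursts
#'
#' Synthesizes, for each immobility epoch of the session, a detection
#' channel and a reference channel at `config$lfp_rate`. Both share a
#' common-mode pink-noise component (emulating muscle/line artifacts that
#' reference subtraction removes) plus independent pink noise. Inside each
#' ground-truth SWR interval, the detection channel additionally carries a
#' Hann-windowed oscillation at `config$swr_freq` whose amplitude is
#' `config$swr_snr` times the RMS of the ripple-band background of the
#' reference-subtracted noise.
#'
#' @param config a [synth_config()].
#' @param truth the `ground_truth` from [generate_session()].
#' @param epochs data.frame of immobility epochs (`day`, `start`, `end`,
#'   `context`), normally `session$epochs`. If `NULL`, spans are derived
#'   from the ground-truth events (2 s padding).
#' @return an `lfp_trace`: list of per-epoch segments, each with `t0`,
#'   `rate`, `lfp`, `ref`, `context`, `day`.
#' @export
generate_lfp <- function(config, truth, epochs = NULL) {
  if (config$swr_snr <= 0) stop_field("swr_snr", "must be > 0")
  rate <- config$lfp_rate
  if (is.null(epochs)) {
    ev <- truth$swr_events
    if (nrow(ev) == 0L) stop("no epochs given and no ground-truth events to derive them from")
    epochs <- do.call(rbind, lapply(split(ev, ev$day), function(d) {
      data.frame(day = d$day[1L], start = min(d$start) - 2,
                 end = max(d$end) + 2, context = d$context[1L])
    }))
  }
  set.seed(derive_seed(config$seed, 101L))
  segs <- vector("list", nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    ep <- epochs[i, ]
    n <- round((ep$end - ep$start) * rate)
    tt <- ep$start + seq_len(n) / rate
    common <- 0.7 * pink_noise(n, rate)
    idio1 <- pink_noise(n, rate)
    idio2 <- pink_noise(n, rate)
    bg_rms <- sd(bandpass_filter(idio1 - idio2, rate, config$swr_band))
    lfp <- common + idio1
    ev <- truth$swr_events
    ev <- ev[ev$start >= ep$start & ev$end <= ep$end, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      sel <- which(tt >= ev$start[j] & tt < ev$end[j])
      if (!length(sel)) next
      ph <- (tt[sel] - ev$start[j])
      env <- 0.5 * (1 - cos(2 * pi * ph / (ev$end[j] - ev$start[j])))
      lfp[sel] <- lfp[sel] +
        config$swr_snr * bg_rms * env * sin(2 * pi * config$swr_freq * ph)
    }
    segs[[i]] <- list(t0 = ep$start, rate = rate, lfp = lfp,
                      ref = common + idio2, context = ep$context, day = ep$day)
  }
  structure(list(segments = segs, rate = rate, band = config$swr_band),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  dur <- sum(vapply(x$segments, function(s) length(s$lfp) / s$rate, 1))
  cat(sprintf("<lfp_trace> %d segments, %.0f s at %g Hz\n",
              length(x$segments), dur, x$rate))
  invisible(x)
}
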