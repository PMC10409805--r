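## Assembly of single-beat P waves and QRST complexes into 10 s, 500 Hz
## 12-lead records: conditional-Gaussian amplitude/interval coupling,
## sigmoid connectors, a power-law heart-rate-variability model, beat-wise
## QT warping, TP segments, composite noise and bandpass filtering.

#' Closed-form Gaussian conditioning on a feature block
#'
#' For a block with mean `mu`, standard deviations `sd` and correlation
#' matrix `cor`, returns the conditional mean and covariance of the
#' `target` components given the `given` components.
#'
#' @param block List with `mean`, `sd`, `cor` (see
#'   [default_synth_config()]).
#' @param given Named numeric vector of conditioning values.
#' @param target Names of the components to condition.
#' @return List with `mean` and `cov` of the conditional distribution.
#' @export
conditional_gaussian <- function(block, given, target) {
  nm <- names(block$mean)
  S <- diag(block$sd, length(block$sd)) %*% block$cor %*%
    diag(block$sd, length(block$sd))
  dimnames(S) <- list(nm, nm)
  g <- names(given)
  mu_t <- block$mean[target]
  if (!length(g)) return(list(mean = mu_t, cov = S[target, target, drop = FALSE]))
  S_gg <- S[g, g, drop = FALSE]
  S_tg <- S[target, g, drop = FALSE]
  w <- S_tg %*% solve(S_gg)
  mean_c <- mu_t + drop(w %*% (given - block$mean[g]))
  cov_c <- S[target, target, drop = FALSE] - w %*% t(S_tg)
  list(mean = mean_c, cov = cov_c)
}

.draw_gaussian <- function(mean, cov, n = 1) {
  L <- chol(cov + diag(1e-12, nrow(cov)))
  drop(matrix(stats::rnorm(n * length(mean)), n) %*% L) + mean
}

#' Scale a QRST beat against a P wave via conditional Gaussian coupling
#'
#' Measures the lead-II P amplitude, draws a target R-peak amplitude from
#' the conditional Gaussian `R | P` of the amplitude block, and applies
#' one global scale factor to all twelve QRST leads so the lead-II R peak
#' meets the target. Non-positive draws are rejected and redrawn above
#' the configured floor.
#'
#' @param qrst,pwave `beat_ecg12` objects.
#' @param config `synth_config`.
#' @return The scaled `beat_ecg12`; the applied factor and target are in
#'   attributes `scale` and `r_target`.
#' @export
scale_qrst <- function(qrst, pwave, config = default_synth_config()) {
  p <- max(pwave$signal["II", ])
  if (!(p > 0)) stop("lead-II P amplitude not measurable")
  cg <- conditional_gaussian(config$mvn$A, c(P_amp = p), "R_amp")
  r_target <- -Inf
  for (i in 1:100) {
    r_target <- .draw_gaussian(cg$mean, cg$cov)
    if (r_target >= config$r_amp_floor) break
  }
  r_target <- max(r_target, config$r_amp_floor)
  ## R peak measured inside the QRS window when fiducials are available
  qwin <- seq_len(ncol(qrst$signal))
  if (!is.null(qrst$fiducials$QRS_on)) {
    dtq <- 1000 / qrst$fs
    qwin <- max(round(qrst$fiducials$QRS_on / dtq), 1):
      min(round(qrst$fiducials$QRS_off / dtq) + 1, ncol(qrst$signal))
  }
  ## dominant QRS deflection magnitude (what a delineator reports as the
  ## R peak when the R wave leads; bounded for S-dominant morphologies)
  r_now <- max(abs(qrst$signal["II", qwin]))
  fac <- r_target / r_now
  qrst$signal <- qrst$signal * fac
  attr(qrst, "scale") <- fac
  attr(qrst, "r_target") <- r_target
  qrst
}

#' Sample a PQ interval consistent with the P-wave duration
#'
#' Conditional draw `PQ | P_dur` from the interval block, rejected until
#' `PQ >= p_dur` (the connector length must be non-negative) and, for
#' first-degree AV block, until `PQ > 200` ms.
#'
#' @param p_dur Simulated P-wave duration, ms.
#' @param config `synth_config`.
#' @param avb Logical: sample from the AV-block range (> 200 ms).
#' @param max_draws Rejection budget.
#' @return PQ interval, ms.
#' @export
sample_pq <- function(p_dur, config = default_synth_config(), avb = FALSE,
                      max_draws = 1000) {
  stopifnot(p_dur > 0)
  cg <- conditional_gaussian(config$mvn$B, c(P_dur = p_dur), "PQ_int")
  lo <- if (avb) max(p_dur + 16, config$avb_pq_min) else p_dur + 16
  for (i in seq_len(max_draws)) {
    pq <- .draw_gaussian(cg$mean, cg$cov)
    if (avb) pq <- config$avb_pq_min + abs(pq - config$avb_pq_min)
    if (pq > lo) return(pq)
  }
  stop("PQ rejection budget exhausted (p_dur = ", round(p_dur, 1), " ms)")
}

## Logistic connector with exact endpoints; 1-99 percent transition
## spanning the segment.
.sigmoid_segment <- function(from, to, n) {
  if (n <= 0) return(matrix(numeric(0), length(from), 0))
  if (n == 1) return(cbind((from + to) / 2))
  u <- seq(0, 1, length.out = n + 2)[2:(n + 1)]
  s <- 1 / (1 + exp(-2 * log(99) * (u - 0.5)))
  s <- (s - min(s)) / (max(s) - min(s) + 1e-300)
  outer(to - from, s) + from
}

#' Concatenate a P wave and a scaled QRST into one full beat
#'
#' Joins the P segment (up to its offset) and the QRST segment (from QRS
#' onset) with a per-lead logistic connector whose length is the PQ
#' interval minus the P-wave duration; endpoints match the segment
#' boundary amplitudes exactly.
#'
#' @param pwave,qrst `beat_ecg12` objects at the same sampling rate.
#' @param pq PQ interval, ms (>= P duration).
#' @return A `beat_ecg12` covering P through T with propagated fiducials
#'   (`P_on`, `P_off`, `QRS_on`, `QRS_off`, `T_off` in beat time, ms).
#' @export
concat_beat <- function(pwave, qrst, pq) {
  stopifnot(pwave$fs == qrst$fs)
  fs <- pwave$fs
  dt <- 1000 / fs
  pf <- pwave$fiducials; qf <- qrst$fiducials
  p_dur <- pf$P_off - pf$P_on
  if (pq < p_dur - 1e-9) stop("PQ shorter than the P-wave duration")
  ## keep a short post-fiducial tail so each segment decays to rest
  ip_end <- max(round((pf$P_off + 15) / dt) + 1, 2)
  ip_end <- min(ip_end, ncol(pwave$signal))
  p_seg <- pwave$signal[, seq_len(ip_end), drop = FALSE]
  iq_on <- max(round(qf$QRS_on / dt) + 1, 1)
  iq_end <- min(round((qf$T_off + 40) / dt) + 1, ncol(qrst$signal))
  q_seg <- qrst$signal[, iq_on:iq_end, drop = FALSE]
  p_tail <- (ip_end - 1) * dt - pf$P_off
  n_conn <- max(round((pq - p_dur - p_tail) / dt), 0)
  conn <- .sigmoid_segment(p_seg[, ncol(p_seg)], q_seg[, 1], n_conn)
  sig <- cbind(p_seg, conn, q_seg)
  t_qrs_on <- (ncol(p_seg) + n_conn) * dt
  fid <- list(P_on = pf$P_on, P_off = pf$P_off,
              QRS_on = t_qrs_on,
              QRS_off = t_qrs_on + (qf$QRS_off - qf$QRS_on),
              T_off = t_qrs_on + (qf$T_off - qf$QRS_on))
  structure(list(signal = sig, fs = fs, fiducials = fid),
            class = "beat_ecg12")
}

#' Generate a long-range-correlated RR interval series
#'
#' Spectral synthesis of a Gaussian series with a `1/f^beta` power-law
#' spectrum, standardized, scaled to the requested SDNN and shifted to
#' the mean RR interval implied by the mean heart rate.
#'
#' @param mean_hr Mean heart rate, bpm.
#' @param n_beats Number of intervals.
#' @param beta Spectral exponent (1 = pink fluctuations).
#' @param sdnn Standard deviation of the intervals, ms.
#' @return Numeric RR series, ms.
#' @export
generate_rr_series <- function(mean_hr, n_beats, beta = 1, sdnn = 30) {
  mean_rr <- 60000 / mean_hr
  if (sdnn <= 0) return(rep(mean_rr, n_beats))
  n <- 2^ceiling(log2(max(n_beats, 64)))
  f <- seq_len(n / 2)
  amp <- f^(-beta / 2)
  phase <- stats::runif(n / 2, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, Conj(rev(spec[-(n / 2)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n_beats)]
  x <- (x - mean(x)) / stats::sd(x)
  mean_rr + sdnn * x
}

#' Warp the T-wave segment of a beat to a target QT interval
#'
#' Draws a QT target from the conditional Gaussian
#' `QT | (QRS_dur, RR)` of the interval block, then linearly time-warps
#' only the `[QRS_off, T_off]` segment (resampling) so the beat's QT
#' interval meets the target; P and QRS segments are untouched.
#'
#' @param beat Full `beat_ecg12` (from [concat_beat()]).
#' @param rr_target RR interval for this beat, ms.
#' @param config `synth_config`.
#' @param qt_target Optional explicit QT target (skips the draw).
#' @return The warped `beat_ecg12`.
#' @export
stretch_beat <- function(beat, rr_target, config = default_synth_config(),
                         qt_target = NULL) {
  fid <- beat$fiducials
  fs <- beat$fs; dt <- 1000 / fs
  qrs_dur <- fid$QRS_off - fid$QRS_on
  if (is.null(qt_target)) {
    cg <- conditional_gaussian(config$mvn$C,
                               c(QRS_dur = qrs_dur, RR_int = rr_target),
                               "QT_int")
    for (i in 1:100) {
      qt_target <- .draw_gaussian(cg$mean, cg$cov)
      if (qt_target > qrs_dur + 60) break
    }
    qt_target <- max(qt_target, qrs_dur + 60)
  }
  ## the warped beat must fit its RR slot (head + QT + tail + margin)
  qt_target <- min(qt_target, rr_target - fid$QRS_on - 90)
  qt_target <- max(qt_target, qrs_dur + 40)
  i_qoff <- round(fid$QRS_off / dt) + 1
  i_toff <- min(round(fid$T_off / dt) + 1, ncol(beat$signal))
  head_seg <- beat$signal[, seq_len(i_qoff - 1), drop = FALSE]
  t_seg <- beat$signal[, i_qoff:i_toff, drop = FALSE]
  tail_seg <- if (i_toff < ncol(beat$signal)) {
    beat$signal[, (i_toff + 1):ncol(beat$signal), drop = FALSE]
  } else matrix(numeric(0), 12, 0)
  n_now <- ncol(t_seg)
  n_new <- max(round((qt_target - (fid$QRS_off - fid$QRS_on)) / dt), 3)
  if (n_new != n_now && n_now >= 2) {
    t_new <- apply(t_seg, 1, function(row) {
      stats::approx(seq_len(n_now), row, n = n_new)$y
    })
    t_seg <- t(t_new)
  }
  beat$signal <- cbind(head_seg, t_seg)
  beat$fiducials$T_off <- fid$QRS_off + (ncol(t_seg) - 1) * dt
  if (ncol(tail_seg)) beat$signal <- cbind(beat$signal, tail_seg)
  beat
}

#' Assemble warped beats into a raw fixed-length record
#'
#' Places each beat at its cumulative RR onset and fills the TP gaps with
#' per-lead logistic segments joining the last beat sample to the next
#' beat's first sample; the result is truncated to exactly
#' `fs * record_s` samples.
#'
#' @param beats List of full `beat_ecg12` (one per RR interval).
#' @param rr RR series, ms (same length as `beats`).
#' @param config `synth_config`.
#' @return List: `signal` (12 x 5000 raw, mV), `fiducials` (data.frame
#'   of per-beat ground truth in record time, ms), `fs`.
#' @export
assemble_record <- function(beats, rr, config = default_synth_config()) {
  fs <- config$fs; dt <- 1000 / fs
  n_out <- config$fs * config$record_s
  sig <- matrix(NA_real_, 12, n_out + 2000)
  fid_rows <- list()
  pos <- 1L   # next free sample
  onset <- 0
  for (k in seq_along(beats)) {
    b <- beats[[k]]
    nb <- ncol(b$signal)
    if (nb * dt > rr[k] && k < length(beats)) {
      stop("beat ", k, " (", round(nb * dt), " ms) longer than its RR slot (",
           round(rr[k]), " ms)")
    }
    i_on <- round(onset / dt) + 1L
    if (i_on > pos) {
      ## TP sigmoid from the last placed sample to this beat's first
      from <- if (pos > 1) sig[, pos - 1] else b$signal[, 1]
      sig[, pos:(i_on - 1)] <- .sigmoid_segment(from, b$signal[, 1],
                                                i_on - pos)
    }
    sig[, i_on:(i_on + nb - 1)] <- b$signal
    pos <- i_on + nb
    fid_rows[[k]] <- data.frame(
      beat = k, onset = onset,
      P_on = onset + b$fiducials$P_on, P_off = onset + b$fiducials$P_off,
      QRS_on = onset + b$fiducials$QRS_on,
      QRS_off = onset + b$fiducials$QRS_off,
      T_off = onset + b$fiducials$T_off, rr = rr[k]
    )
    onset <- onset + rr[k]
    if (i_on > n_out) break
  }
  if (pos <= n_out) {
    sig[, pos:(n_out + 1)] <- sig[, pos - 1]
    pos <- n_out + 2
  }
  list(signal = sig[, seq_len(n_out), drop = FALSE],
       fiducials = do.call(rbind, fid_rows), fs = fs)
}

#' Superimpose realistic composite ECG noise at a chosen SNR
#'
#' Builds three noise components in electrode space (baseline wander
#' below 0.5 Hz, sparse electrode-movement transients, band-limited
#' motion artifact), combines them through the lead derivation so the
#' twelve leads carry correlated noise, and scales the mixture so the
#' measured signal-to-noise ratio equals `snr_db` exactly.
#'
#' @param raw 12 x T raw signal matrix, mV.
#' @param snr_db Target SNR, dB.
#' @param fs Sampling rate, Hz.
#' @return List: `noisy` (12 x T), `noise` (12 x T), `snr_db`.
#' @export
add_noise <- function(raw, snr_db, fs = 500) {
  nt <- ncol(raw)
  p_sig <- mean(raw^2)
  if (p_sig <= 0) stop("zero-power signal")
  if (!is.finite(snr_db) || snr_db >= 100) {
    return(list(noisy = raw, noise = raw * 0, snr_db = Inf))
  }
  t <- (seq_len(nt) - 1) / fs
  el_names <- c("RA", "LA", "LL", paste0("V", 1:6))
  noise_el <- matrix(0, 9, nt, dimnames = list(el_names, NULL))
  bp_lo <- signal::butter(2, min(10 / (fs / 2), 0.99), "low")
  for (e in 1:9) {
    ## baseline wander: slow sinusoids + low-passed random walk
    bw <- 0
    for (j in 1:3) {
      f0 <- stats::runif(1, 0.05, 0.45)
      bw <- bw + stats::runif(1, 0.3, 1) * sin(2 * pi * f0 * t +
                                                 stats::runif(1, 0, 2 * pi))
    }
    walk <- cumsum(stats::rnorm(nt)) / sqrt(nt)
    ## electrode movement: a few abrupt decaying transients
    em <- numeric(nt)
    for (j in seq_len(stats::rpois(1, 2))) {
      i0 <- sample.int(nt, 1)
      tau <- stats::runif(1, 0.05, 0.3) * fs
      len <- min(nt - i0 + 1, round(6 * tau))
      em[i0:(i0 + len - 1)] <- em[i0:(i0 + len - 1)] +
        stats::rnorm(1) * exp(-(seq_len(len) - 1) / tau)
    }
    ## motion artifact: band-limited stochastic component
    ma <- as.numeric(signal::filtfilt(bp_lo, stats::rnorm(nt)))
    noise_el[e, ] <- 0.6 * bw + 0.4 * walk + 0.8 * em + 0.5 * ma
  }
  nb <- derive_leads(noise_el, fs = fs)
  nmat <- nb$signal
  p_noise <- mean(nmat^2)
  alpha <- sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  nmat <- nmat * alpha
  list(noisy = raw + nmat, noise = nmat, snr_db = snr_db)
}

#' Butterworth bandpass for the filtered record variant
#'
#' Third-order Butterworth high-pass at 0.5 Hz and low-pass at 150 Hz,
#' applied zero-phase (forward-backward) so the ground-truth fiducials
#' remain aligned.
#'
#' @param x 12 x T signal matrix, mV.
#' @param fs Sampling rate, Hz.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs = 500) {
  hp <- signal::butter(3, 0.5 / (fs / 2), "high")
  lp <- signal::butter(3, min(150 / (fs / 2), 0.999), "low")
  out <- t(apply(x, 1, function(row) {
    as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, row)))
  }))
  dimnames(out) <- dimnames(x)
  out
}
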