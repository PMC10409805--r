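## Delineation and feature extraction: R-peak detection by derivative
## energy, threshold-based wave onset/offset search, the 11-feature by
## 12-lead table, and cohort distribution summaries.

.movavg <- function(x, n) {
  as.numeric(stats::filter(x, rep(1 / n, n), sides = 2, circular = TRUE))
}

## Scan from `from` toward `to` until |x - iso| stays below `th` for
## `sustain` consecutive samples; returns the first such index (or the
## boundary).
.scan_edge <- function(x, from, to, th, iso, sustain = 3L) {
  stp <- if (to >= from) 1L else -1L
  run <- 0L
  i <- from
  while (i != to) {
    if (abs(x[i] - iso) <= th) {
      run <- run + 1L
      if (run >= sustain) return(i - stp * (sustain - 1L))
    } else run <- 0L
    i <- i + stp
  }
  NA_integer_   # no sustained crossing inside the window
}

#' Delineate one ECG channel
#'
#' Detects R peaks from the smoothed derivative energy of a 5-25 Hz
#' bandpassed copy, then searches slope/threshold windows around each
#' beat for QRS onset/offset, the P wave and the T wave. Undetected
#' fiducials are reported as `NA` rather than fabricated; an empty
#' signal yields an empty set.
#'
#' @param x Numeric signal vector, mV.
#' @param fs Sampling rate, Hz.
#' @return Data frame, one row per detected beat: times in ms
#'   (`P_on`, `P_peak`, `P_off`, `QRS_on`, `Q_peak`, `R_peak`, `S_peak`,
#'   `QRS_off`, `T_peak`, `T_off`) and amplitudes in mV
#'   (`P_amp`, `Q_amp`, `R_amp`, `S_amp`, `T_amp`).
#' @export
delineate <- function(x, fs = 500) {
  empty <- data.frame(P_on = numeric(0), P_peak = numeric(0),
                      P_off = numeric(0), QRS_on = numeric(0),
                      Q_peak = numeric(0), R_peak = numeric(0),
                      S_peak = numeric(0), QRS_off = numeric(0),
                      T_peak = numeric(0), T_off = numeric(0),
                      P_amp = numeric(0), Q_amp = numeric(0),
                      R_amp = numeric(0), S_amp = numeric(0),
                      T_amp = numeric(0))
  nt <- length(x)
  if (nt < 2 * fs || max(x) - min(x) < 1e-9) return(empty)
  dt <- 1000 / fs
  bp <- signal::butter(2, c(5, 25) / (fs / 2), "pass")
  xf <- as.numeric(signal::filtfilt(bp, x))
  e <- .movavg(xf^2, max(round(0.03 * fs), 3))
  ## raw derivative energy localizes QRS bounds more sharply
  ed <- .movavg(c(0, diff(x))^2, max(round(0.01 * fs), 2))
  thr <- 0.15 * max(e)
  refr <- round(0.3 * fs)
  peaks <- integer(0)
  ew <- e
  while (TRUE) {
    i <- which.max(ew)
    if (ew[i] < thr) break
    peaks <- c(peaks, i)
    ew[max(1, i - refr):min(nt, i + refr)] <- -Inf
  }
  if (!length(peaks)) return(empty)
  peaks <- sort(peaks)
  rows <- lapply(seq_along(peaks), function(b) {
    pk <- peaks[b]
    nxt <- if (b < length(peaks)) peaks[b + 1] else nt + round(0.5 * fs)
    w <- max(1, pk - round(0.06 * fs)):min(nt, pk + round(0.06 * fs))
    r_i <- w[which.max(abs(x[w]))]
    ## prefer the signed R peak when the positive deflection is comparable
    r_pos <- w[which.max(x[w])]
    if (x[r_pos] > 0.5 * abs(x[r_i])) r_i <- r_pos
    ## QRS bounds: sustained drop of the raw derivative-energy envelope
    bw_q <- max(1, pk - round(0.13 * fs)):min(nt, pk + round(0.13 * fs))
    ed_pk <- max(ed[bw_q])
    ## asymmetric thresholds: the onset side must clear the PQ-segment
    ## slope, the offset side must keep weak terminal forces
    lo <- r_i; run <- 0L
    while (lo > bw_q[1]) {
      if (ed[lo] <= 0.02 * ed_pk) {
        run <- run + 1L; if (run >= 4L) break
      } else run <- 0L
      lo <- lo - 1L
    }
    lo <- min(lo + max(run - 1L, 0L), r_i)
    hi <- r_i; run <- 0L
    while (hi < bw_q[length(bw_q)]) {
      if (ed[hi] <= 0.004 * ed_pk) {
        run <- run + 1L; if (run >= 4L) break
      } else run <- 0L
      hi <- hi + 1L
    }
    hi <- max(hi - max(run - 1L, 0L), r_i)
    q_w <- max(1, lo):r_i
    s_w <- r_i:min(nt, hi)
    q_i <- q_w[which.min(x[q_w])]
    s_i <- s_w[which.min(x[s_w])]
    ## isoelectric baseline: the TP level dominates the record median
    iso <- stats::median(x)
    ## P wave in the pre-QRS window
    p_w <- max(1, lo - round(0.34 * fs)):max(1, lo - round(0.01 * fs))
    p_on <- p_peak <- p_off <- p_amp <- NA_real_
    if (length(p_w) > 5) {
      dev <- x[p_w] - iso
      p_i <- p_w[which.max(abs(dev))]
      p_amp <- x[p_i] - iso
      ## a genuine P wave is small next to the QRS; anything comparable
      ## is QRS spillover into the search window
      qrs_dom <- max(abs(x[r_i] - iso), abs(x[q_i] - iso),
                     abs(x[s_i] - iso))
      if (abs(p_amp) > 0.5 * qrs_dom) p_amp <- NA_real_
      if (!is.na(p_amp) && abs(p_amp) > 0.02) {
        th_p <- 0.05 * abs(p_amp)
        on_i <- .scan_edge(x, p_i, max(p_w[1], p_i - round(0.12 * fs)),
                           th_p, iso, 4L)
        if (!is.na(on_i)) p_on <- (on_i - 1) * dt
        ## offset: the bottom of the dip between the P end and the PQ
        ## segment (threshold crossings are unreliable when the PQ
        ## segment ramps straight into the QRS)
        off_end <- min(p_w[length(p_w)], p_i + round(0.14 * fs))
        i <- p_i
        while (i < off_end) {
          dev_i <- abs(x[i] - iso)
          if (dev_i < 0.2 * abs(p_amp) && abs(x[i + 1] - iso) >= dev_i) break
          i <- i + 1L
        }
        if (i < off_end) p_off <- (i - 1) * dt
        p_peak <- (p_i - 1) * dt
      } else p_amp <- NA_real_
    }
    ## T wave between this QRS and the next beat's P window
    t_w0 <- min(nt, hi + round(0.04 * fs))
    t_w1 <- min(nt, min(hi + round(0.45 * fs), nxt - round(0.30 * fs)))
    t_peak <- t_off <- t_amp <- NA_real_
    if (t_w1 - t_w0 > 10) {
      t_w <- t_w0:t_w1
      dev <- x[t_w] - iso
      t_i <- t_w[which.max(abs(dev))]
      t_amp <- x[t_i] - iso
      if (abs(t_amp) > 0.02) {
        th_t <- 0.035 * abs(t_amp)
        off_i <- .scan_edge(x, t_i, t_w1, th_t, iso, 4L)
        t_peak <- (t_i - 1) * dt
        if (!is.na(off_i)) t_off <- (off_i - 1) * dt
      } else t_amp <- NA_real_
    }
    data.frame(
      P_on = p_on, P_peak = p_peak, P_off = p_off,
      QRS_on = (lo - 1) * dt, Q_peak = (q_i - 1) * dt,
      R_peak = (r_i - 1) * dt, S_peak = (s_i - 1) * dt,
      QRS_off = (hi - 1) * dt, T_peak = t_peak, T_off = t_off,
      P_amp = p_amp, Q_amp = x[q_i] - iso, R_amp = x[r_i] - iso,
      S_amp = x[s_i] - iso, T_amp = t_amp
    )
  })
  do.call(rbind, rows)
}

#' Delineate all 12 leads of a record
#'
#' @param record An `ecg_record` or 12 x T matrix.
#' @param variant Signal variant for records.
#' @param fs Sampling rate, Hz.
#' @return Named list of per-lead delineation data frames.
#' @export
delineate_record <- function(record, variant = "raw", fs = NULL) {
  sig <- if (inherits(record, "ecg_record")) record[[variant]] else record
  if (is.null(fs)) fs <- if (inherits(record, "ecg_record")) record$fs else 500
  out <- lapply(seq_len(nrow(sig)), function(i) delineate(sig[i, ], fs))
  names(out) <- rownames(sig)
  if (is.null(names(out))) names(out) <- LEAD_NAMES
  out
}

#' Cross-lead consensus fiducials
#'
#' Combines per-lead delineations into one global fiducial set per beat:
#' beats are paired across leads by nearest QRS onset, onsets (`P_on`,
#' `QRS_on`) take the earliest detection over leads and offsets
#' (`P_off`, `QRS_off`, `T_off`) the latest, the multi-lead convention
#' for global wave boundaries.
#'
#' @param delineation Output of [delineate_record()].
#' @param ref_lead Lead whose beats anchor the pairing.
#' @param tol_ms Maximum QRS-onset distance for cross-lead pairing, ms.
#' @return Data frame with one row per anchor beat.
#' @export
global_fiducials <- function(delineation, ref_lead = "II", tol_ms = 150) {
  anchor <- delineation[[ref_lead]]
  if (is.null(anchor) || !nrow(anchor)) {
    anchor <- delineation[[which.max(vapply(delineation, nrow, 0L))]]
  }
  if (is.null(anchor) || !nrow(anchor)) {
    return(data.frame(P_on = numeric(0), P_off = numeric(0),
                      QRS_on = numeric(0), QRS_off = numeric(0),
                      T_off = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(anchor)), function(j) {
    ref_on <- anchor$QRS_on[j]
    beat_rows <- lapply(delineation, function(d) {
      if (!nrow(d)) return(NULL)
      i <- which.min(abs(d$QRS_on - ref_on))
      if (abs(d$QRS_on[i] - ref_on) > tol_ms) return(NULL)
      d[i, ]
    })
    beat_rows <- Filter(Negate(is.null), beat_rows)
    ## per wave, trust only the leads where that wave is prominent
    pick <- function(f, fun, amp_field = NULL, rel = 0.5) {
      vals <- vapply(beat_rows, function(r) r[[f]], numeric(1))
      if (!is.null(amp_field)) {
        amps <- abs(vapply(beat_rows, function(r) r[[amp_field]],
                           numeric(1)))
        amps[is.na(amps)] <- 0
        strong <- amps >= rel * max(amps, na.rm = TRUE)
        vals <- vals[strong]
      }
      vals <- vals[!is.na(vals)]
      if (!length(vals)) NA_real_ else fun(vals)
    }
    qrs_amp <- function(r) max(abs(r$R_amp), abs(r$S_amp), na.rm = TRUE)
    qamps <- vapply(beat_rows, qrs_amp, numeric(1))
    for (k in seq_along(beat_rows)) beat_rows[[k]]$.qrs_amp <- qamps[k]
    data.frame(
      P_on = pick("P_on", min),
      P_off = pick("P_off", max, "P_amp"),
      QRS_on = pick("QRS_on", min, ".qrs_amp", 0.4),
      QRS_off = pick("QRS_off", max, ".qrs_amp", 0.4),
      T_off = pick("T_off", max)
    )
  })
  do.call(rbind, rows)
}

#' The 11 extracted feature names (6 timing, 5 amplitude)
#' @export
FEATURE_NAMES <- c("Pdur", "QRSdur", "Tdur", "PQint", "QTint", "RRint",
                   "Pamp", "Qamp", "Ramp", "Samp", "Tamp")

#' Extract the 11-feature table per lead
#'
#' Six timing features (P-wave duration, QRS duration, T-wave duration,
#' PQ, QT and RR intervals, ms) and five amplitude features (P, Q, R, S,
#' T peak amplitudes relative to the isoelectric baseline, mV),
#' beat-averaged per lead.
#'
#' @param record An `ecg_record` or 12 x T matrix.
#' @param delineation Optional precomputed [delineate_record()] output.
#' @param variant Signal variant for records.
#' @return Data frame: 12 rows (leads) x 11 feature columns plus `lead`.
#' @export
extract_features <- function(record, delineation = NULL, variant = "raw") {
  if (is.null(delineation)) delineation <- delineate_record(record, variant)
  rows <- lapply(names(delineation), function(ld) {
    d <- delineation[[ld]]
    avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    rr <- if (nrow(d) >= 2) mean(diff(d$R_peak)) else NA_real_
    data.frame(
      lead = ld,
      Pdur = avg(d$P_off - d$P_on),
      QRSdur = avg(d$QRS_off - d$QRS_on),
      Tdur = avg(d$T_off - d$QRS_off),
      PQint = avg(d$QRS_on - d$P_on),
      QTint = avg(d$T_off - d$QRS_on),
      RRint = rr,
      Pamp = avg(d$P_amp), Qamp = avg(d$Q_amp), Ramp = avg(d$R_amp),
      Samp = avg(d$S_amp), Tamp = avg(d$T_amp)
    )
  })
  do.call(rbind, rows)
}

#' Summarize feature tables over a cohort
#'
#' Per feature and lead: mean, standard deviation and a Gaussian kernel
#' density estimate on a fixed grid (a bandwidth floor keeps degenerate
#' samples finite).
#'
#' @param tables List of [extract_features()] data frames (n >= 2).
#' @param n_grid Density grid size.
#' @return List of class `feature_summary`: `stats` (data.frame lead,
#'   feature, mu, sigma, n) and `density` (named list of
#'   `density` objects, keys `lead.feature`).
#' @export
summarize_features <- function(tables, n_grid = 128) {
  if (length(tables) < 2) stop("need at least 2 feature tables")
  leads <- tables[[1]]$lead
  stats_rows <- list(); dens <- list()
  for (ld in leads) {
    for (ft in FEATURE_NAMES) {
      vals <- vapply(tables, function(tb) tb[tb$lead == ld, ft], numeric(1))
      vals <- vals[is.finite(vals)]
      mu <- if (length(vals)) mean(vals) else NA_real_
      sg <- if (length(vals) >= 2) stats::sd(vals) else NA_real_
      stats_rows[[paste(ld, ft)]] <- data.frame(
        lead = ld, feature = ft, mu = mu, sigma = sg, n = length(vals))
      if (length(vals) >= 2) {
        bw <- max(stats::bw.nrd0(vals), 1e-6 * max(abs(vals), 1))
        dens[[paste(ld, ft, sep = ".")]] <-
          stats::density(vals, bw = bw, n = n_grid)
      }
    }
  }
  structure(list(stats = do.call(rbind, stats_rows), density = dens),
            class = "feature_summary")
}

#' Write / read a feature summary in the features-by-leads CSV layout
#'
#' Rows are features (mu and sigma per feature), columns are the twelve
#' leads; round-trips through [read_feature_summary()].
#'
#' @param summary A `feature_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_summary <- function(summary, path) {
  st <- summary$stats
  leads <- unique(st$lead)
  out <- data.frame(row = character(0))
  rows <- list()
  for (ft in unique(st$feature)) {
    mu <- vapply(leads, function(ld) st$mu[st$lead == ld & st$feature == ft],
                 numeric(1))
    sg <- vapply(leads, function(ld) {
      st$sigma[st$lead == ld & st$feature == ft]
    }, numeric(1))
    rows[[paste0(ft, "_mu")]] <- c(list(row = paste0(ft, "_mu")),
                                   as.list(mu))
    rows[[paste0(ft, "_sigma")]] <- c(list(row = paste0(ft, "_sigma")),
                                      as.list(sg))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out) <- c("feature", leads)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_summary
#' @export
read_feature_summary <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
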