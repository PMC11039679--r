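# Independent brute-force oracles and fixture builders used across tests.

# Exhaustive episode scan: walks the series frame by frame with an explicit
# state machine, checking every candidate run directly against the
# hysteresis/persistence definitions. Kept deliberately simple and separate
# from the package's implementation.
bf_episodes <- function(foxo, t_h, hi, lo, pers) {
  n <- length(foxo)
  valid <- which(!is.na(foxo))
  if (!length(valid)) {
    return(data.frame(entry_time = numeric(0), exit_time = numeric(0)))
  }
  last_obs <- max(valid)
  is_hi_run <- function(i) {
    if (i + pers - 1L > n) return(FALSE)
    vals <- foxo[i:(i + pers - 1L)]
    all(!is.na(vals) & vals >= hi)
  }
  is_lo_run <- function(i) {
    if (i + pers - 1L > n) return(FALSE)
    vals <- foxo[i:(i + pers - 1L)]
    all(!is.na(vals) & vals <= lo)
  }
  entries <- numeric(0); exits <- numeric(0)
  i <- 1L
  while (i <= last_obs) {
    if (is_hi_run(i)) {
      entries <- c(entries, t_h[i])
      j <- i + 1L
      exit_found <- FALSE
      while (j <= last_obs) {
        if (is_lo_run(j)) {
          exits <- c(exits, t_h[j])
          exit_found <- TRUE
          i <- j + 1L
          break
        }
        j <- j + 1L
      }
      if (!exit_found) {
        exits <- c(exits, NA_real_)
        break
      }
    } else {
      i <- i + 1L
    }
  }
  data.frame(entry_time = entries, exit_time = exits)
}

# Exhaustive onset scan per the baseline + MAD rule.
bf_onset <- function(p53, t_h, mad_mult, run_len, floor_rel, after = 0) {
  base <- median(p53[1:3])
  base_mad <- median(abs(p53[1:3] - base))
  cut <- base + max(mad_mult * base_mad, floor_rel * base)
  n <- length(p53)
  for (i in seq_len(n - run_len + 1L)) {
    vals <- p53[i:(i + run_len - 1L)]
    if (t_h[i] >= after && all(!is.na(vals) & vals > cut)) return(t_h[i])
  }
  NA_real_
}

# Double-loop sample autocorrelation.
bf_acf <- function(x, max_lag) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  sapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(length(x) - k)) s <- s + xc[t] * xc[t + k]
    s / denom
  })
}

# Random noisy step traces for oracle-equality tests.
random_trace <- function(n_frames = 40, dt = 1 / 3) {
  t_h <- seq(0, by = dt, length.out = n_frames)
  base <- runif(1, 0.05, 0.35)
  f <- rep(base, n_frames)
  if (runif(1) < 0.8) {
    on <- sample.int(n_frames - 6, 1)
    off <- min(n_frames, on + sample.int(15, 1) + 2)
    f[on:off] <- runif(1, 0.6, 0.95)
  }
  f <- pmin(1, pmax(0, f + rnorm(n_frames, 0, 0.12)))
  if (runif(1) < 0.2) f[sample.int(n_frames, 3)] <- NA
  p <- 100 * exp(cumsum(rnorm(n_frames, 0, 0.05)))
  list(t_h = t_h, foxo = f, p53 = p)
}

# Small valid in-memory trace table built directly (no simulator).
make_trace_table <- function(n_cells = 3, n_frames = 10, dt = 1 / 3,
                             death_at = NULL) {
  rows <- lapply(seq_len(n_cells), function(i) {
    t_h <- seq(0, by = dt, length.out = n_frames)
    f <- round(runif(n_frames, 0.1, 0.9), 4)
    p <- round(runif(n_frames, 50, 200), 2)
    dead <- rep(FALSE, n_frames)
    if (!is.null(death_at) && i == 1L) {
      dead <- t_h >= death_at
      f[dead] <- NA
      p[dead] <- NA
    }
    data.frame(cell_id = sprintf("c%03d", i), mode = "bolus", dose = 100,
               perturbation = "control", t_h = t_h, foxo1_nuc_frac = f,
               p53_nuc = p, dead = dead, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trace_table", "data.frame")
  out
}

default_thresholds <- function() activation_thresholds()
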