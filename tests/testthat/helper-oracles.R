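# Independent brute-force oracles for the reduction and inference rules.
# Deliberately written as plain element-wise scans so they share no code
# path with the implementation.

# minute counts -> logical vector: is this minute part of a maximal run of
# consecutive zeros of length >= min_len? (worn minutes only; non-worn
# positions break runs)
oracle_nonwear <- function(counts, eligible = rep(TRUE, length(counts)),
                           min_len = 20) {
  n <- length(counts)
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    if (eligible[i] && counts[i] == 0) {
      j <- i
      while (j < n && eligible[j + 1L] && counts[j + 1L] == 0) j <- j + 1L
      if (j - i + 1L >= min_len) out[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

oracle_spurious <- function(counts, thr = 11715) {
  out <- logical(length(counts))
  for (i in seq_along(counts)) if (counts[i] >= thr) out[i] <- TRUE
  out
}

# first/last index with value >= thr (NA if none)
oracle_start_end <- function(x, thr = 150) {
  first <- NA_integer_; last <- NA_integer_
  for (i in seq_along(x)) {
    if (x[i] >= thr) {
      if (is.na(first)) first <- i
      last <- i
    }
  }
  c(first, last)
}

# valid-day / inclusion decision from registered minutes and waking
# minutes per day
oracle_inclusion <- function(registered, waking, wearday_min = 150,
                             validday_min = 600, min_valid = 2) {
  se <- oracle_start_end(waking, wearday_min)
  if (is.na(se[1])) return(list(valid = rep(FALSE, length(registered)),
                                included = FALSE))
  valid <- logical(length(registered))
  for (i in seq_along(registered)) {
    valid[i] <- i >= se[1] && i <= se[2] && waking[i] >= wearday_min &&
      registered[i] >= validday_min
  }
  list(valid = valid, included = sum(valid) >= min_valid)
}

# Benjamini-Hochberg step-up by definition: largest k with
# p(k) <= k*q/m; reject the k smallest
oracle_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * q / m) k_max <- k
  }
  rej <- logical(m)
  if (k_max > 0L) rej[ord[seq_len(k_max)]] <- TRUE
  rej
}

# Moran's I by explicit double sum
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# weighted inverse-CDF quantile by linear scan
oracle_wq <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  target <- p * sum(w)
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + w[i]
    if (acc >= target - 1e-12) return(x[i])
  }
  x[length(x)]
}

# Build a 60 s series from a minute-count vector starting at a clock time.
minute_series <- function(counts, start = "2008-06-02 00:00:00",
                          id = "c1", steps = NULL) {
  epoch_series(id, start, 60, counts, steps %||% rep(0, length(counts)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Masked day template: all-worn day of given length starting 08:00.
worn_day <- function(counts, start = "2008-06-02 08:00:00") {
  s <- minute_series(counts, start)
  s <- flag_spurious(s)
  detect_nonwear(s)
}
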