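# Independent oracles used to cross-check the package implementations.
# Every oracle is written as plain scalar/loop code, deliberately avoiding
# the vectorized paths used inside the package.

# Sadeh discriminant for a single epoch, evaluated literally from its
# definition with explicit indexing into a zero-padded copy of the series.
sadeh_oracle <- function(counts, i) {
  pad <- c(rep(0, 5), counts, rep(0, 5))
  j <- i + 5
  win <- pad[(j - 5):(j + 5)]
  mw <- sum(win) / 11
  nat <- 0
  for (v in win) if (v >= 50 && v < 100) nat <- nat + 1
  six <- pad[(j - 5):j]
  sd6 <- sqrt(sum((six - mean(six))^2) / 5)
  lg <- log(counts[i] + 1)
  7.601 - 0.065 * mw - 1.08 * nat - 0.056 * sd6 - 0.703 * lg
}

# Exhaustive run-length oracle for rest-period detection: build the run
# encoding with a hand-written single pass, then walk the runs exactly as the
# rule is stated.
rest_periods_oracle <- function(states, onset_run, offset_run, min_rest) {
  n <- length(states)
  sleep <- states == "sleep"
  # manual run-length encoding (preallocated)
  vals <- logical(n)
  lens <- integer(n)
  starts <- integer(n)
  nr <- 0L
  k <- 1
  while (k <= n) {
    j <- k
    while (j < n && sleep[j + 1] == sleep[k]) j <- j + 1
    nr <- nr + 1L
    vals[nr] <- sleep[k]
    lens[nr] <- j - k + 1L
    starts[nr] <- k
    k <- j + 1
  }
  vals <- vals[seq_len(nr)]
  lens <- lens[seq_len(nr)]
  starts <- starts[seq_len(nr)]
  out <- list()
  r <- 1
  while (r <= length(vals)) {
    if (vals[r] && lens[r] >= onset_run) {
      start <- starts[r]
      q <- r + 1
      end <- n + 1
      while (q <= length(vals)) {
        if (!vals[q] && lens[q] >= offset_run) {
          end <- starts[q]
          break
        }
        q <- q + 1
      }
      if (end - start >= min_rest) {
        out[[length(out) + 1]] <- c(start, end)
      }
      r <- q
    } else {
      r <- r + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# First run of >= k sleep labels, by brute-force scanning.
first_sleep_run_oracle <- function(states, k) {
  n <- length(states)
  for (i in seq_len(n)) {
    if (i + k - 1 > n) break
    if (all(states[i:(i + k - 1)] == "sleep") &&
        (i == 1 || states[i - 1] != "sleep")) {
      return(i)
    }
  }
  NA_integer_
}

# Maximum Youden J over every candidate threshold, by explicit counting.
youden_oracle_maxJ <- function(positive, scores) {
  u <- sort(unique(scores))
  cands <- c(-Inf, u, Inf)
  best <- -Inf
  for (t in cands) {
    tp <- fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (positive[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    j <- tp / sum(positive) - fp / sum(!positive)
    if (j > best) best <- j
  }
  best
}

youden_J_at <- function(positive, scores, threshold) {
  pred <- scores >= threshold
  sum(pred & positive) / sum(positive) - sum(pred & !positive) / sum(!positive)
}

# Mann-Whitney U by brute-force pair counting.
mw_oracle_U <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
    }
  }
  u
}

# Central-moment features computed with explicit loops.
moments_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - m
    m2 <- m2 + d^2 / n
    m3 <- m3 + d^3 / n
    m4 <- m4 + d^4 / n
  }
  list(mean = m, skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurt = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# Window count by explicit enumeration of admissible start epochs.
window_count_oracle <- function(L, W, S) {
  count <- 0
  s <- 1
  while (s + W - 1 <= L) {
    count <- count + 1
    s <- s + S
  }
  count
}

# OLS by the normal equations, plus R^2 and the overall F statistic.
ols_oracle <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  fitted <- Xd %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p <- ncol(Xd) - 1
  n <- length(y)
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  list(beta = drop(beta), r_squared = r2, f = f)
}
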