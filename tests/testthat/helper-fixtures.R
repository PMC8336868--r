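# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small single-session simulation used across files
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_recording(
      sim_config(n_sessions = 1, trials_per_session = 90, seed = 1)
    )
  })
}

# deterministic hand-built recording: n trials, known values
toy_recording <- function(n_trials = 4, fs = 200, n_samples = 401,
                          tasks = rep(c("left", "right"), length.out = n_trials),
                          sessions = rep(1L, n_trials),
                          fill = function(trial, ch, t) sin(2 * pi * 10 * t) +
                            0.1 * trial + 0.01 * ch) {
  tax <- seq(-(n_samples - 1) / 2, (n_samples - 1) / 2) / fs
  arr <- array(0, c(n_trials, 19, n_samples))
  for (i in seq_len(n_trials)) {
    for (c in 1:19) arr[i, c, ] <- fill(i, c, tax)
  }
  epoched_recording(
    arr, fs, tax,
    tibble::tibble(trial = seq_len(n_trials), task = tasks,
                   session = sessions, day = 1L)
  )
}

# symmetric random correlation-like matrix with montage labels
random_symmetric <- function(n = 19, labels = mi_montage()$channels[seq_len(n)]) {
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}

# brute-force graph-metric oracles (independent of the implementation)
brute_node_degree <- function(m, i) {
  s <- 0
  for (j in seq_len(nrow(m))) if (j != i) s <- s + m[i, j]
  s
}

brute_region_degree <- function(m, idx) {
  s <- 0
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b) s <- s + m[idx[a], idx[b]]
    }
  }
  s
}

brute_transitivity <- function(adj) {
  n <- nrow(adj)
  closed <- 0
  connected <- 0
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        e <- adj[i, j] + adj[i, k] + adj[j, k]
        if (e == 3) {
          closed <- closed + 1
          connected <- connected + 3
        } else if (e == 2) {
          connected <- connected + 1
        }
      }
    }
  }
  if (connected == 0) return(0)
  3 * closed / connected
}

# brute-force Welch formulas, written straight from the textbook definition
brute_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
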