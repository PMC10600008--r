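# Independent reference implementations used as oracles. These are written
# directly from the definitions, not from the package's algorithms.

# Direct per-spike scan over the four burst criteria: open at an ISI <=
# max_start, extend while ISI <= max_end, merge gaps < min_interburst,
# drop bursts with < min_spikes.
brute_force_bursts <- function(spikes, max_start = 20, max_end = 50,
                               min_inter = 50, min_spikes = 2) {
  n <- length(spikes)
  bursts <- list()
  i <- 1L
  while (i < n) {
    isi <- (spikes[i + 1L] - spikes[i]) * 1000
    if (isi <= max_start) {
      j <- i + 1L
      while (j < n && (spikes[j + 1L] - spikes[j]) * 1000 <= max_end) j <- j + 1L
      bursts[[length(bursts) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge
  if (length(bursts) > 1L) {
    merged <- list(bursts[[1L]])
    for (b in bursts[-1L]) {
      last <- merged[[length(merged)]]
      gap <- (spikes[b[1L]] - spikes[last[2L]]) * 1000
      if (gap < min_inter) merged[[length(merged)]] <- c(last[1L], b[2L])
      else merged[[length(merged) + 1L]] <- b
    }
    bursts <- merged
  }
  bursts <- Filter(function(b) b[2L] - b[1L] + 1L >= min_spikes, bursts)
  if (!length(bursts)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, bursts)
}

# Generator matrix of the four-state trapping scheme, written out from the
# transition list (states C, O, OB, CB).
oracle_Q <- function(model, conc, in_event, in_depol) {
  open_scale <- if (in_depol) 1 else model$mg_open_scale
  r_open <- open_scale *
    (if (in_event) model$beta_drive else model$Po_spont * model$spont_event_rate)
  koff <- model$koff0 * (if (in_depol) model$depol_factor else 1)
  kb <- model$kon * conc
  a <- model$alpha
  esc <- model$cb_escape
  matrix(c(-r_open,       r_open,      0,           0,
           a,             -(a + kb),   kb,          0,
           0,             koff,        -(koff + a), a,
           esc,           0,           r_open,      -(r_open + esc)),
         nrow = 4, byrow = TRUE)
}

# Fine-step classical Runge-Kutta integration of dp/dt = Q^T p.
oracle_propagate <- function(Q, p0, t, nstep = 20000L) {
  h <- t / nstep
  p <- p0
  QT <- t(Q)
  for (k in seq_len(nstep)) {
    k1 <- as.numeric(QT %*% p)
    k2 <- as.numeric(QT %*% (p + h / 2 * k1))
    k3 <- as.numeric(QT %*% (p + h / 2 * k2))
    k4 <- as.numeric(QT %*% (p + h * k3))
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p
}

# Random spike train for the oracle-equivalence sweep: mixture of uniform
# spikes and short clusters, de-duplicated and sorted.
random_train <- function(n_max = 200) {
  n <- sample(0:n_max, 1L)
  s <- sort(runif(n, 0, 20))
  if (n > 20 && runif(1) < 0.7) {
    k <- sample(1:5, 1L)
    anchors <- sample(s, k)
    extra <- unlist(lapply(anchors, function(a)
      a + cumsum(runif(sample(1:6, 1L), 0.002, 0.06))))
    s <- sort(c(s, extra))
  }
  s <- s[!duplicated(round(s, 9))]
  s
}
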