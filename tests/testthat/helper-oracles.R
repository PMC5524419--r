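# Independent brute-force implementations used as oracles. These deliberately
# avoid the package's vectorised code paths: plain nested loops over the
# definitions.

# direct space-time filtering and opponent-energy computation
direct_energy_maps <- function(S, bank) {
  g <- bank$geometry
  nf <- g$n_frames
  np <- g$n_positions
  sf <- spatial_filters(bank)
  tf <- temporal_filters(bank)
  m <- (length(sf$even) - 1) / 2
  S0 <- S - mean(S)
  sconv <- function(M, f) {
    out <- matrix(0, nf, np)
    for (i in seq_len(nf)) {
      for (p in seq_len(np)) {
        acc <- 0
        for (q in seq_len(np)) {
          lag <- p - q
          if (abs(lag) <= m) acc <- acc + M[i, q] * f[lag + m + 1]
        }
        out[i, p] <- acc
      }
    }
    out
  }
  tconv <- function(M, r) {
    out <- matrix(0, nf, np)
    for (i in seq_len(nf)) {
      for (p in seq_len(np)) {
        acc <- 0
        for (l in seq_len(i)) acc <- acc + r[i - l + 1] * M[l, p]
        out[i, p] <- acc
      }
    }
    out
  }
  # spatial first, temporal second (the separable order opposite to the
  # package's), then the canonical quadrature combination
  Se <- sconv(S0, sf$even)
  So <- sconv(S0, sf$odd)
  es <- tconv(Se, tf$slow)
  ef <- tconv(Se, tf$fast)
  os <- tconv(So, tf$slow)
  of <- tconv(So, tf$fast)
  rightward <- (es - of)^2 + (os + ef)^2
  leftward <- (es + of)^2 + (ef - os)^2
  list(rightward = rightward, leftward = leftward,
       opponent = rightward - leftward)
}

# per-cell loop implementation of the classification images
direct_classification_images <- function(stims3d, responses) {
  d <- dim(stims3d)
  KL <- matrix(0, d[1], d[2])
  KC <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      vb <- stims3d[i, j, responses == 1]
      vs <- stims3d[i, j, responses == 0]
      KL[i, j] <- mean(vb) - mean(vs)
      KC[i, j] <- mean((vb - mean(vb))^2) - mean((vs - mean(vs))^2)
    }
  }
  list(K_L = KL, K_C = KC)
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))
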