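# Independent direct-definition oracles used to cross-check the package
# implementations. Everything here is deliberately naive (explicit DFT,
# plain loops, normal equations) and shares no code with the package.

# --- Welch PSD via explicit DFT on 1-s Hann windows, 50% overlap ----------
oracle_psd <- function(x, fs) {
  L <- round(fs)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  U <- sum(w^2)
  starts <- seq(1, length(x) - L + 1, by = floor(L / 2))
  n_half <- floor(L / 2)
  k <- 0:n_half
  # explicit DFT matrix (naive periodogram)
  W <- exp(-2i * pi * outer(k, 0:(L - 1)) / L)
  acc <- numeric(n_half + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    X <- as.vector(W %*% seg)
    p <- Mod(X)^2 / (fs * U)
    if (L %% 2 == 0) p[2:n_half] <- 2 * p[2:n_half]
    else p[2:(n_half + 1)] <- 2 * p[2:(n_half + 1)]
    acc <- acc + p
  }
  list(freqs = k * fs / L, power = acc / length(starts))
}

oracle_band_mean <- function(psd, lo, hi) {
  mean(psd$power[psd$freqs >= lo & psd$freqs <= hi])
}
oracle_band_sum <- function(psd, lo, hi) {
  sum(psd$power[psd$freqs >= lo & psd$freqs <= hi])
}

oracle_sqi <- function(x, fs) {
  psd <- oracle_psd(x, fs)
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  # baseline: centred moving average, odd 1-s window, reflected edges
  w <- round(fs); if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  padded <- c(rev(x[2:(half + 1)]), x, rev(x[(n - half):(n - 1)]))
  bl <- vapply(seq_len(n), function(i) mean(padded[i:(i + w - 1)]),
               numeric(1))
  # spectral entropy
  tot <- sum(psd$power)
  se <- if (tot == 0) 0 else {
    p <- psd$power / tot; p <- p[p > 0]
    -sum(p * log(p)) / log(length(psd$power))
  }
  # Hjorth complexity from population variances
  v <- function(z) { m <- sum(z) / length(z); sum((z - m)^2) / length(z) }
  d1 <- x[-1] - x[-n]
  d2 <- d1[-1] - d1[-length(d1)]
  mob_x <- sqrt(v(d1) / v(x))
  mob_d <- sqrt(v(d2) / v(d1))
  nyq <- max(psd$freqs)
  c(pband2 = oracle_band_mean(psd, 10, 20),
    seSQI = se,
    pband4 = oracle_band_mean(psd, 48, 52),
    bas_pow = sqrt(v(bl)),
    pband3 = oracle_band_mean(psd, 20, 48),
    ss = max(abs(d1)) * fs,
    pband1 = oracle_band_mean(psd, 0.5, 10),
    HA = max(x),
    stdSQI = sqrt(m2),
    kSQI = m4 / m2^2,
    pband5 = oracle_band_mean(psd, 52, min(100, nyq)),
    LA = min(x),
    pSQI = oracle_band_sum(psd, 5, 15) / oracle_band_sum(psd, 5, 45),
    complexity = mob_d / mob_x,
    basSQI = oracle_band_sum(psd, 0, 3) /
      oracle_band_sum(psd, 0, min(100, nyq)),
    sSQI = m3 / m2^1.5)
}

# --- brute-force greedy mRMR-MID (recomputed from scratch) -----------------
oracle_mrmr_order <- function(x, y, n_bins = 10L) {
  p <- ncol(x)
  bin1 <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE, type = 7))
    if (length(br) < 2) return(rep(1L, length(v)))
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  mi <- function(a, b) {
    tab <- table(a, b); n <- sum(tab)
    s <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        s <- s + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
    s
  }
  binned <- lapply(seq_len(p), function(j) bin1(x[, j]))
  rel <- vapply(binned, function(b) mi(b, y), numeric(1))
  sel <- integer(0)
  for (k in seq_len(p)) {
    rem <- setdiff(seq_len(p), sel)
    crit <- vapply(rem, function(j) {
      if (length(sel) == 0) rel[j]
      else rel[j] - mean(vapply(sel, function(s) mi(binned[[j]], binned[[s]]),
                                numeric(1)))
    }, numeric(1))
    m <- max(crit)
    sel <- c(sel, rem[crit >= m - 1e-9 * max(1, abs(m))][1])
  }
  colnames(x)[sel]
}

# --- plain covariance-form RLS (identical estimator, different algebra) ----
oracle_rls <- function(d, refs, taps, lambda, delta) {
  refs <- as.matrix(refs)
  n <- length(d); n_ref <- ncol(refs); M <- taps * n_ref
  P <- diag(M) / delta^2
  w <- numeric(M)
  e <- numeric(n)
  for (t in seq_len(n)) {
    u <- numeric(M)
    for (k in seq_len(n_ref)) {
      for (j in seq_len(taps)) {
        idx <- t - j + 1
        u[(k - 1) * taps + j] <- if (idx >= 1) refs[idx, k] else 0
      }
    }
    e[t] <- d[t] - sum(w * u)
    Pu <- P %*% u
    g <- as.vector(Pu) / (lambda + sum(u * Pu))
    w <- w + g * e[t]
    P <- (P - outer(g, as.vector(Pu))) / lambda
  }
  list(e = e, weights = w)
}

# Regularised normal-equation least squares (lambda = 1 closed form).
oracle_normal_eq <- function(d, refs, taps, delta) {
  refs <- as.matrix(refs)
  n <- length(d); n_ref <- ncol(refs); M <- taps * n_ref
  U <- matrix(0, n, M)
  for (k in seq_len(n_ref)) {
    for (j in seq_len(taps)) {
      col <- (k - 1) * taps + j
      U[j:n, col] <- refs[1:(n - j + 1), k]
    }
  }
  solve(delta^2 * diag(M) + crossprod(U), crossprod(U, d))[, 1]
}

# --- exhaustive optimal one-to-one tolerance matching ----------------------
oracle_optimal_tp <- function(det, ref, tol) {
  nd <- length(det); nr <- length(ref)
  if (nd == 0 || nr == 0) return(0L)
  best <- 0L
  rec <- function(ri, used_d, tp) {
    if (tp + (nr - ri + 1) <= best) return()
    if (ri > nr) { best <<- max(best, tp); return() }
    rec(ri + 1, used_d, tp)            # leave this reference unmatched
    for (di in seq_len(nd)) {
      if (!used_d[di] && abs(det[di] - ref[ri]) <= tol) {
        used_d[di] <- TRUE
        rec(ri + 1, used_d, tp + 1L)
        used_d[di] <- FALSE
      }
    }
  }
  rec(1L, logical(nd), 0L)
  best
}

# Small labelled feature table whose classes are separable on two features,
# with the remaining quality indexes pure noise.
make_separable_table <- function(n, seed = 1L, margin = 2) {
  set.seed(seed)
  y <- rep(c("non_informative", "informative"), length.out = n)
  tbl <- as.data.frame(matrix(rnorm(n * 16), n, 16,
                              dimnames = list(NULL, sqi_feature_names())))
  shift <- ifelse(y == "informative", margin, -margin)
  tbl$kSQI <- tbl$kSQI + shift
  tbl$pband2 <- tbl$pband2 + shift
  tbl$label <- factor(y, levels = c("non_informative", "informative"))
  tbl$degenerate <- FALSE
  tbl
}
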