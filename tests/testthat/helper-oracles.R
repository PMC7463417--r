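# Independent brute-force oracles: literal loop/sort implementations,
# deliberately naive and kept free of any package internals.

oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_first_order <- function(x, n_bins = 256L) {
  n <- length(x)
  m <- sum(x) / n
  s <- if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else 0
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  lv <- round(x)
  levels <- sort(unique(lv))
  freq <- vapply(levels, function(l) sum(lv == l), 0)
  rng <- range(x)
  ent <- 0
  if (diff(rng) > 0) {
    width <- diff(rng) / n_bins
    for (b in seq_len(n_bins)) {
      inb <- if (b < n_bins) {
        sum(x >= rng[1] + (b - 1) * width & x < rng[1] + b * width)
      } else {
        sum(x >= rng[1] + (b - 1) * width)
      }
      if (inb > 0) ent <- ent - inb / n * log2(inb / n)
    }
  }
  c(mean = m, sd = s,
    max_frequency = max(freq),
    mode = levels[which.max(freq)],
    minimum = min(x), maximum = max(x),
    p5 = oracle_quantile7(x, .05), p10 = oracle_quantile7(x, .10),
    p25 = oracle_quantile7(x, .25), p50 = oracle_quantile7(x, .50),
    p75 = oracle_quantile7(x, .75), p90 = oracle_quantile7(x, .90),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    entropy = ent)
}

# bin assignment identical in definition to the package's documented rule,
# written independently
oracle_bins <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  b <- floor((x - rng[1]) / diff(rng) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  b
}

# triple-loop per-slice co-occurrence counting
oracle_glcm <- function(vals, mask, offset, n_bins, symmetric = TRUE) {
  q <- array(NA_integer_, dim(vals))
  q[mask] <- oracle_bins(vals[mask], n_bins)
  d <- dim(vals)
  P <- matrix(0, n_bins, n_bins)
  for (z in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      for (cc in seq_len(d[3])) {
        r2 <- r + offset[1]; c2 <- cc + offset[2]
        if (r2 < 1 || r2 > d[2] || c2 < 1 || c2 > d[3]) next
        i <- q[z, r, cc]; j <- q[z, r2, c2]
        if (is.na(i) || is.na(j)) next
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  k <- nrow(P)
  ent <- 0; en <- 0; inert <- 0; mu <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    p <- P[i, j]
    en <- en + p^2
    if (p > 0) ent <- ent - p * log2(p)
    inert <- inert + (i - j)^2 * p
    mu <- mu + i * p
  }
  v <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v <- v + (i - mu)^2 * P[i, j]
  }
  c(entropy_glcm = ent, energy_glcm = en, inertia_glcm = inert,
    variance_glcm = v)
}

oracle_max_diameter <- function(mask_flags, spacing) {
  idx <- which(mask_flags, arr.ind = TRUE)
  best <- 0
  n <- nrow(idx)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(sum(((idx[i, ] - idx[j, ]) * spacing)^2))
    if (d > best) best <- d
  }
  best
}

oracle_mtv <- function(vals, mask_flags, spacing, fraction) {
  v <- vals[mask_flags]
  thr <- fraction * max(v)
  count <- 0
  for (x in v) if (x > thr) count <- count + 1
  count * prod(spacing)
}

# random small test volume + mask (guaranteed to contain a 2x2x2 block so
# every in-plane GLCM direction has pairs)
random_phantom_fixture <- function(seed, d = c(6L, 7L, 8L),
                                   spacing = c(4, 4, 4), p_mask = 0.4) {
  set.seed(seed)
  vals <- array(stats::runif(prod(d), 10, 250), d)
  mask <- array(stats::runif(prod(d)) < p_mask, d)
  mask[2:3, 2:3, 2:3] <- TRUE
  list(volume = image_volume(vals, spacing),
       mask = roi_mask(mask, spacing),
       vals = vals, flags = mask, spacing = spacing)
}
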