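# Independent oracles, deliberately written as plain double/triple loops so
# they share no code path with the package implementations they check.

# Brute-force DMS: enumerate every (ref_a, ref_b, probe) triple with distinct
# reference classes and a probe (distinct sample) from one of the two classes;
# strict nearest-reference rule, ties incorrect.
dms_oracle <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  correct <- 0
  trials <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || labels[a] == labels[b]) next
      for (p in seq_len(n)) {
        if (p == a || p == b) next
        if (!(labels[p] %in% c(labels[a], labels[b]))) next
        trials <- trials + 1
        d_same <- if (labels[p] == labels[a]) d(p, a) else d(p, b)
        d_other <- if (labels[p] == labels[a]) d(p, b) else d(p, a)
        if (d_same < d_other) correct <- correct + 1
      }
    }
  }
  # each unordered reference pair was visited twice (a,b) and (b,a)
  list(percent = 100 * correct / trials, n_trials = trials / 2)
}

# One-sided two-sample KS by direct ECDF maximization over a fine grid of all
# observed points, with the asymptotic one-sided tail bound.
ks_oracle <- function(within, between) {
  xs <- sort(unique(c(within, between)))
  Dmax <- 0
  for (x in xs) {
    diff <- mean(within <= x) - mean(between <= x)
    if (diff > Dmax) Dmax <- diff
  }
  n_eff <- length(within) * length(between) / (length(within) + length(between))
  list(D = Dmax, p = min(1, exp(-2 * n_eff * Dmax^2)))
}

# Textbook pooled-variance two-sample t.
ttest_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

# Double-loop within/between per-sample average distances.
distance_oracle <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  w <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    dw <- c(); db <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (labels[i] == labels[j]) dw <- c(dw, dij) else db <- c(db, dij)
    }
    w[i] <- if (length(dw)) mean(dw) else NA_real_
    b[i] <- mean(db)
  }
  list(within = w, between = b)
}
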