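# Independent oracles used to freeze expected values. These deliberately use
# brute force / enumeration, not the package's code paths.

# exhaustive 256-threshold Otsu: minimize w0*var0 + w1*var1 (population
# variances), ties toward the smaller threshold
otsu_oracle <- function(x) {
  b <- pmin(pmax(as.integer(round(as.vector(x))), 0L), 255L)
  n <- length(b)
  best <- Inf; bt <- 0L
  pvar <- function(v) if (length(v) == 0) 0 else mean((v - mean(v))^2)
  for (t in 0:255) {
    lo <- b[b <= t]; hi <- b[b > t]
    wcv <- length(lo) / n * pvar(lo) + length(hi) / n * pvar(hi)
    if (wcv < best - 1e-12) { best <- wcv; bt <- t }
  }
  bt
}

# full enumeration of the Mann-Whitney null: two-sided p of the observed U
# over all C(n1+n2, n1) group labelings (tie-free data only)
mw_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# random valid fluorescence level quadruples (F0 < FMp <= FM, Ft < FMp)
random_levels <- function(n, seed = 1) {
  set.seed(seed)
  F0 <- runif(n, 50, 500)
  FM <- F0 * (1 + runif(n, 0.5, 4))
  FMp <- F0 + (FM - F0) * runif(n, 0.2, 1)
  Ft <- FMp * runif(n, 0.3, 0.95)
  data.frame(F0 = F0, FM = FM, Ft = Ft, FMp = FMp)
}

recall_of <- function(mask, truth) sum(mask & truth) / sum(truth)
precision_of <- function(mask, truth) sum(mask & truth) / max(sum(mask), 1)
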