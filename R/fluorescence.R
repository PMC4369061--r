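#' Timing layout of a quenching protocol
#'
#' Describes the temporal structure of a PAM quenching measurement. The
#' defaults follow a standard short induction protocol: 5 s of measuring
#' flashes only (F0 window), one 800 ms saturation pulse (FM), 17 s of dark
#' relaxation, then 70 s of red actinic light with saturation pulses at 8,
#' 18, 28, 48 and 68 s after actinic onset. FM' is read from the last
#' actinic pulse and F(t) from a short window just before it.
#'
#' @param f0_window numeric length 2, start/end (s) of the dark F0 window.
#' @param sp1_start_s onset (s) of the first (dark-adapted) saturation pulse.
#' @param sp_duration_s saturation-pulse duration (s).
#' @param relax_s dark relaxation after the first pulse (s).
#' @param actinic_duration_s actinic illumination length (s).
#' @param sp_offsets_s pulse onsets (s) relative to actinic onset.
#' @param ft_window_s length (s) of the F(t) averaging window immediately
#'   before the last pulse; shrink to one sampling interval for a
#'   single-sample reading.
#' @return list of class `"protocol_timing"`; `actinic_start_s` and
#'   `total_s` are derived fields.
#' @export
protocol_timing <- function(f0_window = c(0, 5),
                            sp1_start_s = 5,
                            sp_duration_s = 0.8,
                            relax_s = 17,
                            actinic_duration_s = 70,
                            sp_offsets_s = c(8, 18, 28, 48, 68),
                            ft_window_s = 1) {
  stopifnot(length(f0_window) == 2, f0_window[1] < f0_window[2],
            sp_duration_s > 0, relax_s >= 0, ft_window_s > 0,
            length(sp_offsets_s) >= 1)
  if (f0_window[2] > sp1_start_s)
    stop("F0 window must end before the first saturation pulse")
  sp_offsets_s <- sort(sp_offsets_s)
  if (max(sp_offsets_s) + sp_duration_s > actinic_duration_s)
    stop("last saturation pulse must finish within the actinic phase")
  actinic_start <- sp1_start_s + sp_duration_s + relax_s
  structure(list(
    f0_window = f0_window, sp1_start_s = sp1_start_s,
    sp_duration_s = sp_duration_s, relax_s = relax_s,
    actinic_start_s = actinic_start,
    actinic_duration_s = actinic_duration_s,
    sp_offsets_s = sp_offsets_s, ft_window_s = ft_window_s,
    total_s = actinic_start + actinic_duration_s
  ), class = "protocol_timing")
}

# samples with t in [from, to); informative error when a window is missed
window_idx <- function(times, from, to, name) {
  idx <- which(times >= from & times < to)
  if (length(idx) == 0L)
    stop(sprintf("window %s not covered by trace (%.3f-%.3f s)", name, from, to))
  idx
}

#' Extract the four fluorescence levels from a quenching trace
#'
#' Reads F0 (mean over the dark window), FM (maximum during the first,
#' dark-adapted saturation pulse), FM' (maximum — or mean of the top
#' quartile — during the last actinic-phase pulse) and F(t) (mean over a
#' short window immediately preceding that pulse's onset).
#'
#' @param trace data.frame with columns `time_s` (strictly increasing) and
#'   `signal`, already demodulated (flash-minus-baseline); see
#'   [demodulate_trace()] for raw paired samples.
#' @param timing a [protocol_timing()] object.
#' @param fm_stat how to summarize a saturation-pulse plateau: `"max"`
#'   (default), `"top_quartile_mean"`, or `"mean"` (unbiased on a flat
#'   plateau, the noise-robust choice for validation on synthetic traces).
#' @return list of class `"fluor_levels"`: `F0`, `FM`, `Ft`, `FMp`, `FV`.
#' @export
extract_levels <- function(trace, timing = protocol_timing(),
                           fm_stat = c("max", "top_quartile_mean", "mean")) {
  fm_stat <- match.arg(fm_stat)
  stopifnot(all(c("time_s", "signal") %in% names(trace)))
  t <- trace$time_s; y <- trace$signal
  if (is.unsorted(t, strictly = TRUE)) stop("time_s must be strictly increasing")
  pulse_stat <- function(v) {
    switch(fm_stat,
      max = max(v),
      top_quartile_mean = mean(v[v >= stats::quantile(v, 0.75)]),
      mean = mean(v))
  }
  f0 <- mean(y[window_idx(t, timing$f0_window[1], timing$f0_window[2], "f0")])
  fm <- pulse_stat(y[window_idx(t, timing$sp1_start_s,
                                timing$sp1_start_s + timing$sp_duration_s, "fm")])
  last_on <- timing$actinic_start_s + max(timing$sp_offsets_s)
  ft <- mean(y[window_idx(t, last_on - timing$ft_window_s, last_on, "ft")])
  fmp <- pulse_stat(y[window_idx(t, last_on, last_on + timing$sp_duration_s,
                                 "fmp")])
  structure(list(F0 = f0, FM = fm, Ft = ft, FMp = fmp, FV = fm - f0),
            class = "fluor_levels")
}

#' Subtract pre-flash baselines from raw paired samples
#'
#' PAM instruments record the signal a few microseconds before each
#' measuring flash and during the flash, then subtract the two; this hook
#' performs that subtraction for recordings delivered raw.
#'
#' @param trace data.frame with `time_s`, `during_flash`, `before_flash`.
#' @return data.frame with `time_s`, `signal`.
#' @export
demodulate_trace <- function(trace) {
  stopifnot(all(c("time_s", "during_flash", "before_flash") %in% names(trace)))
  data.frame(time_s = trace$time_s,
             signal = trace$during_flash - trace$before_flash)
}

#' Minimal fluorescence of the light-adapted state, F0'
#'
#' `F0' = F0 / ((FM - F0)/FM + F0/FM')`. In the no-quenching limit
#' (FM' = FM) the denominator is exactly 1 and F0' = F0.
#'
#' @param F0,FM,FMp fluorescence levels, `FM >= F0 > 0`, `FMp > 0`.
#' @return F0' in the same instrument units.
#' @export
f0_prime <- function(F0, FM, FMp) {
  if (any(FM <= 0) || any(FMp <= 0) || any(F0 <= 0))
    stop("fluorescence levels must be positive")
  den <- (FM - F0) / FM + F0 / FMp
  if (any(den <= 0)) stop("degenerate quenching state: non-positive denominator")
  # in the no-quenching limit the denominator is analytically 1; evaluate it
  # as such so the identity F0' = F0 holds to the bit
  ifelse(FMp == FM, F0, F0 / den)
}

#' The six PSII quantum-yield and quenching parameters
#'
#' From the four measured levels (F0, FM, F(t), FM') derives:
#' \describe{
#'   \item{phi_Po}{maximal quantum yield of PSII photochemistry,
#'     dark-adapted: `(FM - F0)/FM = FV/FM`}
#'   \item{phi_P}{actual yield, light-adapted: `(FM' - Ft)/FM'`}
#'   \item{phi_fD}{yield of constitutive (basal) dissipation: `Ft/FM`}
#'   \item{phi_NPQ}{yield of regulatory light-induced heat dissipation:
#'     `Ft/FM' - Ft/FM`}
#'   \item{phi_PSII}{maximal light-adapted yield: `(FM' - F0')/FM'`}
#'   \item{q_P}{fraction of open PSII centers:
#'     `(FM' - Ft)/(FM' - F0')`}
#' }
#' F0' is computed via [f0_prime()]. Two identities hold by construction and
#' are useful numerical checks: `phi_P + phi_fD + phi_NPQ = 1` and
#' `phi_P = q_P * phi_PSII`. All yields are invariant to rescaling every
#' level by a common positive factor.
#'
#' @param levels a `"fluor_levels"` object (or list with `F0`, `FM`, `Ft`,
#'   `FMp`).
#' @return list of class `"quantum_yields"` with the six parameters plus
#'   `F0p`. When `FM' = F0'` (degenerate), `q_P` is `NA` with a warning.
#' @export
quantum_yields <- function(levels) {
  F0 <- levels$F0; FM <- levels$FM; Ft <- levels$Ft; FMp <- levels$FMp
  if (FM < F0) stop("FM must be >= F0")
  if (F0 <= 0 || FMp <= 0) stop("F0 and FM' must be positive")
  f0p <- f0_prime(F0, FM, FMp)
  qp <- if (abs(FMp - f0p) < .Machine$double.eps * FMp) {
    warning("FM' equals F0': q_P undefined")
    NA_real_
  } else (FMp - Ft) / (FMp - f0p)
  structure(list(
    phi_Po = (FM - F0) / FM,
    phi_P = (FMp - Ft) / FMp,
    phi_PSII = (FMp - f0p) / FMp,
    q_P = qp,
    phi_fD = Ft / FM,
    phi_NPQ = Ft / FMp - Ft / FM,
    F0p = f0p
  ), class = "quantum_yields")
}

#' Read a region-mean quenching trace from CSV
#' @param path CSV with columns `time_s`, `signal` (or raw
#'   `during_flash`/`before_flash` pairs, which are demodulated).
#' @return data.frame with `time_s`, `signal`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (all(c("during_flash", "before_flash") %in% names(d)))
    return(demodulate_trace(d))
  if (!all(c("time_s", "signal") %in% names(d)))
    stop("trace CSV must have columns time_s, signal")
  d[, c("time_s", "signal")]
}
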