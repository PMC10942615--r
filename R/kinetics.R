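#' Fractional exchange of one amide under EX2 kinetics
#'
#' In the EX2 limit the observed exchange rate of a backbone amide is its
#' intrinsic chemical rate divided by the protection factor,
#' `k_obs = k_int / pf`, and the deuterated fraction after time `t` of
#' labeling follows first-order kinetics `1 - exp(-k_obs * t)`.
#'
#' @param k_int Intrinsic exchange rate (1/s), > 0. Vectorized.
#' @param pf Protection factor (dimensionless, >= 1). Vectorized.
#' @param t Labeling time (s), >= 0. Vectorized.
#' @return Deuterated fraction(s) in `[0, 1]`.
#' @examples
#' residue_exchange_fraction(0.1, 1, 30)  # 1 - exp(-3)
#' @export
residue_exchange_fraction <- function(k_int, pf, t) {
  if (any(t < 0)) stop("labeling time must be >= 0", call. = FALSE)
  if (any(k_int <= 0)) stop("k_int must be > 0", call. = FALSE)
  if (any(pf < 1)) stop("protection factor must be >= 1", call. = FALSE)
  1 - exp(-(k_int / pf) * t)
}

#' Noise-free peptide deuterium uptake from a ground-truth system
#'
#' Sums the per-residue deuterated fractions over the peptide's
#' amide-bearing positions (start+1 ... end, excluding prolines) and
#' scales by the labeling deuterium fraction. The result lies in
#' `[0, d2o_fraction * n_max]`.
#'
#' @param truth A [simulate_system()] ground-truth system.
#' @param state `"free"` or `"bound"`.
#' @param start,end Peptide range on the construct (1-based inclusive).
#' @param t Labeling time(s) in seconds; vectorized.
#' @return Deuterium uptake in Da, one value per element of `t`.
#' @export
peptide_uptake <- function(truth, state, start, end, t) {
  stopifnot(inherits(truth, "ground_truth_system"))
  state <- match.arg(state, c("free", "bound"))
  if (start < 1L || end > truth$protein$length || start > end)
    stop("peptide range out of bounds for ground-truth protein",
         call. = FALSE)
  pos <- amide_positions(truth$protein, start, end)
  if (length(pos) == 0L) return(rep(0, length(t)))
  lpf <- if (state == "free") truth$log10_pf_free else truth$log10_pf_bound
  k <- truth$k_int[pos]
  pf <- 10^lpf[pos]
  vapply(t, function(tt)
    truth$d2o_fraction * sum(residue_exchange_fraction(k, pf, tt)),
    numeric(1L))
}

#' Uptake as percent of the theoretic maximum (D%)
#'
#' `100 * d / n_max`, where `n_max` is the peptide's exchange-observable
#' amide count. No back-exchange or labeling-fraction rescaling is
#' applied, so fully exchanged peptides labeled in 90% D2O plateau near
#' 90%, not 100%.
#'
#' @param d Deuterium uptake (Da); vectorized.
#' @param n_max Theoretic maximum amide count of the peptide.
#' @return Percent value(s); `NA` with a warning when `n_max` is 0
#'   (undefined).
#' @examples
#' relative_uptake_percent(4, 10)  # 40
#' @export
relative_uptake_percent <- function(d, n_max) {
  stopifnot(length(n_max) == 1L)
  if (n_max == 0) {
    warning("n_max is 0: relative uptake is undefined (NA)", call. = FALSE)
    return(rep(NA_real_, length(d)))
  }
  100 * d / n_max
}
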