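# Lander-Waterman detection probability for a structural variant / TR of
# given size under random read placement.

#' Probability that at least one read covers a structural variant
#'
#' A focal SV of length `d` occupying `[x, x+d)` is covered by a read of
#' length `L` exactly when some read starts in `[x+d-L, x]`, a window of
#' `L - d + 1` positions.  With `N` reads placed uniformly on a genome of
#' size `G` (coverage `c = LN/G`), the miss probability is
#' `(1 - N/G)^(L-d+1)`, approximated by `exp(-c (1 - (d-1)/L))` when `N/G`
#' is small.  The detection probability is one minus the miss probability.
#' For an SV on one allele of a diploid genome, halve the genome coverage
#' before calling (e.g. `c = 3.75` for 7.5x genome coverage).
#'
#' @param c Read coverage (`LN/G`); per-allele coverage for diploid use.
#' @param L Read length in bases.
#' @param d SV length in bases (`1 <= d <= L`); vectorised.
#' @param exact Use the exact `(1 - N/G)^(L-d+1)` form instead of the
#'   exponential approximation (requires `G`; `N` is derived as `cG/L`).
#' @param G Genome size in bases, only for `exact = TRUE`.
#' @return Detection probability in `[0, 1]` (vector along `d`).
#' @examples
#' prob_detect_sv(c = 3.75, L = 14000, d = 5000)  # ~0.9102
#' @export
prob_detect_sv <- function(c, L, d, exact = FALSE, G = NULL) {
  if (c <= 0) stop("coverage must be positive")
  if (any(d < 1)) stop("SV length must be >= 1")
  if (any(d > L)) stop("SV longer than read")
  if (!exact) {
    return(1 - exp(-c * (1 - (d - 1) / L)))
  }
  if (is.null(G)) stop("exact mode needs genome size G")
  N <- c * G / L
  1 - (1 - N / G)^(L - d + 1)
}
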