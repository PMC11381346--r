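# The Mash equation and SetSketch information-theoretic quantities.

#' Convert a Jaccard-type similarity to an ANI/AAI proxy (Mash equation)
#'
#' \deqn{\mathrm{ANI} = 1 + \frac{1}{k}\,\ln\frac{2J}{1+J}}
#' Monotonically increasing in `j`, equal to 1 at `j = 1`.  At `j <= 0` no
#' similarity is detectable and `NA` is returned with a warning.
#'
#' @param j Jaccard or probability-Jaccard similarity in `(0, 1]`.
#' @param k K-mer length the similarity was computed at.
#' @return ANI/AAI proxy as a fraction (vectorised over `j`).
#' @export
mash_transform <- function(j, k) {
  stopifnot(k >= 1)
  out <- rep(NA_real_, length(j))
  ok <- !is.na(j) & j > 0
  if (any(!ok & !is.na(j)))
    warning("j <= 0: no detectable similarity; returning NA")
  out[ok] <- 1 + log(2 * j[ok] / (1 + j[ok])) / k
  out
}

#' Invert the Mash equation
#'
#' Solves the Mash equation for the Jaccard similarity:
#' with \eqn{c = e^{k(\mathrm{ANI}-1)}}, \eqn{J = c/(2-c)}.
#' `mash_transform(mash_inverse(a, k), k)` returns `a` to within 1e-12.
#'
#' @param ani ANI/AAI proxy in `(0, 1]` (vectorised).
#' @param k K-mer length.
#' @return Jaccard-type similarity.
#' @export
mash_inverse <- function(ani, k) {
  stopifnot(k >= 1, all(ani <= 1))
  cc <- exp(k * (ani - 1))
  cc / (2 - cc)
}

#' Per-register Shannon entropy of a SetSketch
#'
#' Numerically evaluates the asymptotic per-register entropy of a base-`b`
#' SetSketch,
#' \deqn{H(b) = \frac{1}{\ln 2 \, \ln b}\Big(\big(1-\tfrac1b\big) +
#'   \int_0^1 z^{1/(b-1)} \frac{(1-z)\ln(1-z)}{z \ln z}\,dz\Big),}
#' by adaptive quadrature (absolute tolerance 1e-6; the integrand extends
#' continuously to 0 at \eqn{z = 0} and has an integrable logarithmic
#' singularity at \eqn{z = 1}).  At `b = 2` this reproduces the classic
#' HyperLogLog register entropy of 2.83 bits.
#'
#' @param b SetSketch base, `b > 1`.
#' @return Entropy in bits per register.
#' @export
setsketch_entropy_per_register <- function(b) {
  stopifnot(b > 1)
  f <- function(z) z^(1 / (b - 1)) * (1 - z) * log(1 - z) / (z * log(z))
  I <- integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-6,
                 subdivisions = 1000L)$value
  ((1 - 1 / b) + I) / (log(2) * log(b))
}

#' Space headroom of entropy-optimal register coding
#'
#' Percentage reduction an entropy-optimal code would achieve over fixed
#' `bits`-bit registers: `100 * (1 - H(b)/bits)`.
#'
#' @param b SetSketch base.
#' @param bits Uncompressed register width in bits (default 16).
#' @return Reduction in percent.
#' @export
setsketch_space_reduction <- function(b, bits = 16) {
  100 * (1 - setsketch_entropy_per_register(b) / bits)
}
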