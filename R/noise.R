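#' Synthesize a 1/f^alpha membrane noise current
#'
#' Frequency-domain synthesis: a random Hermitian spectrum is shaped with
#' magnitude \eqn{|f|^{-\alpha/2}} (DC bin zeroed) and inverse-transformed
#' to a real trace, which is then centered and rescaled so that its sample
#' variance equals \code{sigma_noise^2} exactly.  Each call produces a
#' fresh realization from R's global random number stream.
#'
#' @param n_samples number of samples (>= 2).
#' @param dt sample step in s.
#' @param sigma_noise noise standard deviation in uA (0 gives a zero trace).
#' @param alpha_noise spectral exponent of the power spectral density.
#' @return Numeric vector of length \code{n_samples} (uA).
#' @export
#' @examples
#' set.seed(1)
#' x <- make_noise_current(4096, 1e-6, 8.70, 0.8)
#' var(x)  # 8.70^2
make_noise_current <- function(n_samples, dt, sigma_noise, alpha_noise = 0.8) {
  if (sigma_noise == 0) return(numeric(n_samples))
  p <- .noise_pairs(n_samples, 1L, alpha_noise)
  p$A[, 1L] * sigma_noise
}

# cache of spectral magnitude vectors, keyed by (m, alpha)
.noise_cache <- new.env(parent = emptyenv())

.noise_mag <- function(m, alpha) {
  key <- sprintf("%d_%g", m, alpha)
  mag <- .noise_cache[[key]]
  if (is.null(mag)) {
    k <- seq_len(m) - 1
    f <- pmin(k, m - k)  # two-sided frequency index (units drop out)
    mag <- c(0, f[-1]^(-alpha / 2))
    .noise_cache[[key]] <- mag
  }
  mag
}

# npairs pairs of independent unit-variance noise realizations.  Each
# column of the complex spectrum matrix packs two independent Hermitian
# spectra (real/imaginary parts of the inverse FFT), so one FFT yields the
# two traces a two-neuron trial needs.
.noise_pairs <- function(n, npairs, alpha) {
  stopifnot(n >= 2, npairs >= 1)
  m <- stats::nextn(n, c(2, 3, 5))
  mag <- .noise_mag(m, alpha)
  A <- matrix(0, n, npairs)
  B <- matrix(0, n, npairs)
  chunk <- max(1L, min(npairs, floor(4e6 / m)))
  done <- 0L
  while (done < npairs) {
    nc <- min(chunk, npairs - done)
    z <- noise_spectra_cpp(m, nc, mag)
    s <- split_unit_cpp(stats::mvfft(z, inverse = TRUE), n)
    A[, done + seq_len(nc)] <- s$A
    B[, done + seq_len(nc)] <- s$B
    done <- done + nc
  }
  list(A = A, B = B)
}

# matrix of independent noise realizations at standard deviation sigma
.noise_bank <- function(n, ncol, dt, sigma, alpha) {
  if (sigma == 0) return(matrix(0, n, ncol))
  p <- .noise_pairs(n, ceiling(ncol / 2), alpha)
  cbind(p$A, p$B)[, seq_len(ncol), drop = FALSE] * sigma
}
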