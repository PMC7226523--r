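#' Single-level undecimated 3-D wavelet decomposition
#'
#' Applies a separable stationary (undecimated) wavelet transform: for each of
#' the three axes either the low-pass (`L`) or high-pass (`H`) analysis filter
#' is applied, giving all eight `{L,H}^3` sub-bands on the same grid as the
#' input. The default kernel is the Coiflet-1 analysis pair; boundaries are
#' handled periodically. The label's first letter is the filter on the first
#' array axis.
#'
#' @param volume `image_volume` or 3-D array.
#' @param wavelet wavelet kernel name; currently `"coif1"` or `"haar"`.
#' @return Named list of eight 3-D arrays: `LLL`, `LLH`, `LHL`, `LHH`, `HLL`,
#'   `HLH`, `HHL`, `HHH`.
#' @export
wavelet_decompose <- function(volume, wavelet = "coif1") {
  vol <- if (inherits(volume, "image_volume")) volume$data else volume
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  flt <- wavelet_filters(wavelet)
  if (any(dim(vol) < length(flt$lo)))
    stop("wavelet_decompose: volume smaller than the filter kernel (",
         length(flt$lo), " taps)")
  bands <- list()
  for (b in band_labels()) {
    f <- strsplit(b, "")[[1]]
    pick <- function(ch) if (ch == "L") flt$lo else flt$hi
    out <- cpp_sep_filter3d(as.numeric(vol), as.integer(dim(vol)),
                            pick(f[1]), pick(f[2]), pick(f[3]))
    dim(out) <- dim(vol)
    bands[[b]] <- out
  }
  bands
}

band_labels <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

wavelet_filters <- function(wavelet = c("coif1", "haar")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "haar") {
    lo <- c(1, 1) / sqrt(2)
    hi <- c(1, -1) / sqrt(2)
  } else {
    # Coiflet-1 analysis filters (sum of lo = sqrt(2))
    lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
    hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
            0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  }
  list(lo = lo, hi = hi)
}

# Gaussian smoothing by separable filtering (kernel truncated at 3 sigma,
# renormalized; periodic boundary). Used by the phantom generator.
smooth_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- cpp_sep_filter3d(as.numeric(arr), as.integer(dim(arr)), k, k, k)
  dim(out) <- dim(arr)
  out
}
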