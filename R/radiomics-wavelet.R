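## Two-level 2D Haar wavelet decomposition and the 280 wavelet-domain
## features (35 per subband over 8 subbands).

SUBBAND_NAMES <- c("LL1", "LH1", "HL1", "HH1", "LL2", "LH2", "HL2", "HH2")

## 1D Haar analysis along the columns of x; odd lengths are symmetrically
## padded by repeating the last sample.
haar_cols <- function(x) {
  n <- nrow(x)
  if (n %% 2L == 1L) x <- rbind(x, x[n, , drop = FALSE])
  odd <- x[seq(1, nrow(x), 2), , drop = FALSE]
  even <- x[seq(2, nrow(x), 2), , drop = FALSE]
  list(lo = (odd + even) / sqrt(2), hi = (odd - even) / sqrt(2))
}

## 1D Haar synthesis along columns (inverse of haar_cols before cropping).
haar_icols <- function(lo, hi) {
  n2 <- nrow(lo)
  out <- matrix(0, 2L * n2, ncol(lo))
  out[seq(1, 2 * n2, 2), ] <- (lo + hi) / sqrt(2)
  out[seq(2, 2 * n2, 2), ] <- (lo - hi) / sqrt(2)
  out
}

## Single-level 2D Haar analysis: returns LL, LH, HL, HH. First letter is
## the horizontal (x/column) filter, the second the vertical (y/row) filter.
haar_dwt2 <- function(frame) {
  rowpass <- haar_cols(frame)                      # filter along y (rows)
  lo <- haar_cols(t(rowpass$lo))                   # filter along x
  hi <- haar_cols(t(rowpass$hi))
  list(LL = t(lo$lo), HL = t(lo$hi), LH = t(hi$lo), HH = t(hi$hi))
}

## Inverse single-level 2D Haar for an original frame of size nr x nc.
haar_idwt2 <- function(bands, nr, nc) {
  rowpass_lo <- t(haar_icols(t(bands$LL), t(bands$HL)))[, seq_len(nc), drop = FALSE]
  rowpass_hi <- t(haar_icols(t(bands$LH), t(bands$HH)))[, seq_len(nc), drop = FALSE]
  haar_icols(rowpass_lo, rowpass_hi)[seq_len(nr), , drop = FALSE]
}

#' Eight wavelet subbands of a frame
#'
#' Two-level 2D discrete Haar wavelet decomposition (symmetric padding of
#' odd dimensions). Both approximation images are retained, so exactly
#' eight subbands result: LL1, LH1, HL1, HH1 from the first level and LL2,
#' LH2, HL2, HH2 from decomposing LL1. The first letter of a subband name
#' is the horizontal (x) filter, the second the vertical (y) filter.
#'
#' @param frame Numeric matrix, at least 16 x 16.
#' @return Named list of 8 matrices.
#' @export
wavelet_subbands <- function(frame) {
  if (nrow(frame) < 16L || ncol(frame) < 16L) {
    stop_("frame must be at least 16x16 for the two-level decomposition")
  }
  l1 <- haar_dwt2(frame)
  l2 <- haar_dwt2(l1$LL)
  list(LL1 = l1$LL, LH1 = l1$LH, HL1 = l1$HL, HH1 = l1$HH,
       LL2 = l2$LL, LH2 = l2$LH, HL2 = l2$HL, HH2 = l2$HH)
}

#' 280 wavelet-domain features
#'
#' For each of the 8 subbands of [wavelet_subbands()], 35 features: the 16
#' intensity features plus the first 19 co-occurrence features of the
#' canonical 22-feature order (computed on the subband quantized to
#' `n_levels`); 8 x 35 = 280.
#'
#' @param frame Numeric matrix, at least 16 x 16.
#' @param n_levels Quantization levels for the co-occurrence subset.
#' @return Named numeric vector of length 280 (names prefixed by subband).
#' @export
wavelet_features <- function(frame, n_levels = 32L) {
  sb <- wavelet_subbands(frame)
  out <- lapply(names(sb), function(nm) {
    band <- sb[[nm]]
    g <- glcm_features(quantize_gray(band, n_levels), n_levels)[1:19]
    f <- c(intensity_features(band),
           stats::setNames(g, paste0("glcm_", names(g))))
    stats::setNames(f, paste0(nm, "_", names(f)))
  })
  unlist(out)
}
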