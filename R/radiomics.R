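## Per-frame and per-case radiomic feature vectors.

#' 350 radiomic features of one frame
#'
#' Concatenation of the 16 intensity, 54 texture and 280 wavelet-domain
#' features (16 + 54 + 280 = 350).
#'
#' @param frame Numeric matrix, at least 16 x 16.
#' @param n_levels Quantization levels for texture features.
#' @return Named numeric vector of length 350.
#' @export
frame_radiomics <- function(frame, n_levels = 32L) {
  ints <- intensity_features(frame)
  wav <- wavelet_features(frame, n_levels)
  c(stats::setNames(ints, paste0("intensity_", names(ints))),
    texture_features(frame, n_levels),
    stats::setNames(wav, paste0("wavelet_", names(wav))))
}

#' 1,750-dimensional per-case radiomic vector
#'
#' Extracts the 350 per-frame features at each of the five key frames and
#' concatenates them frame-major (all features of key frame 1, then key
#' frame 2, ...): 350 x 5 = 1,750 named values. Names carry the key-frame
#' slot (`f1_` .. `f5_`), feature group and subband.
#'
#' @param stack A [frame_stack()].
#' @param key_frames Integer vector of 5 valid 0-based frame indices (see
#'   [select_key_frames()]); duplicates allowed.
#' @param n_levels Quantization levels for texture features.
#' @return Named numeric vector of length 1,750.
#' @export
case_radiomics_vector <- function(stack, key_frames, n_levels = 32L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(key_frames) != 5L) stop_("exactly 5 key frames are required")
  if (any(key_frames < 0) || any(key_frames >= length(stack$frames))) {
    stop_("key frame index out of range")
  }
  blocks <- lapply(seq_along(key_frames), function(i) {
    v <- frame_radiomics(stack$frames[[key_frames[i] + 1L]], n_levels)
    stats::setNames(v, paste0("f", i, "_", names(v)))
  })
  unlist(blocks)
}
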