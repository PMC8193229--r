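## Texture features on the quantized frame: 22 gray-level co-occurrence
## (GLCM), 16 run-length (GLRLM) and 16 size-zone (GLSZM) features.

GLCM_NAMES <- c("autocorrelation", "joint_average", "cluster_prominence",
                "cluster_shade", "cluster_tendency", "contrast",
                "correlation", "difference_average", "difference_entropy",
                "difference_variance", "joint_energy", "joint_entropy",
                "imc1", "imc2", "inverse_difference",
                "inverse_difference_norm", "inverse_difference_moment",
                "inverse_difference_moment_norm", "inverse_variance",
                "maximum_probability", "sum_average", "sum_entropy")

GLRLM_NAMES <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                 "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
                 "lrlgle", "lrhgle")

GLSZM_NAMES <- c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                 "zv", "ze", "lglze", "hglze", "salgle", "sahgle",
                 "lalgle", "lahgle")

#' Quantize a frame to discrete gray levels
#'
#' Equal-width binning between the frame minimum and maximum into
#' `n_levels` levels (1-based); a constant frame maps to level 1
#' everywhere.
#'
#' @param frame Numeric matrix.
#' @param n_levels Number of levels (>= 2; default 32).
#' @return Integer matrix with values in `1..n_levels`.
#' @export
quantize_gray <- function(frame, n_levels = 32L) {
  if (!is_count(n_levels) || n_levels < 2) stop_("n_levels must be >= 2")
  rng <- range(frame)
  if (rng[2] <= rng[1]) {
    return(matrix(1L, nrow = nrow(frame), ncol = ncol(frame)))
  }
  q <- floor((frame - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L
  matrix(as.integer(pmin(q, n_levels)), nrow = nrow(frame))
}

## Symmetric, normalized co-occurrence matrix for one offset (dr, dc).
glcm_matrix <- function(q, dr, dc, ng) {
  nr <- nrow(q); nc <- ncol(q)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dr >= 1L & rows + dr <= nr]
  c1 <- cols[cols + dc >= 1L & cols + dc <= nc]
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * ng + b, ng * ng)
  m <- matrix(counts, ng, ng, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_features_one <- function(p, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  ## diagonal / cross-diagonal distributions
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  hxy <- ent(p)
  pxy <- px[i] * py[j]
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px); hy <- ent(py)
  corr <- if (sdx > 0 && sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  da <- sum(k_diff * p_diff)
  inv_var <- sum(p[i != j] / (i - j)[i != j]^2)
  stats::setNames(c(
    sum(i * j * p),
    mux,
    sum((i + j - mux - muy)^4 * p),
    sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    ent(p_diff),
    sum((k_diff - da)^2 * p_diff),
    sum(p^2),
    hxy,
    imc1,
    imc2,
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / ng)),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    inv_var,
    max(p),
    sum(k_sum * p_sum),
    ent(p_sum)
  ), GLCM_NAMES)
}

#' 22 gray-level co-occurrence features
#'
#' Symmetric GLCMs at distance 1 in the four 2D directions (0, 45, 90 and
#' 135 degrees); each feature is computed per direction and averaged.
#' Degenerate statistics on constant frames (correlation, IMC1) are
#' defined as 0.
#'
#' @param q Quantized integer matrix (see [quantize_gray()]).
#' @param n_levels Number of gray levels used in `q`.
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(q, n_levels = 32L) {
  ng <- n_levels
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  feats <- lapply(offsets, function(o) {
    p <- glcm_matrix(q, o[1], o[2], ng)
    if (is.null(p)) return(NULL)
    glcm_features_one(p, ng)
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (length(feats) == 0L) stop_("frame too small for co-occurrence")
  colMeans(do.call(rbind, feats))
}

## Run-length matrix for one direction; returns counts R[level, run_length].
glrlm_matrix <- function(q, direction, ng) {
  runs_of <- function(v) {
    r <- rle(v)
    cbind(level = r$values, len = r$lengths)
  }
  segs <- switch(direction,
    h = lapply(seq_len(nrow(q)), function(r) q[r, ]),
    v = lapply(seq_len(ncol(q)), function(c) q[, c]),
    d1 = split(q, row(q) - col(q)),       # 135-degree diagonals
    d2 = split(q, row(q) + col(q))        # 45-degree diagonals
  )
  rl <- do.call(rbind, lapply(segs, runs_of))
  max_len <- max(rl[, "len"])
  m <- table(factor(rl[, "level"], levels = seq_len(ng)),
             factor(rl[, "len"], levels = seq_len(max_len)))
  matrix(as.numeric(m), ng, max_len)
}

rl_zone_features <- function(m, n_pixels, names) {
  ## shared arithmetic of GLRLM and GLSZM: m[level, size] counts
  nr <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  l <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  p <- m / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  p_nz <- p[p > 0]
  stats::setNames(c(
    sum(m / l^2) / nr,
    sum(m * l^2) / nr,
    sum(rowSums(m)^2) / nr,
    sum(rowSums(m)^2) / nr^2,
    sum(colSums(m)^2) / nr,
    sum(colSums(m)^2) / nr^2,
    nr / n_pixels,
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(p_nz * log2(p_nz)),
    sum(m / i^2) / nr,
    sum(m * i^2) / nr,
    sum(m / (i^2 * l^2)) / nr,
    sum(m * i^2 / l^2) / nr,
    sum(m * l^2 / i^2) / nr,
    sum(m * i^2 * l^2) / nr
  ), names)
}

#' 16 gray-level run-length features
#'
#' Run-length matrices in the four directions, features averaged over
#' directions: short/long run emphasis, gray-level and run-length
#' non-uniformity (plain and normalized), run percentage, gray-level and
#' run-length variance, run entropy, and the four low/high gray-level
#' short/long run emphases.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(q, n_levels = 32L) {
  np <- length(q)
  feats <- lapply(c("h", "v", "d1", "d2"), function(d) {
    rl_zone_features(glrlm_matrix(q, d, n_levels), np, GLRLM_NAMES)
  })
  colMeans(do.call(rbind, feats))
}

#' 16 gray-level size-zone features
#'
#' Zones are 8-connected regions of constant gray level; the size-zone
#' matrix counts zones by level and size. Features mirror the run-length
#' set with zone size in place of run length.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(q, n_levels = 32L) {
  zones <- label_zones(q)
  tab <- table(factor(zones$level, levels = seq_len(n_levels)),
               factor(zones$size, levels = seq_len(max(zones$size))))
  m <- matrix(as.numeric(tab), n_levels, max(zones$size))
  rl_zone_features(m, length(q), GLSZM_NAMES)
}

#' 54 texture features of a frame
#'
#' The frame is quantized with [quantize_gray()] and the 22 co-occurrence,
#' 16 run-length and 16 size-zone features are concatenated
#' (22 + 16 + 16 = 54).
#'
#' @param frame Numeric matrix.
#' @param n_levels Quantization levels (default 32).
#' @return Named numeric vector of length 54 (prefixes `glcm_`, `glrlm_`,
#'   `glszm_`).
#' @export
texture_features <- function(frame, n_levels = 32L) {
  q <- quantize_gray(frame, n_levels)
  out <- c(glcm_features(q, n_levels), glrlm_features(q, n_levels),
           glszm_features(q, n_levels))
  stats::setNames(out, c(paste0("glcm_", GLCM_NAMES),
                         paste0("glrlm_", GLRLM_NAMES),
                         paste0("glszm_", GLSZM_NAMES)))
}
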