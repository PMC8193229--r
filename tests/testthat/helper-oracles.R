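# Independent oracles and fixture builders used across the suite.

# Brute-force average precision: given the ranked TP/FP flags and the truth
# count, enumerate every recall level and scan all prefixes for the maximal
# precision at recall >= r (no cummax shortcut).
ap_oracle <- function(tp_flags, n_truth) {
  if (length(tp_flags) == 0L || n_truth == 0L) return(0)
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  recall <- tp / n_truth
  precision <- tp / (tp + fp)
  levels <- unique(recall)
  ap <- 0
  prev <- 0
  for (r in levels) {
    p_int <- max(precision[recall >= r])
    ap <- ap + (r - prev) * p_int
    prev <- r
  }
  ap
}

# Exhaustive AUC: all positive-negative pairs, ties count 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Cyclic coordinate descent for the lasso objective
# (1/2n)||y - b0 - X w||^2 + lambda ||w||_1 on standardized X.
lasso_oracle <- function(x, y, lambda, n_iter = 2000L) {
  n <- nrow(x); p <- ncol(x)
  b0 <- mean(y)
  w <- numeric(p)
  soft <- function(z, g) sign(z) * max(0, abs(z) - g)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      r <- y - b0 - x %*% w + x[, j] * w[j]
      w[j] <- soft(sum(x[, j] * r) / n, lambda) / (sum(x[, j]^2) / n)
    }
    b0 <- mean(y - x %*% w)
  }
  list(w = w, b0 = b0)
}

lasso_objective <- function(x, y, w, b0, lambda) {
  n <- nrow(x)
  sum((y - b0 - x %*% w)^2) / (2 * n) + lambda * sum(abs(w))
}

# Minimal detection-table row builder.
det_row <- function(frame, label, box, score = NA_real_, case_id = "c1") {
  data.frame(case_id = case_id, frame = frame, label = label,
             x_min = box[1], y_min = box[2], x_max = box[3], y_max = box[4],
             score = score, stringsAsFactors = FALSE)
}

det_rows <- function(...) do.call(rbind, list(...))

# Random valid (positive-area) box inside a w x h canvas.
random_box <- function(w = 40, h = 40) {
  x1 <- sample.int(w - 1, 1) - 1
  x2 <- x1 + sample.int(w - 1 - x1, 1)
  y1 <- sample.int(h - 1, 1) - 1
  y2 <- y1 + sample.int(h - 1 - y1, 1)
  c(x1, y1, x2, y2)
}

# Small seeded phantom rendered once per session for reuse.
phantom_fixture <- local({
  cache <- new.env()
  function(diagnosis = "AVM", seed = 11L, noise_sd = 0) {
    key <- paste(diagnosis, seed, noise_sd)
    if (is.null(cache[[key]])) {
      gr <- if (diagnosis == "AVM") "low" else "none"
      sched <- build_schedule(diagnosis, gr, n_frames = 30, rng_seed = seed)
      cache[[key]] <- render_case(sched, noise_sd = noise_sd, rng_seed = seed)
    }
    cache[[key]]
  }
})
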