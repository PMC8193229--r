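#' @keywords internal
"_PACKAGE"

## The five vascular structure classes tracked on DSA, in hemodynamic order.
DSA_CLASSES <- c("carotid_artery", "willis_circle", "vein", "venous_vessel",
                 "venous_sinus")

PHASE_LEVELS <- c("pre_contrast", "early_arterial", "late_arterial",
                  "capillary", "early_venous", "late_venous", "post_contrast")

#' Vascular structure class labels
#'
#' The five structure classes annotated on DSA frames, in the order in which
#' they normally opacify: internal carotid artery, circle of Willis, (large)
#' vein, venous vessel, venous sinus.
#'
#' @return Character vector of length 5.
#' @export
dsa_classes <- function() DSA_CLASSES

#' Phase labels of the DSA timeline
#'
#' @return Character vector of the seven per-frame phase labels, in temporal
#'   order: pre-contrast, early/late arterial, capillary, early/late venous,
#'   post-contrast.
#' @export
dsa_phases <- function() PHASE_LEVELS

## Round half away from zero (for positive x: "round half up").
round_half_up <- function(x) floor(x + 0.5)

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

## Label 8-connected components of a logical matrix. Returns an integer
## vector of component labels parallel to which(mask); labels are 1..n_comp,
## numbered in first-pixel (column-major) order.
label_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(list(idx = integer(0), label = integer(0), n = 0L))
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- sh[1L]; dc <- sh[2L]
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    hit <- mask[nb]
    edges_from <- c(edges_from, vid[idx[ok][hit]])
    edges_to <- c(edges_to, vid[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  memb <- igraph::components(g)$membership
  ## renumber components by first occurrence for determinism
  relab <- match(memb, unique(memb))
  list(idx = idx, label = relab, n = length(unique(memb)))
}

## Zones (8-connected regions of constant value) of an integer matrix.
## Returns data.frame(level, size), one row per zone.
label_zones <- function(q) {
  nr <- nrow(q)
  nc <- ncol(q)
  n <- nr * nc
  v <- as.integer(q)
  idx <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  ef <- integer(0)
  et <- integer(0)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- sh[1L]; dc <- sh[2L]
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    a <- idx[ok]
    b <- a + dr + dc * nr
    same <- v[a] == v[b]
    ef <- c(ef, a[same])
    et <- c(et, b[same])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  memb <- igraph::components(g)$membership
  size <- tabulate(memb)
  first <- match(seq_along(size), memb)
  data.frame(level = v[first], size = size)
}
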