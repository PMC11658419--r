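`%||%` <- function(a, b) if (is.null(a)) b else a

abort_sq <- function(..., class = "spheroidquant_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort_sq(...)
  invisible(TRUE)
}

# dim of a 3D array with validation
dim3 <- function(a, what = "array") {
  d <- dim(a)
  assert_that(length(d) == 3L, what, " must be a 3D (z,y,x) array, got ",
              length(d) %||% 1L, " dimension(s)")
  d
}

# bounding box (index ranges) of TRUE voxels, optionally padded and clamped
mask_bbox <- function(mask, pad = 0L) {
  d <- dim(mask)
  w <- which(mask)
  assert_that(length(w) > 0L, "mask is empty")
  ai <- arrayInd(w, d)
  lo <- pmax(apply(ai, 2L, min) - pad, 1L)
  hi <- pmin(apply(ai, 2L, max) + pad, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# volume-wide Otsu threshold on a 256-bin histogram
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# population standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
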