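# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic RNG scope: fixes all three RNG kinds so a given seed yields
# identical draws across sessions and platforms, and restores the caller's
# RNG state on exit.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Normalised Gaussian kernel, truncated at `trunc` standard deviations.
gaussian_kernel <- function(sigma, trunc = 3) {
  stopifnot(sigma > 0)
  r <- ceiling(trunc * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-D Gaussian smoothing with reflect padding.
smooth1d <- function(x, sigma, trunc = 3) {
  w <- gaussian_kernel(sigma, trunc)
  r <- (length(w) - 1L) / 2L
  n <- length(x)
  if (n <= r) stop("signal shorter than kernel support", call. = FALSE)
  xp <- c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
  out <- stats::filter(xp, w, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# Separable 2-D Gaussian smoothing (reflect padding), for normal estimation
# and structure tensors on small crops.
smooth2d <- function(m, sigma, trunc = 3) {
  m <- apply(m, 2L, smooth1d, sigma = sigma, trunc = trunc)
  t(apply(m, 1L, smooth1d, sigma = sigma, trunc = trunc))
}

# Bilinear interpolation of img (matrix, row = y, col = x; pixel centers at
# integer coordinates) at real-valued (x, y). Returns NA outside the field.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  x0 <- pmin(pmax(x0, 1L), nc - 1L); y0 <- pmin(pmax(y0, 1L), nr - 1L)
  v00 <- img[cbind(y0, x0)];     v01 <- img[cbind(y0, x0 + 1L)]
  v10 <- img[cbind(y0 + 1L, x0)]; v11 <- img[cbind(y0 + 1L, x0 + 1L)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
       fy       * ((1 - fx) * v10 + fx * v11)
  v[!ok] <- NA_real_
  v
}

# Sample standard deviation that tolerates length-1 input (returns 0).
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
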