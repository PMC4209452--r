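# Internal numeric helpers shared across modules.

.FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a deterministic per-stage substream seed from a global seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
substream_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 48271 + 1664525 * k) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_pos <- function(x, name) {
  if (!.is_num1(x) || x <= 0) .stopf("`%s` must be a single positive number", name)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!.is_num1(x) || x < 0) .stopf("`%s` must be a single nonnegative number", name)
  invisible(x)
}

# Truncated, discretely normalized 1-D Gaussian kernel (sums to 1).
.gauss_kernel <- function(sigma_px, trunc = 4) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(trunc * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# n x n banded blur operator with per-row renormalization at the edges,
# so constants are preserved exactly.
.blur_op <- function(n, sigma_px, trunc = 4) {
  k <- .gauss_kernel(sigma_px, trunc)
  r <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    w <- k[ok]
    B[i, j[ok]] <- w / sum(w)
  }
  B
}

# Separable 2-D Gaussian blur of a matrix, sigma in pixels, renormalized
# truncated kernel at the borders.
.blur2d <- function(m, sigma_px, trunc = 4) {
  if (sigma_px <= 0) return(m)
  Br <- .blur_op(nrow(m), sigma_px, trunc)
  Bc <- .blur_op(ncol(m), sigma_px, trunc)
  Br %*% m %*% t(Bc)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions
# expressed in pixel-index units (1-based pixel centers). Points outside
# the grid return `fill` (NA_real_ to signal out-of-field).
.interp2 <- function(m, ri, ci, fill = NA_real_) {
  H <- nrow(m); W <- ncol(m)
  out <- rep(fill, length(ri))
  tol <- 1e-6      # absorb rounding of exact-grid coordinates
  inside <- ri >= 1 - tol & ri <= H + tol & ci >= 1 - tol & ci <= W + tol
  if (!any(inside)) return(out)
  r <- pmin(pmax(ri[inside], 1), H)
  c <- pmin(pmax(ci[inside], 1), W)
  r0 <- pmin(pmax(floor(r), 1L), H - 1L)
  c0 <- pmin(pmax(floor(c), 1L), W - 1L)
  fr <- r - r0; fc <- c - c0
  v <- m[cbind(r0, c0)]     * (1 - fr) * (1 - fc) +
       m[cbind(r0 + 1, c0)] * fr       * (1 - fc) +
       m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
       m[cbind(r0 + 1, c0 + 1)] * fr   * fc
  out[inside] <- v
  out
}

# mm <-> fractional pixel index conversions for a centered image grid.
# Column j center is at x = (j - 0.5) * ps - W * ps / 2 (x increases with
# column, y with row); the inverse returns 1-based fractional indices.
.mm_to_col <- function(x_mm, W, ps) (x_mm + W * ps / 2) / ps + 0.5
.mm_to_row <- function(y_mm, H, ps) (y_mm + H * ps / 2) / ps + 0.5
.col_to_mm <- function(j, W, ps) (j - 0.5) * ps - W * ps / 2
.row_to_mm <- function(i, H, ps) (i - 0.5) * ps - H * ps / 2
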