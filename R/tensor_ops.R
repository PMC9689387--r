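# Dense tensor primitives for small CNNs on (H, W, C, N) arrays.
#
# Convolutions are evaluated by an im2col gather followed by a matrix
# multiply; the gather index matrix depends only on the spatial geometry, so
# callers that evaluate the same layer repeatedly (the spiking simulator runs
# every layer once per timestep) precompute it with `conv_im2col_index()`.

as_t4 <- function(x) {
  # promote (H,W) or (H,W,C) to (H,W,C,N)
  d <- dim(x)
  if (is.null(d)) stop("expected an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensional array", call. = FALSE)
  x
}

conv_out_dim <- function(n, k, stride, pad) {
  out <- (n + 2L * pad - k) %/% stride + 1L
  if (out < 1L) stop("kernel larger than padded input", call. = FALSE)
  out
}

#' @keywords internal
conv_im2col_index <- function(h, w, c, kh, kw, stride, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  oh <- conv_out_dim(h, kh, stride, pad)
  ow <- conv_out_dim(w, kw, stride, pad)
  pr <- rep((seq_len(oh) - 1L) * stride, times = ow)       # padded row offset
  pc <- rep((seq_len(ow) - 1L) * stride, each = oh)        # padded col offset
  kr <- rep(seq_len(kh), times = kw * c)
  kc <- rep(rep(seq_len(kw), each = kh), times = c)
  kch <- rep(seq_len(c), each = kh * kw)
  idx <- outer(pr, kr, `+`) + (outer(pc, kc, `+`) - 1L) * hp
  idx <- sweep(idx, 2L, (kch - 1L) * (hp * wp), `+`)
  storage.mode(idx) <- "integer"
  list(idx = idx, h = h, w = w, c = c, hp = hp, wp = wp,
       oh = oh, ow = ow, kh = kh, kw = kw, stride = stride, pad = pad)
}

pad_t4 <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# im2col over a batch: rows are (output position, image), columns kernel taps
im2col_t4 <- function(x, ix) {
  d <- dim(x)
  n <- d[4]
  xp <- pad_t4(x, ix$pad)
  per <- ix$hp * ix$wp * ix$c
  npos <- nrow(ix$idx)
  xv <- as.vector(xp)
  k <- ncol(ix$idx)
  if (n == 1L) {
    cols <- xv[ix$idx]
    dim(cols) <- c(npos, k)
    return(cols)
  }
  # gather column-by-column to bound transient allocations
  cols <- matrix(0, npos * n, k)
  off <- rep((seq_len(n) - 1L) * per, each = npos)
  for (q in seq_len(k)) {
    cols[, q] <- xv[rep(ix$idx[, q], n) + off]
  }
  cols
}

#' @keywords internal
conv2d_forward <- function(x, w, b, stride = 1L, pad = 0L, ix = NULL,
                           keep_cols = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  dw <- dim(w)  # (kh, kw, inC, outC)
  if (d[3] != dw[3]) {
    stop(sprintf("conv input has %d channels, weights expect %d", d[3], dw[3]),
         call. = FALSE)
  }
  if (is.null(ix)) {
    ix <- conv_im2col_index(d[1], d[2], d[3], dw[1], dw[2], stride, pad)
  }
  cols <- im2col_t4(x, ix)
  wm <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  out <- cols %*% wm
  out <- sweep(out, 2L, b, `+`)
  y <- array(out, c(ix$oh, ix$ow, d[4], dw[4]))     # (oh, ow, N, outC)
  y <- aperm(y, c(1L, 2L, 4L, 3L))                  # (oh, ow, outC, N)
  if (keep_cols) attr(y, "cols") <- cols
  attr(y, "ix") <- ix
  y
}

#' @keywords internal
conv2d_backward <- function(dy, x, w, ix, cols = NULL) {
  x <- as_t4(x); dy <- as_t4(dy)
  d <- dim(x); dw <- dim(w)
  n <- d[4]
  npos <- ix$oh * ix$ow
  if (is.null(cols)) cols <- im2col_t4(x, ix)
  g <- aperm(dy, c(1L, 2L, 4L, 3L))                 # (oh, ow, N, outC)
  g <- matrix(g, npos * n, dw[4])
  wm <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  dwm <- crossprod(cols, g)
  db <- colSums(g)
  dcols <- g %*% t(wm)
  # scatter-add back through the gather; within one kernel-tap column the
  # padded positions are distinct, so a per-column vectorised add is exact
  per <- ix$hp * ix$wp * ix$c
  dxp <- numeric(per * n)
  for (b in seq_len(n)) {
    off <- (b - 1L) * per
    rows <- (b - 1L) * npos + seq_len(npos)
    for (q in seq_len(ncol(ix$idx))) {
      tgt <- ix$idx[, q] + off
      dxp[tgt] <- dxp[tgt] + dcols[rows, q]
    }
  }
  dxp <- array(dxp, c(ix$hp, ix$wp, ix$c, n))
  p <- ix$pad
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dw = array(dwm, dw), db = db)
}

#' @keywords internal
upsample_nearest <- function(x, factor = 2L) {
  x <- as_t4(x)
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  x[ri, ci, , , drop = FALSE]
}

#' @keywords internal
upsample_nearest_backward <- function(dy, factor = 2L) {
  dy <- as_t4(dy)
  d <- dim(dy)
  oh <- d[1] %/% factor
  ow <- d[2] %/% factor
  ri <- rep(seq_len(oh), each = factor)
  ci <- rep(seq_len(ow), each = factor)
  dx <- array(0, c(oh, ow, d[3], d[4]))
  # accumulate the factor^2 replicated cells
  for (a in seq_len(factor)) {
    for (b in seq_len(factor)) {
      dx <- dx + dy[seq(a, by = factor, length.out = oh),
                    seq(b, by = factor, length.out = ow), , , drop = FALSE]
    }
  }
  dx
}

# Batch normalisation over (H, W, N) per channel.
bn_forward <- function(x, gamma, beta, mu, sigma2, eps = 1e-5,
                       training = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
  if (training) {
    mu <- colMeans(xm)
    sigma2 <- colMeans(sweep(xm, 2L, mu, `-`)^2)
  }
  inv <- 1 / sqrt(sigma2 + eps)
  xhat <- sweep(sweep(xm, 2L, mu, `-`), 2L, inv, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  list(y = y, xhat = xhat, inv = inv, mu = mu, sigma2 = sigma2)
}

bn_backward <- function(dy, cache, gamma) {
  dy <- as_t4(dy)
  d <- dim(dy)
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = d[3])
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), `-`)
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dxm <- sweep(t1 - t2, 2L, cache$inv, `*`)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
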