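# shared helpers for the test suite; all fixtures are generated in code

hexring <- function(n) {
  ab <- NULL
  for (a in -n:n) for (b in -n:n) if (abs(a + b) <= n) ab <- rbind(ab, c(a, b))
  ab
}

zncc_scalar <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# naive sliding-window ZNCC argmax (independent oracle for the FFT matcher)
zncc_brute_argmax <- function(img, tmpl) {
  H <- nrow(img); W <- ncol(img); h <- nrow(tmpl); w <- ncol(tmpl)
  t0 <- tmpl - mean(tmpl); tn <- sqrt(sum(t0^2))
  best <- -Inf; arg <- c(NA, NA)
  for (y in 1:(H - h + 1)) for (x in 1:(W - w + 1)) {
    p <- img[y:(y + h - 1), x:(x + w - 1)]
    p0 <- p - mean(p)
    dn <- sqrt(sum(p0^2)) * tn
    v <- if (dn > 0) sum(p0 * t0) / dn else -Inf
    if (v > best) { best <- v; arg <- c(y, x) }
  }
  list(peak = best, arg = arg)   # 1-based (row, col) of template top-left
}

# dense weighted minimum-norm least-squares oracle for difference systems
dense_lss_oracle <- function(n_nodes, src, dst, delta, w = NULL) {
  m <- length(src)
  if (is.null(w)) w <- rep(1, m)
  A <- matrix(0, m, n_nodes)
  for (e in seq_len(m)) { A[e, dst[e]] <- 1; A[e, src[e]] <- -1 }
  x <- MASS::ginv(A * sqrt(w)) %*% (as.matrix(delta) * sqrt(w))
  sweep(x, 2, colMeans(x))
}

rigid_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}
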