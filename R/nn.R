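## Minimal dense-network machinery with hand-written reverse-mode
## vector-Jacobian products. All "MLPs" in the package are two-hidden-layer
## SiLU networks; caches from the forward pass feed the matching backward
## pass. Parameters are plain nested lists of numerics so they can be
## flattened with unlist()/relist() for the optimizer.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.silu <- function(x) x / (1 + exp(-x))
.silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# add a bias vector to every row (column-major recycling; avoids sweep)
.addbias <- function(m, b) m + rep(b, each = nrow(m))

# Gaussian init scaled by fan-in; final layer optionally zeroed
.mlp_init <- function(d_in, hidden, d_out, rng, zero_final = FALSE) {
  draw <- function(nr, nc) matrix(rng(nr * nc) / sqrt(nr), nr, nc)
  p <- list(
    w1 = draw(d_in, hidden),  b1 = numeric(hidden),
    w2 = draw(hidden, hidden), b2 = numeric(hidden),
    w3 = if (zero_final) matrix(0, hidden, d_out) else draw(hidden, d_out),
    b3 = numeric(d_out)
  )
  p
}

.mlp_forward <- function(p, x) {
  z1 <- .addbias(x %*% p$w1, p$b1)
  a1 <- .silu(z1)
  z2 <- .addbias(a1 %*% p$w2, p$b2)
  a2 <- .silu(z2)
  out <- .addbias(a2 %*% p$w3, p$b3)
  list(out = out, x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

# input gradient only (force evaluation does not need parameter gradients)
.mlp_backward_x <- function(p, cache, gout) {
  gz2 <- (gout %*% t(p$w3)) * .silu_grad(cache$z2)
  gz1 <- (gz2 %*% t(p$w2)) * .silu_grad(cache$z1)
  list(gx = gz1 %*% t(p$w1), gp = NULL)
}

# returns gradient w.r.t. input plus a parameter-gradient list mirroring p
.mlp_backward <- function(p, cache, gout) {
  gb3 <- colSums(gout)
  gw3 <- crossprod(cache$a2, gout)
  ga2 <- gout %*% t(p$w3)
  gz2 <- ga2 * .silu_grad(cache$z2)
  gb2 <- colSums(gz2)
  gw2 <- crossprod(cache$a1, gz2)
  ga1 <- gz2 %*% t(p$w2)
  gz1 <- ga1 * .silu_grad(cache$z1)
  gb1 <- colSums(gz1)
  gw1 <- crossprod(cache$x, gz1)
  gx <- gz1 %*% t(p$w1)
  list(gx = gx,
       gp = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2, w3 = gw3, b3 = gb3))
}

# zero-filled gradient skeleton for an arbitrary nested numeric param list
.zero_like <- function(p) {
  if (is.list(p)) lapply(p, .zero_like)
  else p * 0
}

# elementwise addition of two identically shaped nested lists
.add_params <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- .add_params(a[[k]], b[[k]])
    a
  } else a + b
}

# aggregate rows of x by integer group id, into a matrix with nlev rows
# (groups without members stay zero)
.rowsum_to <- function(x, group, nlev) {
  rs <- rowsum(x, group)
  out <- matrix(0, nlev, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}
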