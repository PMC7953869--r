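# Low-level neural-network primitives for the 3D VGG-style sub-networks.
#
# Tensor layout is (X, Y, Z, B, C) column-major, so the matrix view
# (X*Y*Z*B) x C shares memory with the array and convolution reduces to
# im2col (compiled) followed by a BLAS matrix product.  Backward passes are
# hand-derived; a finite-difference check in the test suite guards them.

leaky_relu <- function(x, alpha = 0.1) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  x
}

leaky_relu_grad <- function(pre, alpha = 0.1) {
  g <- rep(1, length(pre))
  g[pre < 0] <- alpha
  g
}

#' Xavier (Glorot) uniform initialisation
#' @param fan_in,fan_out effective input/output connectivity of the layer
#' @param dim dimensions of the weight array to draw
#' @return array of the requested shape
#' @keywords internal
xavier_init <- function(fan_in, fan_out, dim) {
  a <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -a, a), dim = dim)
}

## ---- convolution -----------------------------------------------------------

conv3d_forward <- function(x, dims, W, b, k, alpha = 0.1) {
  # x: numeric vector viewed as (X,Y,Z,B,Cin); W: (k1*k2*k3*Cin) x Cout
  r <- conv3d_fwd_direct(x, dims, W, b, k[1], k[2], k[3], alpha)
  list(out = r$out,
       dims = c(dims[1:4], ncol(W)),
       cache = list(x = x, neg = r$neg, in_dims = dims, k = k))
}

conv3d_backward <- function(d_out, cache, W, alpha = 0.1) {
  # d_out: numeric vector shaped like the layer output
  conv3d_bwd_direct(d_out, cache$neg, cache$x, cache$in_dims, W,
                    cache$k[1], cache$k[2], cache$k[3], alpha)
}

## ---- pooling ---------------------------------------------------------------

# Output window-centre positions for one axis (0-based).  In-plane stride-2
# pooling maps n -> ceiling(n/2); depth stride-2 pooling maps
# z -> floor(z/2) + 1 (window centres at every even index including z when z
# is even, border windows clipped); stride 1 preserves the axis.
pool_centres <- function(n, stride, depth_axis = FALSE) {
  if (stride == 1L) return(seq.int(0L, n - 1L))
  if (depth_axis) seq.int(0L, by = 2L, length.out = n %/% 2L + 1L)
  else seq.int(0L, by = 2L, length.out = ceiling(n / 2))
}

maxpool_forward <- function(x, dims, stride_z = 1L, kz = 1L) {
  cx <- pool_centres(dims[1], 2L)
  cy <- pool_centres(dims[2], 2L)
  cz <- pool_centres(dims[3], stride_z, depth_axis = TRUE)
  half_z <- as.integer(kz %/% 2L)
  r <- maxpool3d_fwd(x, dims, cx, cy, cz, half_z)
  out_dims <- c(length(cx), length(cy), length(cz), dims[4], dims[5])
  list(out = r$out, dims = out_dims,
       cache = list(argmax = r$argmax, n_in = prod(dims)))
}

maxpool_backward <- function(d_out, cache) {
  maxpool3d_bwd(d_out, cache$argmax, cache$n_in)
}

## ---- global average pooling ------------------------------------------------

gap_forward <- function(x, dims) {
  nvox <- prod(dims[1:3])
  m <- matrix(x, nrow = nvox)            # nvox x (B*C)
  f <- matrix(colMeans(m), nrow = dims[4])  # B x C
  list(out = f, cache = list(dims = dims, nvox = nvox))
}

gap_backward <- function(d_f, cache) {
  # d_f: B x C -> spread evenly over voxels
  rep(as.numeric(d_f), each = cache$nvox) / cache$nvox
}

## ---- dense layers ----------------------------------------------------------

dense_forward <- function(x, W, b, activation = c("leaky", "linear"),
                          alpha = 0.1) {
  activation <- match.arg(activation)
  pre <- x %*% W + rep(b, each = nrow(x))
  out <- if (activation == "leaky") leaky_relu(pre, alpha) else pre
  list(out = out, cache = list(x = x, pre = pre, activation = activation))
}

dense_backward <- function(d_out, cache, W, alpha = 0.1) {
  dpre <- if (cache$activation == "leaky")
    d_out * leaky_relu_grad(cache$pre, alpha) else d_out
  list(dx = tcrossprod(dpre, W),
       gW = crossprod(cache$x, dpre),
       gb = colSums(dpre))
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- matrix(stats::rbinom(length(x), 1L, 1 - p), nrow = nrow(x)) / (1 - p)
  list(out = x * keep, cache = keep)
}

dropout_backward <- function(d_out, cache) {
  if (is.null(cache)) d_out else d_out * cache
}

## ---- softmax / cross-entropy -----------------------------------------------

softmax_rows <- function(L) {
  m <- pmax(L[, 1], L[, 2])
  e1 <- exp(L[, 1] - m); e2 <- exp(L[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# Numerically stable per-sample cross-entropy from 2-class logits.
# y: 0 = insignificant, 1 = significant (class column 2).
ce_from_logits <- function(L, y) {
  m <- pmax(L[, 1], L[, 2])
  lse <- m + log(exp(L[, 1] - m) + exp(L[, 2] - m))
  lse - ifelse(y == 1, L[, 2], L[, 1])
}

onehot_labels <- function(y) cbind(1 - y, y)

## ---- optimiser -------------------------------------------------------------

sgd_momentum_step <- function(params, grads, velocity, lr, momentum,
                              maxnorm_keys = character(), maxnorm = Inf,
                              grad_clip = Inf) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.finite(grad_clip)) {
      gn <- sqrt(sum(g^2))
      if (gn > grad_clip) g <- g * (grad_clip / gn)
    }
    v <- velocity[[nm]]
    if (is.null(v)) v <- array(0, dim = dim(params[[nm]]) %||% length(params[[nm]]))
    v <- momentum * v - lr * g
    params[[nm]] <- params[[nm]] + v
    velocity[[nm]] <- v
  }
  # max-norm constraint on the incoming-weight vector of each dense unit
  if (is.finite(maxnorm)) {
    for (nm in maxnorm_keys) {
      W <- params[[nm]]
      norms <- sqrt(colSums(W^2))
      over <- norms > maxnorm
      if (any(over))
        W[, over] <- sweep(W[, over, drop = FALSE], 2,
                           maxnorm / norms[over], `*`)
      params[[nm]] <- W
    }
  }
  list(params = params, velocity = velocity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
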