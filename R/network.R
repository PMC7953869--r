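# Architecture: parameterised VGG-style 3D sub-networks, the common model
# architecture (CMA) producing three modality-specific 32-element feature
# vectors, and the two classifier heads M1 (plain decision-level fusion)
# and M2 (PI-RADS zone-routed logits with auxiliary classifiers).

#' Symbolic sub-network specification
#'
#' Describes one VGG-style 3D modality sub-network.  Kernels are 3 x 3 x 1
#' except the final convolution block (3 x 3 x 3); the first pooling layers
#' have depth stride 1 and the last depth stride 2, reflecting the coarse
#' slice spacing of mpMRI.  T2W sub-networks carry an extra initial
#' convolution-pooling block (at c/2 channels) owing to the finer in-plane
#' resolution of T2W.
#'
#' @param c base channel count (even); the sub-network output length is `2c`
#' @param extra_block logical; `TRUE` for T2W sub-networks
#' @return object of class `subnet_spec`: list of layer descriptors
#' @export
subnet_spec <- function(c = 16L, extra_block = FALSE) {
  stopifnot(c %% 2 == 0, c >= 2)
  layers <- list()
  if (extra_block) {
    layers <- c(layers, list(
      list(id = "Conv 0_1", op = "conv", k = c(3L, 3L, 1L), channels = c %/% 2L),
      list(id = "Conv 0_2", op = "conv", k = c(3L, 3L, 1L), channels = c %/% 2L),
      list(id = "Pool 0", op = "pool", k = c(3L, 3L, 1L), stride_z = 1L)))
  }
  layers <- c(layers, list(
    list(id = "Conv 1_1", op = "conv", k = c(3L, 3L, 1L), channels = c),
    list(id = "Conv 1_2", op = "conv", k = c(3L, 3L, 1L), channels = c),
    list(id = "Pool 1", op = "pool", k = c(3L, 3L, 1L), stride_z = 1L),
    list(id = "Conv 2_1", op = "conv", k = c(3L, 3L, 3L), channels = 2L * c),
    list(id = "Conv 2_2", op = "conv", k = c(3L, 3L, 3L), channels = 2L * c),
    list(id = "Conv 2_3", op = "conv", k = c(3L, 3L, 3L), channels = 2L * c),
    list(id = "Pool 2", op = "pool", k = c(3L, 3L, 3L), stride_z = 2L),
    list(id = "FC", op = "gap", channels = 2L * c)))
  structure(list(c = as.integer(c), extra_block = extra_block,
                 layers = layers), class = "subnet_spec")
}

#' Trace layer output shapes through a sub-network
#'
#' Symbolic shape inference for [subnet_spec()]: convolutions use "same"
#' padding and preserve spatial dimensions; stride-2 in-plane pooling maps
#' `n -> ceiling(n/2)`; the final pooling layer additionally maps depth
#' `z -> floor(z/2) + 1`; the global average pool emits a `2c` vector.
#'
#' @param spec a [subnet_spec()]
#' @param input integer 3-vector (width, height, depth) of the input VOI
#' @return data.frame with one row per layer: layer id, width, height,
#'   depth, channels (the FC row gives the feature-vector length in
#'   `channels` with spatial dims NA)
#' @export
#' @examples
#' infer_shapes(subnet_spec(16, extra_block = TRUE), c(60, 60, 10))
infer_shapes <- function(spec, input) {
  stopifnot(inherits(spec, "subnet_spec"), length(input) == 3L,
            all(input >= 1))
  w <- input[1]; h <- input[2]; z <- input[3]
  ch <- 1L
  rows <- lapply(spec$layers, function(ly) {
    if (ly$op == "conv") {
      ch <<- ly$channels
    } else if (ly$op == "pool") {
      if (w < 2 || h < 2)
        stop("input too small: in-plane dimension below 2 entering ", ly$id)
      w <<- ceiling(w / 2); h <<- ceiling(h / 2)
      if (ly$stride_z == 2L) z <<- z %/% 2L + 1L
      if (z < 1) stop("input too small: depth vanished at ", ly$id)
    } else if (ly$op == "gap") {
      return(data.frame(layer = ly$id, width = NA_integer_,
                        height = NA_integer_, depth = NA_integer_,
                        channels = ly$channels))
    }
    data.frame(layer = ly$id, width = w, height = h, depth = z, channels = ch)
  })
  do.call(rbind, rows)
}

## ---- parameter construction ------------------------------------------------

.subnet_keys <- function(spec) {
  vapply(Filter(function(l) l$op == "conv", spec$layers),
         function(l) gsub(" ", "", tolower(l$id)), character(1))
}

init_subnet_params <- function(prefix, spec) {
  params <- list()
  cin <- 1L
  for (ly in spec$layers) {
    if (ly$op != "conv") next
    key <- paste0(prefix, ".", gsub(" ", "", tolower(ly$id)))
    kk <- prod(ly$k)
    params[[paste0(key, ".W")]] <-
      xavier_init(kk * cin, kk * ly$channels, c(kk * cin, ly$channels))
    params[[paste0(key, ".b")]] <- numeric(ly$channels)
    cin <- ly$channels
  }
  params
}

init_dense_params <- function(key, n_in, n_out) {
  p <- list()
  p[[paste0(key, ".W")]] <- xavier_init(n_in, n_out, c(n_in, n_out))
  p[[paste0(key, ".b")]] <- numeric(n_out)
  p
}

#' Build the common model architecture (CMA)
#'
#' Six VGG-style 3D sub-networks process the six VOIs in parallel (three
#' T2W planes with the extra convolution block, DWI, ADC, K-Trans).  Within
#' each modality group (T2, DWI-ADC, DCE) the sub-network outputs are
#' concatenated with the five-element zone code and passed through a hidden
#' dense layer and a final dense layer emitting a 32-element
#' modality-specific feature vector.  Dropout and L2 regularisation act on
#' the dense layers.
#'
#' @param c base channel count; the default 16 makes each sub-network output
#'   `2c = 32` elements
#' @param hidden width of the hidden dense layer per modality group
#' @param feature_dim length of each modality feature vector
#' @param dropout dropout probability on hidden dense layers
#' @param alpha leaky-ReLU negative slope
#' @return object of class `cma`: specs, parameters and configuration
#' @export
build_cma <- function(c = 16L, hidden = 64L, feature_dim = 32L,
                      dropout = 0.125, alpha = 0.1) {
  spec_t2 <- subnet_spec(c, extra_block = TRUE)
  spec_fn <- subnet_spec(c, extra_block = FALSE)
  specs <- list(T2W_tra = spec_t2, T2W_sag = spec_t2, T2W_cor = spec_t2,
                DWI = spec_fn, ADC = spec_fn, KTRANS = spec_fn)
  params <- list()
  for (m in MODALITIES) params <- c(params, init_subnet_params(m, specs[[m]]))
  fv <- 2L * c
  group_in <- c(t2 = 3L * fv + 5L, da = 2L * fv + 5L, dce = fv + 5L)
  for (g in names(group_in)) {
    params <- c(params,
                init_dense_params(paste0(g, ".fc1"), group_in[[g]], hidden),
                init_dense_params(paste0(g, ".fc2"), hidden, feature_dim))
  }
  structure(list(c = as.integer(c), hidden = as.integer(hidden),
                 feature_dim = as.integer(feature_dim), dropout = dropout,
                 alpha = alpha, specs = specs, params = params,
                 group_in = group_in, feature_scale = NULL),
            class = "cma")
}

#' Build classifier model M1 (plain decision-level fusion)
#'
#' Concatenates the three 32-element modality feature vectors and applies a
#' dense softmax layer over the two classes.
#'
#' @param cma a [build_cma()] object
#' @return object of class `mpcnn_model`
#' @export
build_m1 <- function(cma = build_cma()) {
  params <- c(cma$params,
              init_dense_params("head", 3L * cma$feature_dim, 2L))
  structure(c(cma[setdiff(names(cma), "params")],
              list(kind = "M1", params = params)),
            class = "mpcnn_model")
}

#' Build classifier model M2 (PI-RADS knowledge-encoded)
#'
#' Appends an auxiliary classifier (dense 2-class logit layer) behind each
#' of the three modality feature vectors.  The final prediction NET-out is
#' the softmax of the zone-routed mean of two auxiliary logit vectors (see
#' [route_logits()]).  During training the auxiliary softmax heads
#' contribute weighted losses; at inference their standalone predictions are
#' discarded, but their logit layers persist as the routing sources.
#'
#' @inheritParams build_m1
#' @return object of class `mpcnn_model`
#' @export
build_m2 <- function(cma = build_cma()) {
  params <- c(cma$params,
              init_dense_params("aux_t2", cma$feature_dim, 2L),
              init_dense_params("aux_da", cma$feature_dim, 2L),
              init_dense_params("aux_dce", cma$feature_dim, 2L))
  structure(c(cma[setdiff(names(cma), "params")],
              list(kind = "M2", params = params)),
            class = "mpcnn_model")
}

#' @export
print.mpcnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<mpcnn model %s  c = %d  %d parameters>\n", x$kind, x$c, np))
  cat(if (x$kind == "M1")
    "  decision-level fusion: concat(3 x 32 features) -> softmax\n"
    else
      "  PI-RADS routing: softmax(mean of two zone-selected auxiliary logit vectors)\n")
  invisible(x)
}

# dense layers subject to L2 regularisation and the max-norm constraint
l2_keys <- function(model) {
  ks <- c("t2.fc1.W", "t2.fc2.W", "da.fc1.W", "da.fc2.W",
          "dce.fc1.W", "dce.fc2.W")
  if (model$kind == "M1") c(ks, "head.W")
  else c(ks, "aux_t2.W", "aux_da.W", "aux_dce.W")
}

## ---- forward / backward ----------------------------------------------------

subnet_forward <- function(params, prefix, spec, x, dims, alpha) {
  caches <- list()
  for (ly in spec$layers) {
    if (ly$op == "conv") {
      key <- paste0(prefix, ".", gsub(" ", "", tolower(ly$id)))
      r <- conv3d_forward(x, dims, params[[paste0(key, ".W")]],
                          params[[paste0(key, ".b")]], ly$k, alpha)
      caches[[length(caches) + 1L]] <- list(op = "conv", key = key,
                                            k = ly$k, cache = r$cache)
    } else if (ly$op == "pool") {
      r <- maxpool_forward(x, dims, stride_z = ly$stride_z,
                           kz = ly$k[3])
      caches[[length(caches) + 1L]] <- list(op = "pool", cache = r$cache)
    } else {  # gap
      r <- gap_forward(x, dims)
      caches[[length(caches) + 1L]] <- list(op = "gap", cache = r$cache)
      return(list(out = r$out, caches = caches))
    }
    x <- r$out
    dims <- r$dims
  }
  stop("sub-network spec missing its global average pool")
}

subnet_backward <- function(params, grads, spec, caches, d_feat, alpha) {
  d <- d_feat
  for (i in rev(seq_along(caches))) {
    ly <- caches[[i]]
    if (ly$op == "gap") {
      d <- gap_backward(d, ly$cache)
    } else if (ly$op == "pool") {
      d <- maxpool_backward(d, ly$cache)
    } else {
      W <- params[[paste0(ly$key, ".W")]]
      r <- conv3d_backward(d, ly$cache, W, alpha)
      grads[[paste0(ly$key, ".W")]] <- (grads[[paste0(ly$key, ".W")]] %||% 0) + r$gW
      grads[[paste0(ly$key, ".b")]] <- (grads[[paste0(ly$key, ".b")]] %||% 0) + r$gb
      d <- r$dx
    }
  }
  grads
}

group_dense_forward <- function(params, g, x, dropout, alpha, train) {
  f1 <- dense_forward(x, params[[paste0(g, ".fc1.W")]],
                      params[[paste0(g, ".fc1.b")]], "leaky", alpha)
  d1 <- dropout_forward(f1$out, dropout, train)
  f2 <- dense_forward(d1$out, params[[paste0(g, ".fc2.W")]],
                      params[[paste0(g, ".fc2.b")]], "leaky", alpha)
  d2 <- dropout_forward(f2$out, dropout, train)
  list(out = d2$out, cache = list(f1 = f1$cache, d1 = d1$cache,
                                  f2 = f2$cache, d2 = d2$cache))
}

group_dense_backward <- function(params, grads, g, cache, d_out, alpha) {
  d <- dropout_backward(d_out, cache$d2)
  r2 <- dense_backward(d, cache$f2, params[[paste0(g, ".fc2.W")]], alpha)
  grads[[paste0(g, ".fc2.W")]] <- (grads[[paste0(g, ".fc2.W")]] %||% 0) + r2$gW
  grads[[paste0(g, ".fc2.b")]] <- (grads[[paste0(g, ".fc2.b")]] %||% 0) + r2$gb
  d <- dropout_backward(r2$dx, cache$d1)
  r1 <- dense_backward(d, cache$f1, params[[paste0(g, ".fc1.W")]], alpha)
  grads[[paste0(g, ".fc1.W")]] <- (grads[[paste0(g, ".fc1.W")]] %||% 0) + r1$gW
  grads[[paste0(g, ".fc1.b")]] <- (grads[[paste0(g, ".fc1.b")]] %||% 0) + r1$gb
  list(grads = grads, dx = r1$dx)
}

# group membership of the six sub-networks
.GROUPS <- list(t2 = c("T2W_tra", "T2W_sag", "T2W_cor"),
                da = c("DWI", "ADC"),
                dce = "KTRANS")

#' Forward pass of the common model architecture
#'
#' @param model an `mpcnn_model` (or `cma`)
#' @param batch a batch as produced by `batch_tensors()`
#' @param train logical; enables dropout
#' @return list with `features` (list of three B x 32 matrices: t2, da, dce)
#'   and `cache` for the backward pass
#' @keywords internal
forward_cma <- function(model, batch, train = FALSE) {
  params <- model$params
  B <- nrow(batch$zone)
  feats <- list(); caches <- list()
  for (m in MODALITIES) {
    x <- batch$vols[[m]]
    r <- subnet_forward(params, m, model$specs[[m]], as.numeric(x), dim(x),
                        model$alpha)
    f <- r$out
    if (!is.null(model$feature_scale)) {
      fs <- model$feature_scale[[m]]
      f <- (f - rep(fs$mean, each = B)) / rep(fs$sd, each = B)
    }
    feats[[m]] <- f
    caches[[m]] <- r$caches
  }
  features <- list(); gcaches <- list(); gconcat <- list()
  for (g in names(.GROUPS)) {
    xin <- do.call(cbind, c(feats[.GROUPS[[g]]], list(batch$zone)))
    r <- group_dense_forward(params, g, xin, model$dropout, model$alpha, train)
    features[[g]] <- r$out
    gcaches[[g]] <- r$cache
    gconcat[[g]] <- ncol(xin)
  }
  list(features = features,
       cache = list(subnets = caches, groups = gcaches, B = B))
}

# Backward through the CMA given d features per group; returns grads.
backward_cma <- function(model, grads, cache, d_features) {
  params <- model$params
  fv <- 2L * model$c
  for (g in names(.GROUPS)) {
    r <- group_dense_backward(params, grads, g, cache$groups[[g]],
                              d_features[[g]], model$alpha)
    grads <- r$grads
    mods <- .GROUPS[[g]]
    for (j in seq_along(mods)) {
      m <- mods[j]
      d_feat <- r$dx[, ((j - 1L) * fv + 1L):(j * fv), drop = FALSE]
      if (!is.null(model$feature_scale))
        d_feat <- d_feat / rep(model$feature_scale[[m]]$sd,
                               each = nrow(d_feat))
      grads <- subnet_backward(params, grads, model$specs[[m]],
                               cache$subnets[[m]], d_feat, model$alpha)
    }
    # gradient w.r.t. the zone one-hot is discarded (input, not a parameter)
  }
  grads
}

#' Calibrate the sub-network feature standardisation
#'
#' The global-average-pooled sub-network outputs have a data-dependent and
#' typically very small scale; feeding them raw into the dense stack makes
#' the optimisation badly conditioned.  Before training, fixed per-feature
#' affine constants (mean, s.d.) are computed over (a subset of) the
#' training samples at the initial weights and frozen, so the modality
#' features enter the dense layers approximately zero-mean unit-variance.
#' This is input standardisation for the dense stack, computed once; it is
#' not a batch-dependent normalisation layer.
#'
#' @param model an `mpcnn_model`
#' @param samples training samples used for calibration
#' @param n_max maximum number of samples used
#' @param batch_size forward-pass batch size
#' @return the model with `feature_scale` set
#' @export
calibrate_feature_scale <- function(model, samples, n_max = 160L,
                                    batch_size = 32L) {
  use <- samples[seq_len(min(length(samples), n_max))]
  acc <- stats::setNames(vector("list", length(MODALITIES)), MODALITIES)
  idx <- split(seq_along(use), ceiling(seq_along(use) / batch_size))
  for (ii in idx) {
    b <- batch_tensors(use[ii])
    for (m in MODALITIES) {
      x <- b$vols[[m]]
      r <- subnet_forward(model$params, m, model$specs[[m]], as.numeric(x),
                          dim(x), model$alpha)
      acc[[m]] <- rbind(acc[[m]], r$out)
    }
  }
  model$feature_scale <- lapply(acc, function(f)
    list(mean = colMeans(f), sd = pmax(apply(f, 2, stats::sd), 1e-8)))
  model
}

#' Forward pass of a classifier model
#'
#' @param model an `mpcnn_model`
#' @param batch a batch as produced by `batch_tensors()`
#' @param train logical; enables dropout
#' @return list with `probs` (B x 2 softmax matrix, column 2 = significant),
#'   per-head `logits`, and `cache`
#' @keywords internal
forward_model <- function(model, batch, train = FALSE) {
  fw <- forward_cma(model, batch, train)
  params <- model$params
  if (model$kind == "M1") {
    xin <- do.call(cbind, fw$features)
    hd <- dense_forward(xin, params[["head.W"]], params[["head.b"]], "linear")
    list(probs = softmax_rows(hd$out), logits = list(net = hd$out),
         cache = list(cma = fw$cache, head = hd$cache, features = fw$features))
  } else {
    aux <- list(
      t2 = dense_forward(fw$features$t2, params[["aux_t2.W"]],
                         params[["aux_t2.b"]], "linear"),
      da = dense_forward(fw$features$da, params[["aux_da.W"]],
                         params[["aux_da.b"]], "linear"),
      dce = dense_forward(fw$features$dce, params[["aux_dce.W"]],
                          params[["aux_dce.b"]], "linear"))
    pz <- batch$zones == "PZ"
    routed <- 0.5 * (aux$da$out +
                       ifelse(matrix(pz, nrow(aux$da$out), 2L),
                              aux$dce$out, aux$t2$out))
    list(probs = softmax_rows(routed),
         logits = list(net = routed, t2 = aux$t2$out, da = aux$da$out,
                       dce = aux$dce$out),
         cache = list(cma = fw$cache, aux = lapply(aux, `[[`, "cache"),
                      pz = pz, features = fw$features))
  }
}
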