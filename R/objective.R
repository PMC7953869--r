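# Composite training objective: weighted average of sub-network
# cross-entropies (weights depending on model kind and lesion stream) plus a
# scaled L2 penalty,
#
#   l(x) = sum_i(l_i * w_i) / sum_i(w_i) + 0.1 * l_L2 / n_L2 .

# (sub-network, stream) -> minor-loss weight for model M2.  NET is
# stream-independent; the dominant sequence of each stream gets the larger
# auxiliary weight, the complementary one a small nonzero weight so its
# features keep training.
.M2_WEIGHTS <- list(
  PZ_stream = c(NET = 100, DCE = 20, T2 = 5, DWI_ADC = 12.5),
  TZ_stream = c(NET = 100, DCE = 5, T2 = 20, DWI_ADC = 12.5))

#' Minor-loss weights for a model kind and lesion zone
#'
#' M1 trains only the whole-network output (weight 100).  M2 additionally
#' trains the three auxiliary classifiers with zone-dependent weights: for
#' peripheral-zone lesions DCE = 20, T2 = 5; for transition-zone lesions
#' (including AFS, SV and CZ, which follow the TZ rules) DCE = 5, T2 = 20;
#' DWI_ADC = 12.5 for both.  The weights are not normalised.
#'
#' @param model_kind `"M1"` or `"M2"`
#' @param zone zone label (see [ZONES])
#' @return named numeric vector of (output id -> weight)
#' @export
#' @examples
#' minor_weights("M2", "PZ")
#' minor_weights("M2", "AFS")  # TZ column
minor_weights <- function(model_kind, zone) {
  model_kind <- match.arg(model_kind, c("M1", "M2"))
  if (model_kind == "M1") return(c(NET = 100))
  .M2_WEIGHTS[[stream_for_zone(zone)]]
}

#' Composite loss for one sample
#'
#' `sum(minor_losses * weights) / sum(weights) + 0.1 * l2_loss / n_l2`.
#' Invariant to rescaling all weights by a positive constant.
#'
#' @param minor_losses numeric vector of per-output cross-entropies
#' @param weights matching numeric vector of minor-loss weights
#' @param l2_loss total L2 regularisation loss over regulated layers
#' @param n_l2 number of L2-regulated layers
#' @return scalar loss
#' @export
#' @examples
#' composite_loss(c(0.6, 0.5, 0.7, 0.4), minor_weights("M2", "PZ"))
composite_loss <- function(minor_losses, weights, l2_loss = 0, n_l2 = 1L) {
  if (length(minor_losses) != length(weights))
    stop("minor_losses and weights must align (",
         length(minor_losses), " vs ", length(weights), ")")
  stopifnot(all(weights > 0), sum(weights) > 0, n_l2 >= 1L)
  sum(minor_losses * weights) / sum(weights) + 0.1 * l2_loss / n_l2
}

#' Mini-batch composite loss
#'
#' Per-sample composite losses are computed with each sample's own
#' zone-dependent weights and averaged over the mini-batch; the L2 term is
#' added once per batch, not per sample.
#'
#' @param minor_losses list (one element per sample) of numeric vectors
#' @param zones character vector of zone labels, one per sample
#' @param model_kind `"M1"` or `"M2"`
#' @inheritParams composite_loss
#' @return scalar batch loss
#' @export
batch_loss <- function(minor_losses, zones, model_kind = "M2",
                       l2_loss = 0, n_l2 = 1L) {
  if (length(minor_losses) == 0L) stop("empty mini-batch")
  if (length(minor_losses) != length(zones))
    stop("one zone label is required per sample")
  per_sample <- mapply(function(l, z)
    composite_loss(l, minor_weights(model_kind, z)),
    minor_losses, zones)
  mean(per_sample) + 0.1 * l2_loss / n_l2
}

## ---- loss + gradients for training ----------------------------------------

l2_penalty <- function(model) {
  ks <- l2_keys(model)
  list(loss = sum(vapply(ks, function(k) sum(model$params[[k]]^2),
                         numeric(1))),
       n = length(ks), keys = ks)
}

# Full forward + loss + parameter gradients for one mini-batch.
# Returns list(loss, probs, grads).
model_loss_grads <- function(model, batch, train = TRUE) {
  fw <- forward_model(model, batch, train)
  B <- length(batch$labels)
  y <- batch$labels
  Y <- onehot_labels(y)
  l2 <- l2_penalty(model)
  grads <- list()

  if (model$kind == "M1") {
    # single minor loss (NET) with weight 100: the weighted average is the
    # plain cross-entropy
    L <- fw$logits$net
    loss <- mean(ce_from_logits(L, y)) + 0.1 * l2$loss / l2$n
    dlog <- (softmax_rows(L) - Y) / B
    r <- dense_backward(dlog, fw$cache$head, model$params[["head.W"]])
    grads[["head.W"]] <- r$gW
    grads[["head.b"]] <- r$gb
    fd <- model$feature_dim
    d_features <- list(t2 = r$dx[, 1:fd, drop = FALSE],
                       da = r$dx[, (fd + 1):(2 * fd), drop = FALSE],
                       dce = r$dx[, (2 * fd + 1):(3 * fd), drop = FALSE])
  } else {
    pz <- fw$cache$pz
    wtab <- t(vapply(batch$zones, function(z) minor_weights("M2", z),
                     numeric(4)))        # B x (NET, DCE, T2, DWI_ADC)
    wsum <- rowSums(wtab)
    l_net <- ce_from_logits(fw$logits$net, y)
    l_dce <- ce_from_logits(fw$logits$dce, y)
    l_t2 <- ce_from_logits(fw$logits$t2, y)
    l_da <- ce_from_logits(fw$logits$da, y)
    per_sample <- (l_net * wtab[, "NET"] + l_dce * wtab[, "DCE"] +
                     l_t2 * wtab[, "T2"] + l_da * wtab[, "DWI_ADC"]) / wsum
    loss <- mean(per_sample) + 0.1 * l2$loss / l2$n

    scale <- 1 / (B * wsum)
    d_net <- (softmax_rows(fw$logits$net) - Y) * (wtab[, "NET"] * scale)
    d_dce <- (softmax_rows(fw$logits$dce) - Y) * (wtab[, "DCE"] * scale)
    d_t2 <- (softmax_rows(fw$logits$t2) - Y) * (wtab[, "T2"] * scale)
    d_da <- (softmax_rows(fw$logits$da) - Y) * (wtab[, "DWI_ADC"] * scale)
    # routing: NET logits are the mean of two aux logit vectors per stream
    d_da <- d_da + 0.5 * d_net
    d_dce <- d_dce + 0.5 * d_net * pz
    d_t2 <- d_t2 + 0.5 * d_net * (!pz)

    d_features <- list()
    for (g in c("t2", "da", "dce")) {
      dlog <- switch(g, t2 = d_t2, da = d_da, dce = d_dce)
      key <- paste0("aux_", g)
      r <- dense_backward(dlog, fw$cache$aux[[g]],
                          model$params[[paste0(key, ".W")]])
      grads[[paste0(key, ".W")]] <- r$gW
      grads[[paste0(key, ".b")]] <- r$gb
      d_features[[g]] <- r$dx
    }
  }

  grads <- backward_cma(model, grads, fw$cache$cma, d_features)
  # L2 penalty gradient, once per batch
  for (k in l2$keys)
    grads[[k]] <- (grads[[k]] %||% 0) + (0.2 / l2$n) * model$params[[k]]
  list(loss = loss, probs = fw$probs, grads = grads)
}

#' Predict class probabilities for samples
#'
#' @param model an `mpcnn_model`
#' @param samples list of [mp_sample()]
#' @param batch_size forward-pass batch size
#' @return numeric vector of significant-class probabilities
#' @export
predict_proba <- function(model, samples, batch_size = 32L) {
  out <- numeric(length(samples))
  idx <- split(seq_along(samples),
               ceiling(seq_along(samples) / batch_size))
  for (ii in idx) {
    b <- batch_tensors(samples[ii])
    out[ii] <- forward_model(model, b, train = FALSE)$probs[, 2]
  }
  out
}
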