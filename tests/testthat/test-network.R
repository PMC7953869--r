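# Architecture: shape inference, zone encoding, routing, model heads,
# and a finite-difference check of the hand-derived backward pass.

test_that("shape inference matches an independent hand trace", {
  geoms <- list(c(60, 60, 10), c(20, 20, 10), c(15, 15, 10), c(16, 16, 6))
  for (cc in c(16L, 4L)) for (extra in c(TRUE, FALSE)) for (g in geoms) {
    tr <- infer_shapes(subnet_spec(cc, extra), g)
    oracle <- oracle_shape_trace(g, cc, extra)
    expect_equal(nrow(tr), length(oracle$trace) + 1L)  # + FC row
    for (i in seq_along(oracle$trace)) {
      o <- oracle$trace[[i]]
      expect_equal(tr$layer[i], unname(o["id"]))
      expect_equal(unname(unlist(tr[i, c("width", "height", "depth",
                                         "channels")])),
                   as.numeric(o[c("w", "h", "z", "ch")]))
    }
    expect_equal(tr$channels[nrow(tr)], oracle$final_len)
  }
})

test_that("final-pool depth follows floor(z/2) + 1 and the 2c output length", {
  tr <- infer_shapes(subnet_spec(16, TRUE), c(60, 60, 10))
  expect_equal(tr$depth[tr$layer == "Pool 2"], 10 %/% 2 + 1)
  expect_equal(tr$channels[tr$layer == "FC"], 32)
  tr2 <- infer_shapes(subnet_spec(2, FALSE), c(8, 8, 4))
  expect_equal(tr2$channels[tr2$layer == "FC"], 4)
  expect_error(infer_shapes(subnet_spec(4, FALSE), c(1, 8, 4)), "Pool")
})

test_that("zone one-hot encoding is exhaustive and exclusive", {
  expect_equal(zone_onehot("PZ"), c(1, 0, 0, 0, 0))
  expect_equal(zone_onehot("SV"), c(0, 0, 0, 0, 1))
  for (z in ZONES) {
    v <- zone_onehot(z)
    expect_equal(sum(v), 1)
    expect_true(all(v %in% c(0, 1)))
  }
  expect_error(zone_onehot("XY"), "unknown")
})

test_that("stream routing follows the PI-RADS dominant-sequence table", {
  expect_equal(stream_for_zone("PZ"), "PZ_stream")
  for (z in c("TZ", "AFS", "SV", "CZ"))
    expect_equal(stream_for_zone(z), "TZ_stream")
  # routing is total over the enumeration
  for (z in ZONES)
    expect_true(stream_for_zone(z) %in% c("PZ_stream", "TZ_stream"))
})

test_that("route_logits averages exactly the two stream-relevant heads", {
  expect_equal(route_logits("PZ", c(9, 9), da_logits = c(1, 0),
                            dce_logits = c(0, 1)), c(0.5, 0.5))
  expect_equal(route_logits("TZ", t2_logits = c(2, -1), da_logits = c(2, -1),
                            dce_logits = c(50, 50)), c(2, -1))
  # perturbing the non-routed head never changes the result
  base <- route_logits("PZ", c(0, 0), c(1, 2), c(3, 4))
  expect_equal(route_logits("PZ", c(100, -100), c(1, 2), c(3, 4)), base)
  base_tz <- route_logits("AFS", c(1, 2), c(3, 4), c(0, 0))
  expect_equal(route_logits("AFS", c(1, 2), c(3, 4), c(-50, 50)), base_tz)
})

test_that("the CMA emits three 32-element features and the stated widths", {
  cma <- build_cma(c = 16)
  expect_equal(unname(cma$group_in), c(3 * 32 + 5, 2 * 32 + 5, 32 + 5))
  set.seed(51)
  cma4 <- build_cma(c = 4)
  b <- piradsnet:::batch_tensors(tiny_samples()[1:3])
  fw <- piradsnet:::forward_cma(build_m1(cma4), b)
  expect_named(fw$features, c("t2", "da", "dce"))
  for (f in fw$features) expect_equal(dim(f), c(3L, 32L))
})

test_that("inference is deterministic (dropout disabled)", {
  set.seed(52)
  model <- build_m2(build_cma(c = 4))
  b <- piradsnet:::batch_tensors(tiny_samples()[1:3])
  p1 <- piradsnet:::forward_model(model, b, train = FALSE)$probs
  p2 <- piradsnet:::forward_model(model, b, train = FALSE)$probs
  expect_identical(p1, p2)
})

test_that("M1 softmax output normalises over two classes", {
  set.seed(53)
  model <- build_m1(build_cma(c = 4))
  expect_equal(dim(model$params$head.W), c(96L, 2L))
  b <- piradsnet:::batch_tensors(tiny_samples()[1:4])
  p <- piradsnet:::forward_model(model, b)$probs
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
})

test_that("M2 has three auxiliary heads and routes their mean", {
  set.seed(54)
  model <- build_m2(build_cma(c = 4))
  expect_true(all(c("aux_t2.W", "aux_da.W", "aux_dce.W") %in%
                    names(model$params)))
  b <- piradsnet:::batch_tensors(tiny_samples()[1:4])
  fw <- piradsnet:::forward_model(model, b)
  expect_equal(rowSums(fw$probs), rep(1, 4), tolerance = 1e-6)
  # force all heads to constant logits L: NET-out must be softmax(L)
  L <- c(0.7, -0.4)
  for (k in c("aux_t2", "aux_da", "aux_dce")) {
    model$params[[paste0(k, ".W")]][] <- 0
    model$params[[paste0(k, ".b")]] <- L
  }
  fw2 <- piradsnet:::forward_model(model, b)
  expect_equal(fw2$probs,
               matrix(rep(exp(L) / sum(exp(L)), each = 4), 4, 2),
               tolerance = 1e-9)
})

test_that("M2 predictions ignore the non-routed modality head", {
  set.seed(55)
  model <- build_m2(build_cma(c = 4))
  samples <- tiny_samples()
  pz <- Filter(function(s) s$finding$zone == "PZ", samples)[1:3]
  b <- piradsnet:::batch_tensors(pz)
  p0 <- piradsnet:::forward_model(model, b)$probs
  model$params$aux_t2.W[] <- rnorm(length(model$params$aux_t2.W), sd = 5)
  model$params$aux_t2.b <- c(3, -3)
  expect_equal(piradsnet:::forward_model(model, b)$probs, p0)
})

test_that("backward pass matches finite differences (smooth configuration)", {
  set.seed(56)
  samples <- tiny_samples()[c(1, 6, 11, 16)]
  b <- piradsnet:::batch_tensors(samples)
  for (kind in c("M1", "M2")) {
    cma <- build_cma(c = 2, hidden = 6, feature_dim = 4, alpha = 1)
    model <- if (kind == "M1") build_m1(cma) else build_m2(cma)
    r <- piradsnet:::model_loss_grads(model, b, train = FALSE)
    set.seed(57)
    for (nm in sample(names(r$grads), 8)) {
      g <- r$grads[[nm]]
      i <- sample(length(g), 1)
      eps <- 1e-6
      up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      fd <- (piradsnet:::model_loss_grads(up, b, train = FALSE)$loss -
               piradsnet:::model_loss_grads(dn, b, train = FALSE)$loss) /
        (2 * eps)
      expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-7), 1e-4)
    }
  }
})
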