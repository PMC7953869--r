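# Shared fixtures: small phantom cohorts and a hand-written shape oracle.

# tiny balanced two-zone cohort used by several suites (memoised per session)
.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(n_per_cell = 5L, seed = 402L) {
  key <- paste0("cohort_", n_per_cell, "_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  comp <- data.frame(zone = c("PZ", "PZ", "TZ", "TZ"),
                     significant = c(FALSE, TRUE, FALSE, TRUE),
                     count = rep(as.integer(n_per_cell), 4))
  co <- generate_cohort(phantom_config("tiny", composition = comp),
                        seed = seed)
  .fixture_env[[key]] <- co
  co
}

tiny_samples <- function(n_per_cell = 5L, seed = 402L) {
  key <- paste0("samples_", n_per_cell, "_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  s <- cohort_samples(tiny_cohort(n_per_cell, seed))
  .fixture_env[[key]] <- s
  s
}

# Independent layer-by-layer shape trace of the sub-network architecture,
# written directly from the layer table rules (kept separate from
# infer_shapes on purpose).
oracle_shape_trace <- function(input, c, extra_block) {
  w <- input[1]; h <- input[2]; z <- input[3]
  halve <- function(n) ceiling(n / 2)
  rows <- list()
  add <- function(id, ch) rows[[length(rows) + 1L]] <<-
    c(id = id, w = w, h = h, z = z, ch = ch)
  if (extra_block) {
    add("Conv 0_1", c / 2); add("Conv 0_2", c / 2)
    w <- halve(w); h <- halve(h); add("Pool 0", c / 2)
  }
  add("Conv 1_1", c); add("Conv 1_2", c)
  w <- halve(w); h <- halve(h); add("Pool 1", c)
  add("Conv 2_1", 2 * c); add("Conv 2_2", 2 * c); add("Conv 2_3", 2 * c)
  w <- halve(w); h <- halve(h); z <- floor(z / 2) + 1
  add("Pool 2", 2 * c)
  list(trace = rows, final_len = 2 * c)
}

# exact two-sided Wilcoxon signed-rank p-value by full sign-pattern
# enumeration (no zeros/ties assumed)
oracle_wilcoxon_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  # two-sided: double the smaller tail (mirror-symmetric null)
  mu <- n * (n + 1) / 4
  p <- 2 * min(mean(v_null >= v_obs), mean(v_null <= v_obs))
  min(p, 1)
}

# brute-force pairwise AUC with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
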