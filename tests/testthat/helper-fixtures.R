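# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

# small default-mechanism cohort
small_cohort <- function(n = 400, seed = 42) {
  key <- paste0("co_", n, "_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generate_cohort(gt_config(), n, seed)
  .fx[[key]]
}

# the shared s_Kr cache (cell + fiber tabulation)
twin_cache_fixture <- function() {
  if (is.null(.fx$cache)) .fx$cache <- build_twin_cache()
  .fx$cache
}

# registry-scale fixture for the end-to-end checks: cohort, twins, twin probs
big_fixture <- function(n = 10000, seed = 101) {
  key <- paste0("big_", n, "_", seed)
  if (is.null(.fx[[key]])) {
    co <- generate_cohort(gt_config(), n, seed)
    tw <- calibrate_cohort(co, cache = twin_cache_fixture())
    .fx[[key]] <- list(cohort = co, twins = tw,
                       twin_prob = twin_risk_probability(tw, co))
  }
  .fx[[key]]
}

# brute-force concordant-pair AUC (O(n^2) oracle)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
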