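## Shared fixtures and independent oracles for the test suite.

## scaled config with a short horizon, for quick closed-loop runs
quick_cfg <- function(...) {
  hr_config("scaled", total_steps = 5e4, checkpoint_period = 5e4,
            obs_interval = 1e4, obs_window = 1e3, ...)
}

## fresh seeded network + state pair for engine-equivalence runs
seeded_state <- function(cfg, seed = 1L, learn = TRUE,
                         case = cfg$training_case) {
  set.seed(seed)
  net <- init_network(cfg$geometry, cfg$n_hidden)
  set.seed(seed + 1000003L)
  init_state(net, cfg, case, learn = learn)
}

## independent brute-force maximal-clique oracle (subset enumeration, n <= 10)
bf_assemblies <- function(W, threshold = 0) {
  n <- nrow(W)
  adj <- (W > threshold) & (t(W) > threshold)
  diag(adj) <- FALSE
  is_clique <- function(v) {
    if (length(v) < 2) return(FALSE)
    pr <- utils::combn(v, 2)
    all(adj[t(pr)])
  }
  cliques <- list()
  for (sz in 2:n)
    for (v in utils::combn(n, sz, simplify = FALSE))
      if (is_clique(v)) cliques[[length(cliques) + 1L]] <- v
  ## keep maximal only
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j)
      i != j && all(cliques[[i]] %in% cliques[[j]]), logical(1)))
  }, logical(1))
  cliques[keep]
}

## canonical form for comparing assembly sets
canon_sets <- function(sets) {
  s <- lapply(sets, function(v) sort(as.integer(v)))
  s[order(vapply(s, function(v) paste(v, collapse = ","), character(1)))]
}
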