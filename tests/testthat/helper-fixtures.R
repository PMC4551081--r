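# shared fixtures: small simulated series and hand-built covariance objects

# white-noise p-variate series
wn_ts <- function(p = 3, T = 200, seed = 1) {
  set.seed(seed)
  roi_ts(matrix(rnorm(p * T), p, T), orientation = "roi")
}

# stationary VAR(1) series from a reduced-form Phi (no contemporaneous part)
var1_ts <- function(Phi, T = 300, seed = 1, burn = 200) {
  set.seed(seed)
  p <- nrow(Phi)
  y <- matrix(0, p, T + burn)
  for (t in 2:(T + burn)) y[, t] <- Phi %*% y[, t - 1] + rnorm(p)
  roi_ts(y[, burn + seq_len(T), drop = FALSE], orientation = "roi")
}

# wrap a plain covariance matrix as a lagged_cov (for closed-form fits)
fake_lagged_cov <- function(S, p, order, n_eff, n_extra = 0) {
  structure(list(S = S, order = order, n_eff = n_eff, p = p, m = nrow(S),
                 n_extra = n_extra,
                 var_names = paste0("v", seq_len(nrow(S))),
                 block_labels = rep(NA, nrow(S)), T = n_eff + order),
            class = "lagged_cov")
}

# a spec with given free A / Phi coordinate lists
quick_spec <- function(p, order, A = NULL, Phi = list()) {
  sp <- model_spec(p, order)
  for (idx in A) sp$free_A[idx[1], idx[2]] <- TRUE
  for (q in seq_along(Phi))
    for (idx in Phi[[q]]) sp$free_Phi[[q]][idx[1], idx[2]] <- TRUE
  sp
}

free_ids <- function(spec) {
  tab <- param_table(spec)
  tab$id[tab$free]
}
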