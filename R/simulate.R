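#' Specification of a generative uSEM / euSEM simulation
#'
#' Describes the true model a synthetic ROI series is drawn from:
#' contemporaneous matrix \code{A}, lagged matrices \code{Phi_q}, and
#' optionally direct (\code{gamma}) and bilinear (\code{tau}) input
#' effects.  Process innovations are zero-mean Gaussian with covariance
#' \code{innovation_cov} (identity by default).  The reduced-form
#' companion matrix must have spectral radius below 1 (stationarity)
#' and I - A must be invertible; violations are an error before any
#' simulation.
#'
#' @param p number of ROI series.
#' @param T series length returned (after burn-in).
#' @param order maximum lag of \code{Phi}.
#' @param A p x p contemporaneous matrix (zero diagonal).
#' @param Phi list of p x p lagged matrices, length \code{order}.
#' @param gamma optional list over input lags r = 0..f of p x 1 direct
#'   effects.
#' @param tau optional list over (q, r) of p x p bilinear effects
#'   (single input), stored row-major in q then r.
#' @param g,h bilinear lag bounds matching \code{tau}.
#' @param innovation_cov p x p innovation covariance (default identity).
#' @param burn_in transient samples discarded before recording.
#' @param seed optional integer seed pinned to Mersenne-Twister /
#'   inversion sampling for bit-reproducible draws.
#' @return object of class \code{"sim_spec"}.
#' @export
sim_spec <- function(p, T, order, A = matrix(0, p, p),
                     Phi = lapply(seq_len(order), function(q) matrix(0, p, p)),
                     gamma = NULL, tau = NULL, g = 1, h = 1,
                     innovation_cov = diag(p), burn_in = 500, seed = NULL) {
  stopifnot(p >= 1, T > p, order >= 0, length(Phi) == order)
  A <- as.matrix(A)
  if (any(abs(diag(A)) > 0)) stop("the diagonal of A must be zero")
  IA <- diag(p) - A
  if (abs(det(IA)) < 1e-12) stop("I - A is singular")
  if (!isTRUE(all.equal(innovation_cov, t(innovation_cov))) ||
      any(eigen(innovation_cov, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("innovation covariance must be symmetric positive definite")
  sr <- .spectral_radius(A, Phi, p, order)
  if (sr >= 1)
    stop(sprintf("non-stationary specification: spectral radius %.3f >= 1", sr))
  structure(list(p = p, T = T, order = order, A = A, Phi = Phi,
                 gamma = gamma, tau = tau, g = g, h = h,
                 innovation_cov = innovation_cov,
                 burn_in = burn_in, seed = seed,
                 spectral_radius = sr),
            class = "sim_spec")
}

# spectral radius of the reduced-form companion matrix
.spectral_radius <- function(A, Phi, p, order) {
  if (order == 0) return(0)
  G <- solve(diag(p) - A)
  comp <- matrix(0, p * order, p * order)
  for (q in seq_len(order))
    comp[seq_len(p), (q - 1) * p + seq_len(p)] <- G %*% Phi[[q]]
  if (order > 1)
    comp[p + seq_len(p * (order - 1)), seq_len(p * (order - 1))] <-
      diag(p * (order - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.sim_spec <- function(x, ...) {
  nz <- sum(x$A != 0) + sum(vapply(x$Phi, function(M) sum(M != 0), 0)) +
    sum(vapply(x$gamma, function(M) sum(M != 0), 0)) +
    sum(vapply(x$tau, function(M) sum(M != 0), 0))
  cat("simulation spec: p =", x$p, ", T =", x$T, ", order =", x$order,
      ",", nz, "nonzero coefficients, spectral radius",
      signif(x$spectral_radius, 3), "\n")
  invisible(x)
}

.pin_seed <- function(seed) {
  if (!is.null(seed))
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

#' Simulate an ROI time series from a uSEM
#'
#' Iterates \eqn{y(t) = (I-A)^{-1}(\sum_q \Phi_q y(t-q) + \zeta(t))}
#' with Gaussian innovations, discards the burn-in, and returns T
#' points.  A fixed seed gives bit-reproducible output.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed overrides \code{spec$seed}.
#' @param tr_seconds repetition time attached to the series.
#' @return a \code{\link{roi_ts}} (not centered).
#' @export
#' @examples
#' ts <- simulate_usem(scenario_3roi_lag2(), seed = 1)
simulate_usem <- function(spec, seed = spec$seed, tr_seconds = 2) {
  .pin_seed(seed)
  p <- spec$p; a <- spec$order
  G <- solve(diag(p) - spec$A)
  n <- spec$T + spec$burn_in
  Rchol <- chol(spec$innovation_cov)
  Z <- t(Rchol) %*% matrix(rnorm(p * n), p, n)
  y <- matrix(0, p, n)
  for (t in seq_len(n)) {
    acc <- Z[, t]
    for (q in seq_len(min(a, t - 1)))
      acc <- acc + spec$Phi[[q]] %*% y[, t - q]
    y[, t] <- G %*% acc
  }
  roi_ts(y[, spec$burn_in + seq_len(spec$T), drop = FALSE],
         tr_seconds = tr_seconds, orientation = "roi")
}

#' The 3-ROI second-order demonstration scenario
#'
#' A single-subject generative scenario with 3 ROIs and 200 time
#' points, simulated from a second-order uSEM with identity innovation
#' covariance: each ROI has a first-order autoregressive component, the
#' third ROI an additional second-order autoregressive component,
#' activity in the first ROI is contemporaneously predicted by the
#' third ROI, and the first ROI predicts second-ROI activity at lag
#' one -- six nonzero coefficients in all.  The default magnitudes
#' (0.4 first-order AR, 0.3 second-order AR, 0.5 contemporaneous, 0.4
#' cross-lag) are this package's stationarity-checked choices and may
#' be overridden.
#'
#' @param ar1 first-order autoregressive coefficient (all ROIs).
#' @param ar2 second-order autoregressive coefficient (ROI 3).
#' @param contemporaneous effect of ROI 3 on ROI 1 at lag 0.
#' @param cross_lag effect of ROI 1 on ROI 2 at lag 1.
#' @param T series length.
#' @return a \code{\link{sim_spec}} with p = 3, order = 2.
#' @export
scenario_3roi_lag2 <- function(ar1 = 0.4, ar2 = 0.3,
                               contemporaneous = 0.5, cross_lag = 0.4,
                               T = 200) {
  A <- matrix(0, 3, 3)
  A[1, 3] <- contemporaneous
  Phi1 <- diag(ar1, 3)
  Phi1[2, 1] <- cross_lag
  Phi2 <- matrix(0, 3, 3)
  Phi2[3, 3] <- ar2
  sim_spec(p = 3, T = T, order = 2, A = A, Phi = list(Phi1, Phi2))
}

# true free mask of a sim_spec, for scoring recovery
sim_truth_spec <- function(spec) {
  ms <- model_spec(spec$p, spec$order,
                   n_u = if (is.null(spec$gamma)) 0L else 1L,
                   f = max(length(spec$gamma) - 1, 1),
                   g = spec$g, h = spec$h,
                   bilinear = !is.null(spec$tau))
  ms$free_A <- spec$A != 0
  diag(ms$free_A) <- FALSE
  for (q in seq_len(spec$order)) ms$free_Phi[[q]] <- spec$Phi[[q]] != 0
  if (!is.null(spec$gamma))
    for (r in seq_along(spec$gamma))
      ms$free_gamma[[r]] <- as.matrix(spec$gamma[[r]] != 0)
  if (!is.null(spec$tau))
    for (i in seq_along(spec$tau)) ms$free_tau[[i]] <- spec$tau[[i]] != 0
  ms
}

#' Simulate an euSEM series with task input
#'
#' Builds a boxcar condition vector from the block protocol, convolves
#' it with the HRF kernel, and iterates the euSEM recursion including
#' the direct \eqn{\gamma_r u(t-r)} and bilinear
#' \eqn{\tau_{qr} y(t-q) u(t-r)} terms.
#'
#' @param spec a \code{\link{sim_spec}} with \code{gamma} and/or
#'   \code{tau}.
#' @param protocol list with \code{onsets} and \code{durations} (in
#'   scans) of the task blocks; zero blocks give an all-zero input.
#' @param kernel an \code{\link{hrf_kernel}} (default double gamma at
#'   \code{tr_seconds}).
#' @param seed overrides \code{spec$seed}.
#' @param tr_seconds repetition time.
#' @return list with \code{ts} (a \code{\link{roi_ts}}) and \code{input}
#'   (the convolved \code{\link{input_series}}).
#' @export
simulate_eusem <- function(spec, protocol = list(onsets = c(), durations = c()),
                           kernel = hrf_double_gamma(tr_seconds),
                           seed = spec$seed, tr_seconds = 2) {
  u <- numeric(spec$T + spec$burn_in)
  for (i in seq_along(protocol$onsets)) {
    on <- spec$burn_in + protocol$onsets[i]
    u[on:min(on + protocol$durations[i] - 1, length(u))] <- 1
  }
  uconv <- convolve_input(input_series(matrix(u, 1)), kernel)
  uc <- uconv$convolved[1, ]
  .pin_seed(seed)
  p <- spec$p; a <- spec$order
  G <- solve(diag(p) - spec$A)
  n <- spec$T + spec$burn_in
  Rchol <- chol(spec$innovation_cov)
  Z <- t(Rchol) %*% matrix(rnorm(p * n), p, n)
  y <- matrix(0, p, n)
  f <- length(spec$gamma) - 1
  for (t in seq_len(n)) {
    acc <- Z[, t]
    for (q in seq_len(min(a, t - 1)))
      acc <- acc + spec$Phi[[q]] %*% y[, t - q]
    if (!is.null(spec$gamma))
      for (r in 0:f)
        if (t > r) acc <- acc + spec$gamma[[r + 1]] * uc[t - r]
    if (!is.null(spec$tau))
      for (q in seq_len(spec$g)) for (r in seq_len(spec$h))
        if (t > max(q, r))
          acc <- acc + (spec$tau[[(q - 1) * spec$h + r]] %*% y[, t - q]) *
            uc[t - r]
    y[, t] <- G %*% acc
  }
  keep <- spec$burn_in + seq_len(spec$T)
  out_u <- input_series(matrix(u[keep], 1))
  out_u <- convolve_input(out_u, kernel)
  # use the realized (burn-in-aware) convolved input actually driving y
  out_u$convolved <- matrix(uc[keep], 1)
  out_u$kernel_id <- kernel$kernel_id
  list(ts = roi_ts(y[, keep, drop = FALSE], tr_seconds = tr_seconds,
                   orientation = "roi"),
       input = out_u)
}

#' Group simulation specification
#'
#' Describes a multi-subject sample sharing a group-level connection
#' structure with between-subject coefficient jitter, plus
#' subject-specific individual connections and -- for a designated
#' fraction of subjects -- an additional lag-2 autoregressive edge.
#' Defaults mirror a typical resting-state configuration: 32 subjects,
#' 4 ROIs, 160 time points, a first-order autoregressive connection for
#' each ROI plus four contemporaneous connections at the group level.
#'
#' @param n_subjects sample size.
#' @param p,T series count and length per subject.
#' @param group_A,group_Phi1 group-level coefficient matrices (means).
#' @param jitter half-width of the uniform between-subject coefficient
#'   jitter.
#' @param n_individual number of individual-level edges added per
#'   subject (drawn from the currently-empty A and Phi1 cells).
#' @param individual_beta magnitude of individual-level edges.
#' @param fraction_lag2 fraction of subjects receiving one lag-2
#'   autoregressive edge.
#' @param lag2_beta magnitude of that edge.
#' @param seed integer seed.
#' @return object of class \code{"group_sim_spec"}.
#' @export
group_sim_spec <- function(n_subjects = 32, p = 4, T = 160,
                           group_A = .default_group_A(p),
                           group_Phi1 = diag(0.4, p),
                           jitter = 0.1,
                           n_individual = 1, individual_beta = 0.3,
                           fraction_lag2 = 0.5, lag2_beta = 0.4,
                           seed = NULL) {
  stopifnot(n_subjects >= 1, fraction_lag2 >= 0, fraction_lag2 <= 1)
  structure(list(n_subjects = n_subjects, p = p, T = T,
                 group_A = group_A, group_Phi1 = group_Phi1,
                 jitter = jitter, n_individual = n_individual,
                 individual_beta = individual_beta,
                 fraction_lag2 = fraction_lag2, lag2_beta = lag2_beta,
                 seed = seed),
            class = "group_sim_spec")
}

.default_group_A <- function(p) {
  A <- matrix(0, p, p)
  for (j in seq_len(p)) A[j %% p + 1, j] <- 0.4   # a directed ring
  A
}

#' Simulate a group-structured multi-subject sample
#'
#' Draws each subject's coefficients as group mean plus uniform jitter,
#' adds subject-specific individual edges, gives a designated fraction
#' of subjects one lag-2 autoregressive edge, checks stationarity
#' (re-drawing up to 10 times), and simulates every subject.
#'
#' @param gspec a \code{\link{group_sim_spec}}.
#' @param seed overrides \code{gspec$seed}.
#' @return list with \code{ts_list} (named list of \code{\link{roi_ts}})
#'   and \code{truth} -- a data.frame ledger of every nonzero edge
#'   (subject, matrix, lag, row, col, beta, level) for scoring
#'   recovery.
#' @export
simulate_group <- function(gspec, seed = gspec$seed) {
  .pin_seed(seed)
  n <- gspec$n_subjects; p <- gspec$p
  n_lag2 <- round(gspec$fraction_lag2 * n)
  lag2_subjects <- if (n_lag2 > 0) sample.int(n, n_lag2) else integer(0)
  ts_list <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    for (attempt in seq_len(10)) {
      A <- gspec$group_A
      nzA <- which(A != 0)
      A[nzA] <- A[nzA] + runif(length(nzA), -gspec$jitter, gspec$jitter)
      Phi1 <- gspec$group_Phi1
      nzP <- which(Phi1 != 0)
      Phi1[nzP] <- Phi1[nzP] + runif(length(nzP), -gspec$jitter, gspec$jitter)
      # individual-level edges from currently-empty off-diagonal cells
      pool <- rbind(
        cbind(which(A == 0 & upper.tri(A) | A == 0 & lower.tri(A),
                    arr.ind = TRUE), mat = 1),
        cbind(which(Phi1 == 0, arr.ind = TRUE), mat = 2))
      ind <- if (gspec$n_individual > 0 && nrow(pool) > 0)
        pool[sample.int(nrow(pool), min(gspec$n_individual, nrow(pool))), ,
             drop = FALSE]
      else pool[0, , drop = FALSE]
      for (e in seq_len(nrow(ind))) {
        b <- gspec$individual_beta * sample(c(-1, 1), 1)
        if (ind[e, "mat"] == 1) A[ind[e, "row"], ind[e, "col"]] <- b
        else Phi1[ind[e, "row"], ind[e, "col"]] <- b
      }
      order_i <- if (i %in% lag2_subjects) 2L else 1L
      Phi <- list(Phi1)
      lag2_roi <- NA_integer_
      if (order_i == 2L) {
        Phi2 <- matrix(0, p, p)
        lag2_roi <- sample.int(p, 1)
        Phi2[lag2_roi, lag2_roi] <- gspec$lag2_beta
        Phi[[2]] <- Phi2
      }
      sp <- tryCatch(sim_spec(p, gspec$T, order_i, A, Phi),
                     error = function(e) NULL)
      if (!is.null(sp)) break
      if (attempt == 10) stop("could not draw a stationary spec for subject ", i)
    }
    ts_list[[i]] <- simulate_usem(sp, seed = NULL)   # stream continues
    truth[[i]] <- .edge_ledger(i, sp, gspec)
  }
  names(ts_list) <- sprintf("subj%02d", seq_len(n))
  list(ts_list = ts_list, truth = do.call(rbind, truth))
}

.edge_ledger <- function(i, sp, gspec) {
  rows <- list()
  add <- function(matrix, lag, idx, beta, level) {
    if (!nrow(idx)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      subject = i, matrix = matrix, lag = lag,
      row = idx[, 1], col = idx[, 2], beta = beta, level = level)
  }
  gA <- gspec$group_A != 0; gP <- gspec$group_Phi1 != 0
  add("A", 0L, which(sp$A != 0 & gA, arr.ind = TRUE),
      sp$A[sp$A != 0 & gA], "group")
  add("A", 0L, which(sp$A != 0 & !gA, arr.ind = TRUE),
      sp$A[sp$A != 0 & !gA], "individual")
  add("Phi", 1L, which(sp$Phi[[1]] != 0 & gP, arr.ind = TRUE),
      sp$Phi[[1]][sp$Phi[[1]] != 0 & gP], "group")
  add("Phi", 1L, which(sp$Phi[[1]] != 0 & !gP, arr.ind = TRUE),
      sp$Phi[[1]][sp$Phi[[1]] != 0 & !gP], "individual")
  if (sp$order >= 2)
    add("Phi", 2L, which(sp$Phi[[2]] != 0, arr.ind = TRUE),
        sp$Phi[[2]][sp$Phi[[2]] != 0], "individual")
  do.call(rbind, rows)
}
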