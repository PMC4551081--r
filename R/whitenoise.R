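#' Degrees of freedom of the white-noise test model
#'
#' The white-noise null fitted to the block-Toeplitz covariance of the
#' prediction errors frees only one repeated p x p contemporaneous
#' innovation covariance; all lag-1..L blocks are fixed at zero and all
#' diagonal blocks are constrained equal.  With m = p(L+1) variables,
#' \deqn{df = m(m+1)/2 - p(p+1)/2.}
#'
#' @param p number of residual series.
#' @param L order of the VAR null (default 3).
#' @return integer degrees of freedom.
#' @export
#' @examples
#' white_noise_df(3, 3)  # 72
#' white_noise_df(4, 3)  # 126
#' white_noise_df(7, 3)  # 378
white_noise_df <- function(p, L = 3) {
  stopifnot(p >= 1, L >= 0)
  m <- p * (L + 1)
  as.integer(m * (m + 1) / 2 - p * (p + 1) / 2)
}

#' White-noise test of one-step-ahead prediction errors
#'
#' Tests whether a fitted map's residuals are serially independent by
#' fitting a high-order (default 3) VAR to them by the block-Toeplitz
#' method and testing the null model in which every lagged regression
#' coefficient is zero: the implied covariance is block-diagonal with
#' one repeated free p x p contemporaneous covariance.  The test passes
#' when the null reaches excellent fit under the 2-of-4 rule.  The
#' modification-index table reports, for each (target ROI, source ROI,
#' lag 1..L), the Lagrange-multiplier statistic for the corresponding
#' lagged regression coefficient; significant entries point at the
#' unmodeled sequential dependencies.
#'
#' @param res residual series (\code{residuals()} of a \code{"usem"}
#'   fit, or any \code{\link{roi_ts}}).
#' @param L VAR order of the null (default 3).
#' @param config a \code{\link{usem_config}} providing the excellent-fit
#'   thresholds.
#' @return object of class \code{"white_noise_test"}: \code{fit} (a
#'   \code{\link{fit_indices}} result), \code{mi} (lagged-dependency
#'   MI table), \code{passed}, \code{L}, \code{p}.
#' @export
white_noise_test <- function(res, L = 3, config = usem_config()) {
  if (!inherits(res, "roi_ts")) res <- roi_ts(res, orientation = "roi")
  res <- center(res)
  p <- nrow(res$values); Tr <- ncol(res$values)
  if (Tr <= p * (L + 1))
    stop("residual series too short for a lag-", L, " white-noise test: T = ",
         Tr, ", need > ", p * (L + 1))
  S <- block_toeplitz_cov(res, L)
  m <- S$m
  n_eff <- S$n_eff
  # ML estimate of the repeated contemporaneous covariance: the null
  # Sigma = I_(L+1) (x) C is minimized at C = mean of the diagonal blocks,
  # which the Toeplitz construction makes equal to the lag-0 block.
  Cbar <- matrix(0, p, p)
  for (i in 0:L) Cbar <- Cbar + S$S[i * p + seq_len(p), i * p + seq_len(p)]
  Cbar <- Cbar / (L + 1)
  Sigma <- diag(L + 1) %x% Cbar
  Fml <- as.numeric(determinant(Sigma)$modulus) +
    sum(diag(solve(Sigma, S$S))) -
    as.numeric(determinant(S$S)$modulus) - m
  chi2 <- max((n_eff - 1) * Fml, 0)
  df <- white_noise_df(p, L)
  stopifnot(df == m * (m + 1) / 2 - p * (p + 1) / 2)
  base <- .baseline_fit(S$S, n_eff)
  fit <- fit_indices(chi2, df, base$chi2, base$df, n_eff, S$S, Sigma)
  mi <- .wn_mod_indices(S$S, p, L, Cbar, n_eff)
  structure(list(fit = fit, mi = mi, passed = excellent_fit(fit, config),
                 L = L, p = p, n_eff = n_eff, C = Cbar),
            class = "white_noise_test")
}

# LM statistics for the lagged regression coefficients of the residual VAR,
# conditioned on the free contemporaneous covariance of the null model
.wn_mod_indices <- function(S, p, L, Cbar, n_eff) {
  m <- p * (L + 1); mx <- m - p
  ix <- seq_len(mx); ie <- mx + seq_len(p)
  Sigma <- diag(L + 1) %x% Cbar
  Sigi <- solve(Sigma)
  Sxx_imp <- Sigma[ix, ix, drop = FALSE]
  derivs <- list()
  for (j in seq_len(p)) for (l in j:p) {
    dC <- matrix(0, p, p); dC[j, l] <- 1
    if (l != j) dC[l, j] <- 1
    derivs[[length(derivs) + 1]] <- diag(L + 1) %x% dC
  }
  nf <- length(derivs)
  cand <- expand.grid(col = seq_len(p), row = seq_len(p), q = seq_len(L))
  cand <- cand[order(cand$q, cand$row, cand$col), c("q", "row", "col")]
  for (i in seq_len(nrow(cand))) {
    # regression of residual k on residual j at lag l: x column (L-l)*p + j
    xcol <- (L - cand$q[i]) * p + cand$col[i]
    D <- matrix(0, m, m)
    D[ie[cand$row[i]], ix] <- Sxx_imp[xcol, ]
    D[ix, ie[cand$row[i]]] <- Sxx_imp[, xcol]
    derivs[[length(derivs) + 1]] <- D
  }
  ig <- .info_and_grad(Sigi, S, derivs)
  idx_c <- nf + seq_len(nrow(cand))
  Vff <- ig$V[seq_len(nf), seq_len(nf), drop = FALSE]
  Vfc <- ig$V[seq_len(nf), idx_c, drop = FALSE]
  condv <- diag(ig$V)[idx_c] - colSums(Vfc * .solve_ridge(Vff, Vfc))
  g <- ig$g[idx_c]
  mi <- (n_eff - 1) / 2 * g^2 / condv
  mi[!is.finite(mi) | condv <= 1e-12] <- 0
  out <- data.frame(matrix = "Phi", q = cand$q, r = NA_integer_,
                    row = cand$row, col = cand$col, lag = cand$q,
                    mi = pmax(mi, 0),
                    epc = ifelse(condv > 1e-12, -g / condv, NA_real_))
  out$id <- sprintf("Phi%d[%d,%d]", out$q, out$row, out$col)
  out <- out[, c("id", "matrix", "q", "r", "row", "col", "lag", "mi", "epc")]
  rownames(out) <- NULL
  class(out) <- c("mod_index_table", "data.frame")
  out
}

#' @export
print.white_noise_test <- function(x, ...) {
  cat("white-noise test (VAR(", x$L, ") null on prediction errors):\n",
      sep = "")
  print(x$fit)
  cat("residuals", if (x$passed) "PASS as white noise"
      else "FAIL: unmodeled sequential dependencies", "\n")
  nsig <- sum(x$mi$mi > qchisq(0.95, 1))
  if (!x$passed && nsig)
    cat(nsig, "significant lagged-dependency modification indices; largest:\n")
  if (!x$passed && nsig)
    print(as.data.frame(x$mi)[head(order(-x$mi$mi), 3),
                              c("id", "mi", "epc")],
          digits = 4, row.names = FALSE)
  invisible(x)
}
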