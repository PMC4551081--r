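# Expected-information machinery shared by standard errors, modification
# indices (Lagrange multiplier tests) and Wald tests.
#
# For the Wishart ML discrepancy F, the expected information of parameter
# pair (i, j) per unit (n_eff - 1) is tr(Sigma^-1 dSigma_i Sigma^-1 dSigma_j)
# and the fit-function gradient is tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma_i].
# The MI (score test) for a fixed candidate c conditioned on the free
# parameters is  (n_eff - 1)/2 * g_c^2 / (V_cc - V_cf V_ff^-1 V_fc).

# derivative context for the regression-form model (saturated Sigma_xx)
.deriv_context <- function(S, spec, params) {
  p <- spec$p
  m <- nrow(S); mx <- m - p
  ix <- seq_len(mx); ie <- mx + seq_len(p)
  Sxx <- S[ix, ix, drop = FALSE]
  A <- params$A; B <- params$B; psi <- params$psi
  G <- solve(diag(p) - A)
  Sig <- implied_sigma(spec, params, Sxx)
  Sigi <- solve(Sig)
  Sex <- Sig[ie, ix, drop = FALSE]
  See <- Sig[ie, ie, drop = FALSE]
  Ekl <- function(k, l, nr, nc) { E <- matrix(0, nr, nc); E[k, l] <- 1; E }
  blk <- function(dxx = NULL, dex = NULL, dee = NULL) {
    D <- matrix(0, m, m)
    if (!is.null(dxx)) D[ix, ix] <- dxx
    if (!is.null(dex)) { D[ie, ix] <- dex; D[ix, ie] <- t(dex) }
    if (!is.null(dee)) D[ie, ie] <- dee
    D
  }
  dA <- function(k, l) {
    E <- Ekl(k, l, p, p)
    dex <- G %*% E %*% Sex
    dee <- G %*% E %*% See
    blk(dex = dex, dee = dee + t(dee))
  }
  dB <- function(k, l) {
    E <- Ekl(k, l, p, mx)
    dex <- G %*% E %*% Sxx
    dee <- G %*% (E %*% t(Sex))
    blk(dex = dex, dee = dee + t(dee))
  }
  derivs <- list(); labs <- character(0)
  masks <- free_masks(spec)
  for (l in seq_len(p)) for (k in seq_len(p)) if (masks$A[k, l]) {
    derivs[[length(derivs) + 1]] <- dA(k, l)
    labs <- c(labs, param_id("A", NA, NA, k, l))
  }
  lay <- masks$layout
  tabB <- param_table(spec)
  tabB <- tabB[tabB$free & tabB$matrix != "A", , drop = FALSE]
  for (i in seq_len(nrow(tabB))) {
    derivs[[length(derivs) + 1]] <- dB(tabB$row[i], param_bcol(spec, tabB[i, ], lay))
    labs <- c(labs, tabB$id[i])
  }
  n_reg <- length(derivs)
  for (j in seq_len(p)) {
    derivs[[length(derivs) + 1]] <- blk(dee = tcrossprod(G[, j]))
    labs <- c(labs, paste0("psi", j))
  }
  if (mx > 0) {
    GB <- G %*% B
    for (jj in seq_len(mx)) for (ll in jj:mx) {
      dxx <- Ekl(jj, ll, mx, mx)
      if (ll != jj) dxx <- dxx + t(dxx)
      dex <- GB %*% dxx
      derivs[[length(derivs) + 1]] <-
        blk(dxx = dxx, dex = dex, dee = GB %*% dxx %*% t(GB))
      labs <- c(labs, paste0("sxx", jj, ".", ll))
    }
  }
  list(S = S, Sig = Sig, Sigi = Sigi, derivs = derivs, labs = labs,
       n_reg = n_reg, dA = dA, dB = dB, spec = spec, m = m, p = p, mx = mx)
}

# information matrix V and gradient g for a list of derivative matrices
.info_and_grad <- function(Sigi, S, derivs) {
  K <- length(derivs)
  m <- nrow(Sigi)
  MP <- matrix(0, m * m, K)
  MPt <- matrix(0, m * m, K)
  for (i in seq_len(K)) {
    P <- Sigi %*% derivs[[i]]
    MP[, i] <- as.vector(P)
    MPt[, i] <- as.vector(t(P))
  }
  V <- crossprod(MPt, MP)
  Dg <- Sigi - Sigi %*% S %*% Sigi
  g <- vapply(derivs, function(D) sum(Dg * D), numeric(1))
  list(V = V, g = g)
}

.solve_ridge <- function(V, B) {
  tryCatch(solve(V, B), error = function(e)
    solve(V + diag(1e-10 * max(diag(V)), nrow(V)), B))
}

# standard errors of the free regression coefficients from the inverse
# expected information over all free parameters, scaled by 2/(n_eff - 1)
.param_se <- function(S, spec, params, n_eff) {
  ctx <- .deriv_context(S, spec, params)
  ig <- .info_and_grad(ctx$Sigi, S, ctx$derivs)
  Vinv <- .solve_ridge(ig$V, diag(nrow(ig$V)))
  v <- diag(Vinv) * 2 / (n_eff - 1)
  v[v < 0] <- NA_real_
  se <- sqrt(v)
  by_id <- as.list(se[seq_len(ctx$n_reg)])
  names(by_id) <- ctx$labs[seq_len(ctx$n_reg)]
  list(by_id = by_id, all = se, labs = ctx$labs)
}

#' Modification indices for fixed candidate parameters
#'
#' Computes the Lagrange-multiplier (score) statistic for every
#' currently-fixed candidate regression coefficient: the squared
#' fit-function gradient divided by the candidate's expected
#' information, conditioned on the free parameters, scaled by
#' \eqn{(n_{eff}-1)/2} to the chi-square(1) scale.  The MI approximates
#' the chi-square decrease from freeing that single candidate and
#' refitting; the expected parameter change (EPC) is reported alongside.
#'
#' @param S a \code{\link{block_toeplitz_cov}} result.
#' @param spec the fitted \code{\link{model_spec}}.
#' @param params converged parameters from \code{\link{fit_ml}}.
#' @param candidates optional subset of rows of the spec's parameter
#'   table; defaults to every structurally possible fixed parameter.
#' @return a data.frame of class \code{"mod_index_table"} in the
#'   deterministic (lag, target, source) order, with columns \code{id},
#'   \code{matrix}, \code{q}, \code{r}, \code{row}, \code{col},
#'   \code{lag}, \code{mi}, \code{epc}.
#' @export
modification_indices <- function(S, spec, params, candidates = NULL) {
  stopifnot(inherits(S, "lagged_cov"))
  tab <- param_table(spec)
  if (is.null(candidates)) candidates <- tab[!tab$free, , drop = FALSE]
  else {
    already <- candidates$id %in% tab$id[tab$free]
    if (any(already)) {
      warning("dropping already-free candidates: ",
              paste(candidates$id[already], collapse = ", "))
      candidates <- candidates[!already, , drop = FALSE]
    }
  }
  out <- candidates[, c("id", "matrix", "q", "r", "row", "col", "lag"),
                    drop = FALSE]
  if (nrow(out) == 0) {
    out$mi <- numeric(0); out$epc <- numeric(0)
    class(out) <- c("mod_index_table", "data.frame")
    return(out)
  }
  ctx <- .deriv_context(S$S, spec, params)
  lay <- x_layout(spec)
  cand_derivs <- lapply(seq_len(nrow(candidates)), function(i) {
    par <- candidates[i, ]
    if (par$matrix == "A") ctx$dA(par$row, par$col)
    else ctx$dB(par$row, param_bcol(spec, par, lay))
  })
  ig <- .info_and_grad(ctx$Sigi, S$S, c(ctx$derivs, cand_derivs))
  nf <- length(ctx$derivs)
  idx_c <- nf + seq_len(nrow(candidates))
  Vff <- ig$V[seq_len(nf), seq_len(nf), drop = FALSE]
  Vfc <- ig$V[seq_len(nf), idx_c, drop = FALSE]
  cond <- diag(ig$V)[idx_c] -
    colSums(Vfc * .solve_ridge(Vff, Vfc))
  g <- ig$g[idx_c]
  mi <- (S$n_eff - 1) / 2 * g^2 / cond
  mi[!is.finite(mi) | cond <= 1e-12] <- 0
  out$mi <- pmax(mi, 0)
  out$epc <- ifelse(cond > 1e-12, -g / cond, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("mod_index_table", "data.frame")
  out
}

#' @export
print.mod_index_table <- function(x, n = 10, ...) {
  cat("modification indices (top", min(n, nrow(x)), "of", nrow(x), ")\n")
  if (nrow(x)) {
    ord <- order(-x$mi)
    print(as.data.frame(x)[head(ord, n), c("id", "mi", "epc")],
          digits = 4, row.names = FALSE)
  }
  invisible(x)
}
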