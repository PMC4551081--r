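#' Degrees of freedom of a uSEM-family covariance-structure model
#'
#' The number of distinct fitted second moments minus the number of free
#' parameters.  With m = p(a+1) + extra_exog observed variables, the
#' saturated exogenous block spends (m-p)(m-p+1)/2 moments, the p
#' innovation variances spend p, and each freed regression coefficient
#' spends one:
#' \deqn{df = m(m+1)/2 - (m-p)(m-p+1)/2 - p - k_{free}.}
#'
#' @param p number of endogenous (ROI) series.
#' @param a model order.
#' @param k_free number of freed regression coefficients.
#' @param extra_exog number of appended input/product variables.
#' @return integer degrees of freedom.
#' @export
#' @examples
#' model_df(3, 1, 5)   # 7
#' model_df(3, 2, 4)   # 17
#' model_df(3, 2, 6)   # 15
model_df <- function(p, a, k_free, extra_exog = 0) {
  stopifnot(p >= 1, a >= 0, k_free >= 0, extra_exog >= 0)
  m <- p * (a + 1) + extra_exog
  mx <- m - p
  df <- m * (m + 1) / 2 - mx * (mx + 1) / 2 - p - k_free
  if (df < 0)
    stop("over-parameterized model: ", k_free,
         " free regression coefficients leave negative df (", df, ")")
  as.integer(df)
}

# concentrated ML fit of e = A e + B x + zeta on a covariance matrix S whose
# leading mx rows are the exogenous block.  Sigma_xx is saturated (profiled to
# S_xx) and the diagonal innovation covariance Psi is profiled to the residual
# variances, leaving an optimization over the free elements of (A, B) only:
#   F(A, B) = log det S_xx + sum_j log W_jj - 2 log|det(I-A)| - log det S,
# with W = R S R', R = [-B, I-A].
.fit_core <- function(S, p, freeA, freeB, n_eff, start = NULL) {
  m <- nrow(S); mx <- m - p
  ix <- seq_len(mx); ie <- mx + seq_len(p)
  ldetS <- as.numeric(determinant(S)$modulus)
  ldetSxx <- if (mx > 0)
    as.numeric(determinant(S[ix, ix, drop = FALSE])$modulus) else 0
  nA <- sum(freeA); nB <- sum(freeB); k <- nA + nB
  Ip <- diag(p)
  unpack <- function(th) {
    A <- matrix(0, p, p); B <- matrix(0, p, mx)
    if (nA) A[freeA] <- th[seq_len(nA)]
    if (nB) B[freeB] <- th[nA + seq_len(nB)]
    list(A = A, B = B)
  }
  obj <- function(th) {
    u <- unpack(th)
    IA <- Ip - u$A
    R <- cbind(-u$B, IA)
    Wd <- rowSums((R %*% S) * R)
    d <- determinant(IA)
    if (any(Wd <= 0) || !is.finite(d$modulus)) return(1e10)
    ldetSxx + sum(log(Wd)) - 2 * as.numeric(d$modulus) - ldetS
  }
  grad <- function(th) {
    u <- unpack(th)
    IA <- Ip - u$A
    R <- cbind(-u$B, IA)
    RS <- R %*% S
    Wd <- rowSums(RS * R)
    if (any(Wd <= 0)) return(rep(0, k))
    G <- tryCatch(solve(IA), error = function(e) NULL)
    if (is.null(G)) return(rep(0, k))
    gA <- -2 * RS[, ie, drop = FALSE] / Wd + 2 * t(G)
    gB <- -2 * RS[, ix, drop = FALSE] / Wd
    c(gA[freeA], gB[freeB])
  }
  th0 <- if (is.null(start)) rep(0, k) else start
  converged <- TRUE
  if (k > 0) {
    opt <- optim(th0, obj, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    th <- opt$par
    gn <- sqrt(sum(grad(th)^2))
    if (gn >= 1e-6) {   # polish with a restart before declaring failure
      opt <- optim(th, obj, grad, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      th <- opt$par
      gn <- sqrt(sum(grad(th)^2))
    }
    Fml <- opt$value
    converged <- gn < 1e-6
  } else {
    th <- numeric(0); Fml <- obj(th0); gn <- 0
  }
  u <- unpack(th)
  R <- cbind(-u$B, Ip - u$A)
  psi <- rowSums((R %*% S) * R)
  if (any(psi < 1e-8))
    warning("Heywood case: innovation variance driven to zero for series ",
            paste(which(psi < 1e-8), collapse = ", "))
  list(A = u$A, B = u$B, psi = psi, Fml = max(Fml, 0),
       chi2 = max((n_eff - 1) * Fml, 0), gnorm = gn, converged = converged,
       theta = th)
}

#' Model-implied covariance matrix
#'
#' Assembles the covariance matrix implied by the regression parameters:
#' with x the stacked lagged (and input) variables and
#' \eqn{B = [\Phi_a ... \Phi_1 | \gamma | \tau]},
#' \eqn{\Sigma_{xe} = \Sigma_{xx} B' (I-A)^{-T}} and
#' \eqn{\Sigma_{ee} = (I-A)^{-1}(B \Sigma_{xx} B' + \Psi)(I-A)^{-T}};
#' the exogenous block \eqn{\Sigma_{xx}} is saturated.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param params a fitted parameter set from \code{\link{fit_ml}} (or any
#'   list with elements \code{A}, \code{B}, \code{psi}).
#' @param sigma_xx exogenous-block covariance ((m-p) x (m-p)).
#' @return symmetric m x m matrix.
#' @export
implied_sigma <- function(spec, params, sigma_xx) {
  A <- params$A; B <- params$B; psi <- params$psi
  p <- nrow(A)
  IA <- diag(p) - A
  if (abs(det(IA)) < 1e-12)
    stop("I - A is singular; offending contemporaneous matrix A:\n",
         paste(utils::capture.output(print(A)), collapse = "\n"))
  G <- solve(IA)
  if (ncol(B) == 0) {
    See <- G %*% diag(psi, p) %*% t(G)
    return((See + t(See)) / 2)
  }
  Sex <- G %*% B %*% sigma_xx
  See <- G %*% (B %*% sigma_xx %*% t(B) + diag(psi, p)) %*% t(G)
  Sig <- rbind(cbind(sigma_xx, t(Sex)), cbind(Sex, See))
  (Sig + t(Sig)) / 2
}

#' Maximum-likelihood fit of a uSEM-family model
#'
#' Minimizes the ML covariance-structure discrepancy
#' \eqn{F(\theta) = \log\det\Sigma(\theta) + tr(S \Sigma(\theta)^{-1})
#' - \log\det S - m} over the free regression coefficients, with the
#' exogenous block saturated and the diagonal innovation covariance
#' profiled.  \eqn{\chi^2 = (n_{eff}-1) F} at the optimum.  Standard
#' errors come from the inverse expected (Fisher) information scaled by
#' \eqn{2/(n_{eff}-1)}.
#'
#' @param S a \code{\link{block_toeplitz_cov}} result.
#' @param spec a \code{\link{model_spec}} consistent with \code{S}.
#' @param start optional start values (a previous fit's \code{theta}).
#' @param se compute standard errors (skippable in search inner loops).
#' @return list with elements \code{params} (class
#'   \code{"usem_params"}: \code{A}, \code{Phi}, \code{gamma},
#'   \code{tau}, \code{B}, \code{psi}, \code{table} of free-parameter
#'   estimates with SE and 95\% CI) and \code{fit} (class
#'   \code{"fit_result"}).
#' @export
fit_ml <- function(S, spec, start = NULL, se = TRUE) {
  stopifnot(inherits(S, "lagged_cov"), inherits(spec, "model_spec"))
  masks <- free_masks(spec)
  p <- spec$p
  mx <- S$m - p
  if (ncol(masks$B) != mx)
    stop("spec implies ", ncol(masks$B), " exogenous variables but S has ", mx)
  core <- .fit_core(S$S, p, masks$A, masks$B, S$n_eff, start)
  k_free <- sum(masks$A) + sum(masks$B)
  df <- model_df(p, spec$order, k_free, extra_exog = S$n_extra)
  Sxx <- S$S[seq_len(mx), seq_len(mx), drop = FALSE]
  params <- .unpack_params(spec, core, masks)
  Sigma <- implied_sigma(spec, params, Sxx)
  base <- .baseline_fit(S$S, S$n_eff)
  fit <- fit_indices(core$chi2, df, base$chi2, base$df, S$n_eff, S$S, Sigma)
  fit$converged <- core$converged
  fit$k_free <- k_free
  if (se && k_free > 0) {
    ses <- tryCatch(.param_se(S$S, spec, params, S$n_eff),
                    error = function(e) NULL)
    params <- .attach_se(spec, params, ses, S$n_eff)
  } else {
    params <- .attach_se(spec, params, NULL, S$n_eff)
  }
  params$theta <- core$theta
  params$sigma_xx <- Sxx
  list(params = params, fit = fit)
}

# split the regression-form estimates back into named matrices
.unpack_params <- function(spec, core, masks = free_masks(spec)) {
  lay <- masks$layout
  p <- spec$p
  Phi <- lapply(seq_len(spec$order), function(q)
    core$B[, lay$col[lay$kind == "roi" & lay$q == q], drop = FALSE])
  gamma <- if (spec$n_u > 0)
    lapply(0:spec$f, function(r)
      core$B[, lay$col[lay$kind == "input" & lay$r == r], drop = FALSE])
  else list()
  tau <- if (spec$n_u > 0 && spec$bilinear)
    unlist(lapply(seq_len(spec$g), function(q) lapply(seq_len(spec$h), function(r)
      core$B[, lay$col[lay$kind == "prod" & lay$q == q & lay$r == r],
             drop = FALSE])), recursive = FALSE)
  else list()
  structure(list(A = core$A, B = core$B, Phi = Phi, gamma = gamma, tau = tau,
                 psi = core$psi, spec = spec),
            class = "usem_params")
}

.attach_se <- function(spec, params, ses, n_eff) {
  tab <- param_table(spec)
  tab <- tab[tab$free, , drop = FALSE]
  lay <- x_layout(spec)
  est <- se <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$matrix[i] == "A") est[i] <- params$A[tab$row[i], tab$col[i]]
    else est[i] <- params$B[tab$row[i], param_bcol(spec, tab[i, ], lay)]
    se[i] <- if (is.null(ses)) NA_real_ else ses$by_id[[tab$id[i]]]
  }
  tab$estimate <- est
  tab$se <- se
  tab$z <- est / se
  tab$p_value <- 2 * pnorm(-abs(tab$z))
  tab$ci_low <- est - 1.96 * se
  tab$ci_high <- est + 1.96 * se
  params$table <- tab[, c("id", "matrix", "q", "r", "row", "col", "lag",
                          "estimate", "se", "z", "p_value",
                          "ci_low", "ci_high")]
  params
}

#' @export
print.usem_params <- function(x, ...) {
  cat("uSEM parameter estimates (", nrow(x$table), " free coefficients)\n",
      sep = "")
  if (nrow(x$table))
    print(x$table[, c("id", "estimate", "se", "ci_low", "ci_high")],
          digits = 3, row.names = FALSE)
  cat("innovation variances:", signif(x$psi, 3), "\n")
  invisible(x)
}

# independence baseline: diagonal Sigma with free variances
.baseline_fit <- function(S, n_eff) {
  m <- nrow(S)
  R <- cov2cor(S)
  chi2 <- max(-(n_eff - 1) * as.numeric(determinant(R)$modulus), 0)
  list(chi2 = chi2, df = m * (m - 1) / 2)
}
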