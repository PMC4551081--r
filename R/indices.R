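#' Goodness-of-fit indices for a covariance-structure fit
#'
#' Computes the four alternative fit indices used throughout the model
#' family, against the independence baseline (diagonal implied
#' covariance, variances free, df = m(m-1)/2):
#' \itemize{
#'   \item RMSEA \eqn{= \sqrt{\max(\chi^2-df,0)/(df (n_{eff}-1))}}
#'     (0 when df = 0);
#'   \item SRMR: root mean square of the standardized covariance
#'     residuals \eqn{(s_{jk}-\sigma_{jk})/\sqrt{s_{jj} s_{kk}}} over
#'     j <= k;
#'   \item CFI \eqn{= 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,
#'     \chi^2-df, 0)}, clipped to the unit interval;
#'   \item NNFI (TLI) \eqn{= ((\chi^2_b/df_b)-(\chi^2/df))/
#'     ((\chi^2_b/df_b)-1)}, reported unclipped, missing when df = 0.
#' }
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param baseline_chi2,baseline_df independence-baseline values.
#' @param n_eff effective sample size.
#' @param S,Sigma observed and implied covariance matrices (for SRMR).
#' @return object of class \code{"fit_result"}.
#' @export
fit_indices <- function(chi2, df, baseline_chi2, baseline_df, n_eff,
                        S, Sigma) {
  excess <- max(chi2 - df, 0)
  rmsea <- if (df == 0) 0 else sqrt(excess / (df * (n_eff - 1)))
  d <- sqrt(diag(S))
  Rres <- (S - Sigma) / outer(d, d)
  srmr <- sqrt(mean(Rres[upper.tri(Rres, diag = TRUE)]^2))
  denom <- max(baseline_chi2 - baseline_df, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - excess / denom
  cfi <- min(max(cfi, 0), 1)
  nnfi <- if (df == 0 || baseline_df == 0) NA_real_ else {
    rb <- baseline_chi2 / baseline_df
    if (abs(rb - 1) < .Machine$double.eps) NA_real_
    else (rb - chi2 / df) / (rb - 1)
  }
  structure(list(chi2 = chi2, df = as.integer(df),
                 p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE)
                           else NA_real_,
                 rmsea = rmsea, srmr = srmr, cfi = cfi, nnfi = nnfi,
                 baseline_chi2 = baseline_chi2,
                 baseline_df = as.integer(baseline_df),
                 converged = TRUE, n_eff = n_eff),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.2f (p %s), n_eff = %d%s\n", x$df, x$chi2,
              if (is.na(x$p_value)) "= NA" else sprintf("= %.3g", x$p_value),
              x$n_eff,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("RMSEA = %.3f  SRMR = %.3f  CFI = %.3f  NNFI = %s\n",
              x$rmsea, x$srmr, x$cfi,
              if (is.na(x$nnfi)) "NA" else sprintf("%.3f", x$nnfi)))
  invisible(x)
}

#' Two-of-four excellent-fit rule
#'
#' A model is accepted when at least \code{n_pass} of the four
#' alternative index tests pass: RMSEA <= \code{rmsea_max},
#' SRMR <= \code{srmr_max}, CFI >= \code{cfi_min},
#' NNFI >= \code{nnfi_min}.  Boundary equality passes; a missing index
#' counts as a failed test.
#'
#' @param fr a \code{\link{fit_indices}} result.
#' @param cfg a \code{\link{usem_config}}.
#' @return logical.
#' @export
excellent_fit <- function(fr, cfg = usem_config()) {
  tests <- c(!is.na(fr$rmsea) && fr$rmsea <= cfg$rmsea_max,
             !is.na(fr$srmr) && fr$srmr <= cfg$srmr_max,
             !is.na(fr$cfi) && fr$cfi >= cfg$cfi_min,
             !is.na(fr$nnfi) && fr$nnfi >= cfg$nnfi_min)
  sum(tests) >= cfg$n_pass
}
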