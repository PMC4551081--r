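#' Wald trimming of non-significant parameters
#'
#' Iteratively fixes to zero the free regression coefficient with the
#' largest Wald p-value at or above \code{alpha}, refits, and repeats
#' until every remaining free regression coefficient is significant.
#' Innovation variances and the exogenous block are never pruned.
#'
#' @param S a \code{\link{block_toeplitz_cov}} result.
#' @param spec the fitted \code{\link{model_spec}}.
#' @param fit a \code{\link{fit_ml}} result for \code{spec} (refitted if
#'   \code{NULL}).
#' @param alpha significance level; default 0.05.
#' @param protect optional \code{\link{model_spec}} whose free parameters
#'   must not be pruned (e.g. the group-level mask in GIMME stage 2).
#' @return list with the pruned \code{spec}, \code{params}, \code{fit}.
#' @export
wald_prune <- function(S, spec, fit = NULL, alpha = 0.05, protect = NULL) {
  if (is.null(fit)) fit <- fit_ml(S, spec)
  repeat {
    tab <- fit$params$table
    if (nrow(tab) == 0) break
    eligible <- rep(TRUE, nrow(tab))
    if (!is.null(protect))
      eligible <- !vapply(seq_len(nrow(tab)), function(i)
        isTRUE(spec_get(protect, tab[i, ])), NA)
    pv <- tab$p_value
    pv[!eligible | is.na(pv)] <- -1
    worst <- which.max(pv)
    if (pv[worst] < alpha) break
    new_spec <- spec_set(spec, tab[worst, ], FALSE)
    new_fit <- tryCatch(fit_ml(S, new_spec), error = function(e) NULL)
    if (is.null(new_fit) || !new_fit$fit$converged) {
      warning("pruning ", tab$id[worst],
              " left a non-convergent model; reverting and stopping")
      break
    }
    spec <- new_spec
    fit <- new_fit
  }
  list(spec = spec, params = fit$params, fit = fit$fit)
}
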