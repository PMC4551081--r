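#' Fit a unified structural equation model (uSEM) to ROI time series
#'
#' Maps directed functional connectivity among p ROI series as a
#' structural VAR with contemporaneous (\code{A}) and lagged
#' (\code{Phi_q}) regression matrices, fitted by maximum likelihood on
#' the block-Toeplitz lagged covariance of the centered series.
#'
#' In the data-driven mode (\code{method = "search"}) the fit starts
#' from the null model (empty \code{A} and \code{Phi_q}) and repeatedly
#' frees the candidate connection with the largest significant
#' modification index, refitting until no candidate would significantly
#' improve fit, then trims non-significant parameters with Wald tests.
#' In the confirmatory mode the supplied \code{spec} is fitted once,
#' with no search.
#'
#' @param ts a \code{\link{roi_ts}} (or T x p matrix); centered
#'   automatically.
#' @param order model order (maximum lag); overrides \code{config$order}.
#' @param method \code{"search"} (data-driven) or \code{"confirmatory"}.
#' @param spec a \code{\link{model_spec}} -- required for confirmatory
#'   fits.
#' @param input optional \code{\link{input_series}} for euSEM terms (see
#'   \code{\link{eusem}}).
#' @param config a \code{\link{usem_config}}.
#' @param base optional \code{\link{model_spec}} whose free parameters
#'   seed the search and are protected from Wald trimming (used by the
#'   GIMME individual stage).
#' @return an object of class \code{"usem"}: list with the series,
#'   final \code{spec}, \code{params} (estimates, SEs, CIs),
#'   \code{fit} (chi-square and fit indices), the search path, and the
#'   configuration.
#' @seealso \code{\link{eusem}}, \code{\link{gimme}},
#'   \code{\link{validate_order}}
#' @export
#' @examples
#' sim <- simulate_usem(scenario_3roi_lag2(), seed = 1)
#' m <- usem(sim, order = 1)
#' summary(m)
usem <- function(ts, order = config$order,
                 method = c("search", "confirmatory"),
                 spec = NULL, input = NULL,
                 config = usem_config(), base = NULL) {
  method <- match.arg(method)
  if (!inherits(ts, "roi_ts")) ts <- roi_ts(ts)
  if (!ts$centered) ts <- center(ts, standardize = config$standardize)
  if (!is.null(input)) {
    if (!inherits(input, "input_series")) input <- input_series(input)
    if (is.null(input$convolved))
      input <- convolve_input(input, hrf_double_gamma(ts$tr_seconds))
    if (all(abs(input$convolved) < 1e-12)) {
      warning("task input is constant zero; excluding gamma/tau candidates")
      input <- NULL
    }
  }
  S <- block_toeplitz_cov(ts, order, input,
                          f = config$f, g = config$g, h = config$h)
  if (method == "confirmatory") {
    if (is.null(spec)) stop("confirmatory fit requires a model spec")
    if (any(diag(spec$free_A))) stop("the diagonal of A cannot be freed")
    if (spec$order != order)
      stop("spec order (", spec$order, ") differs from requested order (",
           order, ")")
    ans <- fit_ml(S, spec)
    return(.new_usem(ts, input, spec, ans, S, config, method,
                     search = NULL, base = base))
  }
  .usem_search(ts, input, S, order, config, base)
}

#' Fit an extended uSEM (euSEM) with task input
#'
#' The euSEM augments the uSEM with direct effects \code{gamma_r} of an
#' HRF-convolved task input on each ROI (lags r = 0..f) and bilinear
#' modulating effects \code{tau_qr} of the input on lagged ROI-to-ROI
#' connections, realized as regressions on appended input and product
#' variables.  The data-driven search protocol is identical to
#' \code{\link{usem}} over the enlarged candidate set.
#'
#' @param ts a \code{\link{roi_ts}}.
#' @param input an \code{\link{input_series}}; convolved with the
#'   default double-gamma kernel if still raw.
#' @param order model order.
#' @param config a \code{\link{usem_config}} (fields \code{f}, \code{g},
#'   \code{h} bound the input lags).
#' @param ... passed to \code{\link{usem}}.
#' @return a \code{"usem"} object.
#' @export
eusem <- function(ts, input, order = config$order,
                  config = usem_config(), ...) {
  if (is.null(input)) stop("euSEM requires a task input; use usem() without one")
  usem(ts, order = order, input = input, config = config, ...)
}

.null_spec <- function(ts, input, order, config) {
  n_u <- if (is.null(input)) 0L else nrow(input$raw)
  model_spec(nrow(ts$values), order, ts$labels, n_u = n_u,
             f = config$f, g = config$g, h = config$h,
             bilinear = n_u == 1)
}

.usem_search <- function(ts, input, S, order, config, base = NULL) {
  spec <- .null_spec(ts, input, order, config)
  if (!is.null(base)) spec <- spec_union(spec_extend(base, order), spec)
  cand <- param_table(spec)
  cand <- cand[!cand$free, , drop = FALSE]
  crit <- qchisq(1 - config$mi_alpha, 1)
  fit <- fit_ml(S, spec, se = FALSE)
  path <- list()
  n_freed <- 0
  repeat {
    if (nrow(cand) == 0 || n_freed >= config$max_free) break
    # the search stops as soon as the model reaches excellent fit (or no
    # candidate would significantly improve it); residual misfit beyond
    # that point is the job of the a posteriori validation loop
    if (excellent_fit(fit$fit, config)) break
    # freeing one more must leave non-negative df
    df_ok <- tryCatch({
      model_df(spec$p, spec$order, fit$fit$k_free + 1, S$n_extra); TRUE
    }, error = function(e) FALSE)
    if (!df_ok) break
    mi <- modification_indices(S, spec, fit$params, cand)
    top <- which.max(mi$mi)   # first max = lowest (lag, target, source)
    if (mi$mi[top] <= crit) break
    pick <- mi[top, ]
    new_spec <- spec_set(spec, pick, TRUE)
    new_fit <- tryCatch(fit_ml(S, new_spec, se = FALSE),
                        error = function(e) NULL)
    if (pick$matrix == "gamma") {
      # HRF-convolved input regressors at adjacent lags are nearly collinear,
      # so the MI locates the direct effect but not its lag; compare the
      # candidate lags of the same effect by refit and keep the best
      alts <- which(cand$matrix == "gamma" & cand$row == pick$row &
                      cand$col == pick$col & cand$r != pick$r)
      for (ai in alts) {
        a_spec <- spec_set(spec, cand[ai, ], TRUE)
        a_fit <- tryCatch(fit_ml(S, a_spec, se = FALSE),
                          error = function(e) NULL)
        if (!is.null(a_fit) && a_fit$fit$converged &&
            (is.null(new_fit) || !new_fit$fit$converged ||
             a_fit$fit$chi2 < new_fit$fit$chi2 - 1e-8)) {
          pick <- cand[ai, ]
          new_spec <- a_spec
          new_fit <- a_fit
        }
      }
    }
    if (pick$matrix == "A") {
      # the MI locates the contemporaneous pair; the orientation is decided
      # by which direction improves the likelihood more on refit
      recip <- which(cand$matrix == "A" & cand$row == pick$col &
                       cand$col == pick$row)
      if (length(recip) == 1) {
        r_spec <- spec_set(spec, cand[recip, ], TRUE)
        r_fit <- tryCatch(fit_ml(S, r_spec, se = FALSE),
                          error = function(e) NULL)
        take_recip <- FALSE
        if (!is.null(r_fit) && r_fit$fit$converged) {
          if (is.null(new_fit) || !new_fit$fit$converged) take_recip <- TRUE
          else if (r_fit$fit$chi2 < new_fit$fit$chi2 - 1e-8) take_recip <- TRUE
          else if (abs(r_fit$fit$chi2 - new_fit$fit$chi2) <= 1e-8) {
            # exact tie (covariance-equivalent orientations): break it by a
            # label-free convention -- the higher-variance series is the
            # source -- so the search commutes with ROI relabeling
            v <- diag(S$S)[S$m - spec$p + seq_len(spec$p)]
            take_recip <- v[cand$col[recip]] > v[pick$col]
          }
        }
        if (take_recip) {
          pick <- cand[recip, ]
          new_spec <- r_spec
          new_fit <- r_fit
        }
      }
    }
    if (is.null(new_fit) || !new_fit$fit$converged ||
        new_fit$fit$chi2 > fit$fit$chi2 + 1e-6 * max(fit$fit$chi2, 1)) {
      # revert (e.g. reciprocal pair rendering I-A near-singular) and skip
      cand <- cand[cand$id != pick$id, , drop = FALSE]
      next
    }
    path[[length(path) + 1]] <- list(id = pick$id, mi = mi$mi[top],
                                     chi2 = new_fit$fit$chi2)
    spec <- new_spec
    fit <- new_fit
    cand <- cand[cand$id != pick$id, , drop = FALSE]
    n_freed <- n_freed + 1
  }
  spec <- .orient_contemporaneous(S, spec, base)
  pruned <- wald_prune(S, spec, fit_ml(S, spec), alpha = config$mi_alpha,
                       protect = base)
  ans <- list(params = pruned$params, fit = pruned$fit)
  .new_usem(ts, input, pruned$spec, ans, S, config, "search",
            search = path, base = base)
}

# Re-evaluate the orientation of each freed contemporaneous edge against the
# final fitted structure: when an A edge was freed early in the search (e.g.
# from the null model, where the two orientations of a pair are
# covariance-equivalent), the lagged structure added later can identify the
# direction, so each freed A[k,l] is compared with its reversal by refit and
# the better-fitting orientation kept.  Group-level (base) edges are left
# untouched.
.orient_contemporaneous <- function(S, spec, base = NULL) {
  fit <- fit_ml(S, spec, se = FALSE)
  # try the coherent reversal of all swappable edges first: a consistently
  # mis-oriented edge set can be locally optimal under single flips
  unpaired <- spec$free_A & !t(spec$free_A)
  if (!is.null(base)) unpaired <- unpaired & !base$free_A
  if (any(unpaired)) {
    rev_all <- spec
    rev_all$free_A <- (spec$free_A & !unpaired) | t(unpaired)
    rv <- tryCatch(fit_ml(S, rev_all, se = FALSE), error = function(e) NULL)
    if (!is.null(rv) && rv$fit$converged &&
        rv$fit$chi2 < fit$fit$chi2 - 1e-6) {
      spec <- rev_all
      fit <- rv
    }
  }
  repeat {
    improved <- FALSE
    idx <- which(spec$free_A, arr.ind = TRUE)
    for (e in seq_len(nrow(idx))) {
      k <- idx[e, 1]; l <- idx[e, 2]
      if (!spec$free_A[k, l] || spec$free_A[l, k]) next
      if (!is.null(base) && isTRUE(base$free_A[k, l])) next
      sw <- spec
      sw$free_A[k, l] <- FALSE
      sw$free_A[l, k] <- TRUE
      sw_fit <- tryCatch(fit_ml(S, sw, se = FALSE), error = function(e) NULL)
      if (!is.null(sw_fit) && sw_fit$fit$converged &&
          sw_fit$fit$chi2 < fit$fit$chi2 - 1e-6) {
        spec <- sw
        fit <- sw_fit
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  spec
}

.new_usem <- function(ts, input, spec, ans, S, config, method, search, base) {
  structure(list(ts = ts, input = input, spec = spec,
                 params = ans$params, fit = ans$fit,
                 S = S, config = config, method = method,
                 search = search, base = base),
            class = "usem")
}

#' @export
print.usem <- function(x, ...) {
  kind <- if (!is.null(x$input)) "euSEM" else "uSEM"
  cat(sprintf("%s(%d), %s fit: p = %d ROIs, T = %d, %d freed parameters\n",
              kind, x$spec$order, x$method, x$spec$p, ncol(x$ts$values),
              spec_k_free(x$spec)))
  print(x$fit)
  invisible(x)
}

#' @export
summary.usem <- function(object, ...) {
  structure(list(model = object,
                 excellent = excellent_fit(object$fit, object$config)),
            class = "summary.usem")
}

#' @export
print.summary.usem <- function(x, ...) {
  print(x$model)
  cat(if (x$excellent) "model accepted" else "model NOT accepted",
      "under the", x$model$config$n_pass, "of 4 excellent-fit rule\n")
  if (nrow(x$model$params$table)) {
    cat("\ncoefficients:\n")
    print(x$model$params$table[, c("id", "estimate", "se", "z", "p_value",
                                   "ci_low", "ci_high")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.usem <- function(object, ...) {
  setNames(object$params$table$estimate, object$params$table$id)
}

#' One-step-ahead prediction errors of a fitted model
#'
#' The realized innovations
#' \eqn{\hat\zeta(t) = (I-\hat A) y(t) - \sum_q \hat\Phi_q y(t-q)
#' - \sum_r \hat\gamma_r u(t-r) - \sum_{q,r} \hat\tau_{qr} y(t-q) u(t-r)}
#' for t = a+1..T; the first a time points are dropped.
#'
#' @param ts a centered \code{\link{roi_ts}}.
#' @param params fitted parameters (a \code{\link{fit_ml}} result's
#'   \code{params}, or a \code{"usem"} object's).
#' @param input the input series used in the fit, if any.
#' @return a \code{\link{roi_ts}} of class \code{c("resid_ts",
#'   "roi_ts")} with \code{a_used} recording the dropped history.
#' @export
prediction_errors <- function(ts, params, input = NULL) {
  spec <- params$spec
  y <- ts$values
  p <- nrow(y); T <- ncol(y)
  if (!ts$centered) stop("series must be centered")
  if (spec$n_u > 0) {
    if (is.null(input) || is.null(input$convolved))
      stop("fitted model includes input terms; supply the convolved input")
    des <- .design_extras(y, input$convolved, spec$order,
                          spec$f, spec$g, spec$h, spec$bilinear, ts$labels)
    a_used <- des$maxlag
    nlag <- p * spec$order
    X <- cbind(des$roi_lags[, seq_len(nlag), drop = FALSE], des$extras)
    E <- des$roi_lags[, nlag + seq_len(p), drop = FALSE]
  } else {
    a_used <- spec$order
    rows <- (a_used + 1):T
    X <- do.call(cbind, lapply(seq_len(spec$order), function(i)
      t(y[, rows - (spec$order - i + 1), drop = FALSE])))
    if (is.null(X)) X <- matrix(0, length(rows), 0)
    E <- t(y[, rows, drop = FALSE])
  }
  IA <- diag(p) - params$A
  Z <- E %*% t(IA) - (if (ncol(X) > 0) X %*% t(params$B) else 0)
  out <- roi_ts(Z, labels = ts$labels, tr_seconds = ts$tr_seconds)
  out$a_used <- a_used
  class(out) <- c("resid_ts", class(out))
  out
}

#' @export
residuals.usem <- function(object, ...) {
  prediction_errors(object$ts, object$params, object$input)
}

#' @export
fitted.usem <- function(object, ...) {
  z <- prediction_errors(object$ts, object$params, object$input)
  y <- object$ts$values[, (z$a_used + 1):ncol(object$ts$values), drop = FALSE]
  y - z$values
}

#' @export
simulate.usem <- function(object, nsim = 1, seed = NULL, T = NULL, ...) {
  spec <- object$spec
  ssp <- sim_spec(p = spec$p, T = if (is.null(T)) ncol(object$ts$values) else T,
                  order = spec$order, A = object$params$A,
                  Phi = object$params$Phi,
                  innovation_cov = diag(object$params$psi, spec$p),
                  seed = seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_usem(ssp, seed = if (is.null(seed)) NULL else seed + i - 1))
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.usem <- function(x, ...) {
  g <- .map_igraph(edge_list(x), x$ts$labels)
  plot(g, edge.label = signif(igraph::E(g)$estimate, 2), ...)
  invisible(x)
}
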