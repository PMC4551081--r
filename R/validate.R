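#' Decision criteria after a failed white-noise test
#'
#' When a map's prediction errors are not white, the residual
#' modification indices drive the revision: if only a few (at most
#' \code{config$few_threshold}) lagged dependencies are significant,
#' the corresponding model parameters are freed in a confirmatory refit
#' (option a); when more are significant with no clear pattern, a
#' data-driven search at the next order is run instead (option b).
#' Option c (subdividing a long, possibly non-stationary series) is a
#' manual route via \code{\link{validate_segments}} and is never
#' auto-selected.
#'
#' A residual dependency at lag l from ROI j to ROI k maps to the model
#' parameter \code{Phi_l[k,j]} (contemporaneous misfit would map to
#' \code{A[k,j]}), raising the model order when l exceeds it.
#'
#' Order escalation is stepwise: residual dependencies at lags more than
#' one above the current model order are disregarded when choosing and
#' mapping (deeper lags are reconsidered at the next iteration once the
#' intermediate order is in place).
#'
#' @param wn a failed \code{\link{white_noise_test}}.
#' @param config a \code{\link{usem_config}}.
#' @param current_spec optional current \code{\link{model_spec}}; mapped
#'   parameters already free are dropped (falling back to option b when
#'   none remain).
#' @param max_lag highest residual lag considered (default: current
#'   order + 1 when a spec is given, else \code{wn$L}).
#' @return list with \code{action} (\code{"option_a"} or
#'   \code{"option_b"}) and, for option a, \code{mapped} -- the rows of
#'   model parameters to free.
#' @export
decide_option <- function(wn, config = usem_config(), current_spec = NULL,
                          max_lag = if (is.null(current_spec)) wn$L
                                    else current_spec$order + 1) {
  if (isTRUE(wn$passed))
    stop("decide_option() applies only to failed white-noise tests")
  crit <- qchisq(1 - config$mi_alpha, 1)
  sig <- as.data.frame(wn$mi)[wn$mi$mi > crit & wn$mi$lag <= max_lag, ,
                              drop = FALSE]
  if (nrow(sig) > 0 && !is.null(current_spec)) {
    keep <- vapply(seq_len(nrow(sig)), function(i) {
      par <- sig[i, ]
      if (par$matrix == "Phi" && par$q > current_spec$order) return(TRUE)
      !isTRUE(spec_get(current_spec, par))
    }, NA)
    sig <- sig[keep, , drop = FALSE]
  }
  if (nrow(sig) >= 1 && nrow(sig) <= config$few_threshold)
    list(action = "option_a", mapped = sig)
  else
    list(action = "option_b", mapped = NULL)
}

#' A posteriori validation of the temporal order of a fitted map
#'
#' Iterates white-noise testing and map revision: the model's
#' one-step-ahead prediction errors are tested against the lag-L VAR
#' white-noise null; on failure the map is revised -- a confirmatory
#' refit freeing the few implicated parameters (option a, raising the
#' order when needed) or a data-driven search at the next order (option
#' b, from the group mask when one is attached) -- and re-validated.
#' The loop accepts when residuals are white, and gives up when the
#' order would exceed \code{max_order} or a previously visited
#' specification recurs.
#'
#' @param model a fitted \code{"usem"} object.
#' @param config a \code{\link{usem_config}}.
#' @param max_order highest order to escalate to.
#' @return an object of class \code{"validation_trace"}: per-iteration
#'   records (model, white-noise result, action), \code{final_order},
#'   \code{final_model}, \code{accepted}.
#' @export
validate_order <- function(model, config = model$config,
                           max_order = config$max_order) {
  stopifnot(inherits(model, "usem"))
  records <- list()
  seen <- character(0)
  cur <- model
  give_up <- function(reason, wn = NULL) {
    records[[length(records) + 1]] <<-
      list(order = cur$spec$order, fit = cur$fit, wn = wn,
           action = "give_up", reason = reason,
           spec_ids = .free_ids(cur$spec))
  }
  accepted <- FALSE
  for (iter in seq_len(2 * max_order + 4)) {
    seen <- c(seen, spec_hash(cur$spec))
    wn <- tryCatch(white_noise_test(residuals(cur), config$L, config),
                   error = function(e) NULL)
    if (is.null(wn)) { give_up("white-noise test failed"); break }
    if (wn$passed) {
      # trim any non-significant (e.g. confirmatory-mapped) parameters,
      # keeping the pruned model only if its residuals are still white
      trimmed <- .trim_accepted(cur, config)
      if (!is.null(trimmed)) { cur <- trimmed$model; wn <- trimmed$wn }
      records[[length(records) + 1]] <-
        list(order = cur$spec$order, fit = cur$fit, wn = wn,
             action = "accept", spec_ids = .free_ids(cur$spec))
      accepted <- TRUE
      break
    }
    dec <- decide_option(wn, config, cur$spec)
    if (dec$action == "option_a") {
      new_order <- max(cur$spec$order, max(dec$mapped$lag))
      if (new_order > max_order) { give_up("order cap reached", wn); break }
      nspec <- spec_extend(cur$spec, new_order)
      for (i in seq_len(nrow(dec$mapped)))
        nspec <- spec_set(nspec, dec$mapped[i, ], TRUE)
      if (spec_hash(nspec) %in% seen) { give_up("revisited spec", wn); break }
      new_model <- tryCatch(
        usem(cur$ts, order = new_order, method = "confirmatory",
             spec = nspec, input = cur$input, config = config),
        error = function(e) NULL)
    } else {
      new_order <- cur$spec$order + 1
      if (new_order > max_order) { give_up("order cap reached", wn); break }
      base <- model$base
      new_model <- tryCatch(
        usem(cur$ts, order = new_order, input = cur$input,
             config = config, base = base),
        error = function(e) NULL)
    }
    if (is.null(new_model) || !new_model$fit$converged) {
      give_up("revision did not converge", wn); break
    }
    if (spec_hash(new_model$spec) %in% seen) { give_up("revisited spec", wn); break }
    records[[length(records) + 1]] <-
      list(order = cur$spec$order, fit = cur$fit, wn = wn,
           action = dec$action,
           mapped = if (!is.null(dec$mapped)) dec$mapped$id,
           spec_ids = .free_ids(cur$spec))
    cur <- new_model
  }
  if (!accepted && (!length(records) ||
                    records[[length(records)]]$action != "give_up"))
    give_up("iteration cap reached")
  structure(list(records = records, final_model = cur,
                 final_order = .effective_order(cur$spec),
                 accepted = accepted),
            class = "validation_trace")
}

# the order a map actually carries: the highest lag with a freed connection
# (a higher-order container whose deep lags were all trimmed away is not a
# higher-order map)
.effective_order <- function(spec) {
  lags <- which(vapply(spec$free_Phi, any, NA))
  as.integer(max(1L, lags, na.rm = TRUE))
}

# Wald-trim an accepted model (protecting its group base); returns NULL when
# nothing was pruned or the pruned model's residuals are no longer white
.trim_accepted <- function(model, config) {
  pruned <- tryCatch(
    wald_prune(model$S, model$spec,
               list(params = model$params, fit = model$fit),
               alpha = config$mi_alpha, protect = model$base),
    error = function(e) NULL)
  if (is.null(pruned) || spec_hash(pruned$spec) == spec_hash(model$spec))
    return(NULL)
  new_model <- model
  new_model$spec <- pruned$spec
  new_model$params <- pruned$params
  new_model$fit <- pruned$fit
  new_model$method <- model$method
  wn2 <- tryCatch(white_noise_test(residuals(new_model), config$L, config),
                  error = function(e) NULL)
  if (is.null(wn2) || !wn2$passed) return(NULL)
  list(model = new_model, wn = wn2)
}

.free_ids <- function(spec) {
  tab <- param_table(spec)
  tab$id[tab$free]
}

#' @export
print.validation_trace <- function(x, ...) {
  cat("temporal-order validation:", length(x$records), "iteration(s),",
      if (x$accepted) "ACCEPTED" else "GAVE UP", "at order",
      x$final_order, "\n")
  for (i in seq_along(x$records)) {
    r <- x$records[[i]]
    cat(sprintf("\n-- iteration %d: order-%d model (%d connections) --\n",
                i, r$order, length(r$spec_ids)))
    cat("MODEL FIT\n"); print(r$fit)
    if (!is.null(r$wn)) { cat("WHITE NOISE TEST\n"); print(r$wn$fit) }
    cat("action:", r$action,
        if (!is.null(r$mapped)) paste0("(freeing ",
                                       paste(r$mapped, collapse = ", "), ")"),
        if (!is.null(r$reason)) paste0("(", r$reason, ")"), "\n")
  }
  invisible(x)
}

#' Validate every subject of a GIMME fit
#'
#' Runs \code{\link{validate_order}} per subject with the group-level
#' mask held as the permanent base of any revision (the null model of a
#' higher-order individual search is the group model, so the
#' group-level structure is maintained), and reports how many subjects
#' require connections beyond order 1.
#'
#' @param gm a \code{\link{gimme}} fit.
#' @param config a \code{\link{usem_config}}.
#' @param max_order highest order to escalate to.
#' @return object of class \code{"group_validation"}: per-subject
#'   \code{traces}, \code{n_above_order1}, \code{fraction_above_order1}.
#' @export
validate_group <- function(gm, config = gm$config,
                           max_order = config$max_order) {
  stopifnot(inherits(gm, "gimme"))
  traces <- lapply(gm$fits, function(f)
    tryCatch(validate_order(f, config, max_order), error = function(e) e))
  ok <- !vapply(traces, inherits, NA, "error")
  orders <- vapply(traces[ok], function(tr) tr$final_order, 0)
  acc <- vapply(traces[ok], function(tr) tr$accepted, NA)
  n_above <- sum(orders > 1)
  structure(list(traces = traces, subject_ids = gm$subject_ids,
                 failed = gm$subject_ids[!ok],
                 accepted = acc,
                 final_orders = orders,
                 n_above_order1 = n_above,
                 fraction_above_order1 = n_above / sum(ok)),
            class = "group_validation")
}

#' @export
print.group_validation <- function(x, ...) {
  n <- length(x$final_orders)
  cat("group temporal-order validation:", n, "subjects\n")
  cat(sprintf("subjects requiring order > 1: %d of %d (%.0f%%)\n",
              x$n_above_order1, n, 100 * x$fraction_above_order1))
  if (length(x$failed))
    cat("validation failed for:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Manual series-subdivision validation (option c)
#'
#' For long series suspected of task-related non-stationarity, splits
#' the series at the given boundaries, refits the model on each segment
#' and validates each independently.  Requires
#' \code{config$allow_subdivision}.
#'
#' @param model a fitted \code{"usem"}.
#' @param boundaries time indices at which to cut the series.
#' @param config a \code{\link{usem_config}} with
#'   \code{allow_subdivision = TRUE}.
#' @return list of per-segment \code{\link{validate_order}} traces.
#' @export
validate_segments <- function(model, boundaries, config = model$config) {
  if (!isTRUE(config$allow_subdivision))
    stop("series subdivision (option c) must be enabled explicitly via ",
         "usem_config(allow_subdivision = TRUE)")
  T <- ncol(model$ts$values)
  cuts <- sort(unique(c(1, boundaries, T + 1)))
  lapply(seq_len(length(cuts) - 1), function(i) {
    idx <- cuts[i]:(cuts[i + 1] - 1)
    seg <- roi_ts(model$ts$values[, idx, drop = FALSE],
                  labels = model$ts$labels,
                  tr_seconds = model$ts$tr_seconds, orientation = "roi")
    m <- usem(seg, order = model$spec$order, input = model$input,
              config = config)
    validate_order(m, config)
  })
}

#' Serialize a validation trace to JSON
#'
#' Writes the per-iteration record (freed connections, fit indices,
#' white-noise indices, action) machine-readably.
#'
#' @param trace a \code{\link{validate_order}} result.
#' @param path output file.
#' @export
trace_to_json <- function(trace, path) {
  recs <- lapply(trace$records, function(r) {
    list(order = r$order,
         connections = r$spec_ids,
         fit = r$fit[c("chi2", "df", "p_value", "rmsea", "srmr",
                       "cfi", "nnfi")],
         white_noise = if (!is.null(r$wn))
           c(r$wn$fit[c("chi2", "df", "p_value", "rmsea", "srmr",
                        "cfi", "nnfi")], passed = r$wn$passed),
         action = r$action,
         mapped = r$mapped,
         reason = r$reason)
  })
  jsonlite::write_json(
    list(accepted = trace$accepted, final_order = trace$final_order,
         iterations = recs),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
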