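#' Model specification: free and fixed parameters of a uSEM-family model
#'
#' A \code{model_spec} records which regression coefficients of the model
#' are freely estimated: contemporaneous ROI-to-ROI effects \code{A}
#' (diagonal structurally fixed to zero), lagged effects \code{Phi_q} for
#' q = 1..order, and -- when a task input is attached -- direct input
#' effects \code{gamma_r} (r = 0..f) and bilinear modulating effects
#' \code{tau_qr} (q = 1..g, r = 1..h), realized as regressions on
#' appended input and product variables.  The innovation variances and
#' the exogenous (lagged/input) block covariance are always free and are
#' not part of the mask.
#'
#' @param p number of ROI series.
#' @param order maximum ROI lag (model order) a >= 0.
#' @param labels optional ROI labels.
#' @param n_u number of input vectors (0 = no input).
#' @param f,g,h input lag bounds (see \code{\link{usem_config}}).
#' @param bilinear include bilinear \code{tau} terms (requires a single
#'   input vector).
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(p, order = 1, labels = NULL, n_u = 0,
                       f = 1, g = 1, h = 1, bilinear = n_u == 1) {
  stopifnot(p >= 1, order >= 0, n_u >= 0)
  if (bilinear && n_u != 1)
    stop("bilinear terms require exactly one input vector")
  if (is.null(labels)) labels <- paste0("ROI", seq_len(p))
  spec <- list(p = as.integer(p), order = as.integer(order), labels = labels,
               n_u = n_u, f = f, g = g, h = h, bilinear = bilinear,
               free_A = matrix(FALSE, p, p),
               free_Phi = if (order > 0)
                 lapply(seq_len(order), function(q) matrix(FALSE, p, p))
               else list(),
               free_gamma = if (n_u > 0)
                 lapply(0:f, function(r) matrix(FALSE, p, n_u))
               else list(),
               free_tau = if (n_u > 0 && bilinear)
                 lapply(seq_len(g * h), function(i) matrix(FALSE, p, p))
               else list())
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("uSEM model spec: p =", x$p, ", order =", x$order,
      if (x$n_u > 0) paste0(", inputs = ", x$n_u) else "", "\n")
  cat("free parameters:", spec_k_free(x), "\n")
  invisible(x)
}

.tau_index <- function(spec, q, r) (q - 1L) * spec$h + r

# number of appended exogenous (input + product) variables
spec_n_extra <- function(spec) {
  if (spec$n_u == 0) return(0L)
  as.integer((spec$f + 1) * spec$n_u +
               if (spec$bilinear) spec$g * spec$h * spec$p else 0L)
}

# layout of the stacked exogenous vector x: ROI lag blocks (oldest first),
# then input lags, then bilinear product variables
x_layout <- function(spec) {
  p <- spec$p; a <- spec$order
  out <- list()
  if (a > 0)
    for (q in a:1)
      out[[length(out) + 1]] <- data.frame(
        kind = "roi", q = q, r = NA_integer_, j = seq_len(p), i = NA_integer_,
        name = paste0(spec$labels, ".l", q))
  if (spec$n_u > 0) {
    for (r in 0:spec$f)
      out[[length(out) + 1]] <- data.frame(
        kind = "input", q = NA_integer_, r = r, j = NA_integer_,
        i = seq_len(spec$n_u), name = paste0("u", seq_len(spec$n_u), ".l", r))
    if (spec$bilinear)
      for (q in seq_len(spec$g)) for (r in seq_len(spec$h))
        out[[length(out) + 1]] <- data.frame(
          kind = "prod", q = q, r = r, j = seq_len(p), i = 1L,
          name = paste0(spec$labels, ".l", q, ".x.u.l", r))
  }
  lay <- do.call(rbind, out)
  lay$col <- seq_len(nrow(lay))
  lay
}

# free masks in regression form: A (p x p) and B (p x mx)
free_masks <- function(spec) {
  p <- spec$p; a <- spec$order
  lay <- x_layout(spec)
  mx <- nrow(lay)
  freeB <- matrix(FALSE, p, mx)
  for (q in seq_len(a))
    freeB[, lay$col[lay$kind == "roi" & lay$q == q]] <- spec$free_Phi[[q]]
  if (spec$n_u > 0) {
    for (r in 0:spec$f)
      freeB[, lay$col[lay$kind == "input" & lay$r == r]] <- spec$free_gamma[[r + 1]]
    if (spec$bilinear)
      for (q in seq_len(spec$g)) for (r in seq_len(spec$h))
        freeB[, lay$col[lay$kind == "prod" & lay$q == q & lay$r == r]] <-
          spec$free_tau[[.tau_index(spec, q, r)]]
  }
  list(A = spec$free_A, B = freeB, layout = lay)
}

spec_k_free <- function(spec) {
  sum(spec$free_A) + sum(vapply(spec$free_Phi, sum, 0)) +
    sum(vapply(spec$free_gamma, sum, 0)) + sum(vapply(spec$free_tau, sum, 0))
}

# canonical one-line identifier for a parameter
param_id <- function(matrix, q, r, row, col) {
  switch(matrix,
         A = sprintf("A[%d,%d]", row, col),
         Phi = sprintf("Phi%d[%d,%d]", q, row, col),
         gamma = sprintf("gamma%d[%d,%d]", r, row, col),
         tau = sprintf("tau%d,%d[%d,%d]", q, r, row, col))
}

# set or clear a free flag; param given as a one-row data.frame or list with
# fields matrix, q, r, row, col
spec_set <- function(spec, par, value = TRUE) {
  m <- as.character(par$matrix)
  if (m == "A") {
    if (par$row == par$col) stop("the diagonal of A is structurally fixed to zero")
    spec$free_A[par$row, par$col] <- value
  } else if (m == "Phi") {
    if (par$q > spec$order) stop("lag ", par$q, " exceeds model order ", spec$order)
    spec$free_Phi[[par$q]][par$row, par$col] <- value
  } else if (m == "gamma") {
    spec$free_gamma[[par$r + 1]][par$row, par$col] <- value
  } else if (m == "tau") {
    spec$free_tau[[.tau_index(spec, par$q, par$r)]][par$row, par$col] <- value
  } else stop("unknown parameter matrix: ", m)
  spec
}

spec_get <- function(spec, par) {
  m <- as.character(par$matrix)
  switch(m,
         A = spec$free_A[par$row, par$col],
         Phi = spec$free_Phi[[par$q]][par$row, par$col],
         gamma = spec$free_gamma[[par$r + 1]][par$row, par$col],
         tau = spec$free_tau[[.tau_index(spec, par$q, par$r)]][par$row, par$col])
}

# enumerate all structurally possible regression parameters, in the
# deterministic tie-break order (lag, target row, source col)
param_table <- function(spec, include_input = TRUE) {
  p <- spec$p
  rows <- list()
  add <- function(matrix, q, r, lag) {
    grid <- expand.grid(row = seq_len(p),
                        col = seq_len(if (matrix == "gamma") spec$n_u else p))
    grid <- grid[order(grid$row, grid$col), ]
    if (matrix == "A") grid <- grid[grid$row != grid$col, ]
    if (nrow(grid) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      matrix = matrix, q = q, r = r, row = grid$row, col = grid$col, lag = lag)
  }
  add("A", NA_integer_, NA_integer_, 0L)
  for (q in seq_len(spec$order)) add("Phi", q, NA_integer_, q)
  if (include_input && spec$n_u > 0) {
    for (r in 0:spec$f) add("gamma", NA_integer_, r, r)
    if (spec$bilinear)
      for (q in seq_len(spec$g)) for (r in seq_len(spec$h))
        add("tau", q, r, max(q, r))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$lag, tab$row, tab$col,
                   match(tab$matrix, c("A", "Phi", "gamma", "tau"))), ]
  rownames(tab) <- NULL
  tab$free <- vapply(seq_len(nrow(tab)), function(i) spec_get(spec, tab[i, ]), NA)
  tab$id <- vapply(seq_len(nrow(tab)), function(i)
    param_id(tab$matrix[i], tab$q[i], tab$r[i], tab$row[i], tab$col[i]), "")
  tab
}

# map a param-table row to its (A) entry or B column in regression form
param_bcol <- function(spec, par, lay = x_layout(spec)) {
  m <- as.character(par$matrix)
  if (m == "A") return(NA_integer_)
  sel <- switch(m,
                Phi = lay$kind == "roi" & lay$q == par$q & lay$j == par$col,
                gamma = lay$kind == "input" & lay$r == par$r & lay$i == par$col,
                tau = lay$kind == "prod" & lay$q == par$q & lay$r == par$r &
                  lay$j == par$col)
  lay$col[sel]
}

spec_hash <- function(spec) {
  masks <- free_masks(spec)
  paste0(spec$order, ":", paste(as.integer(c(masks$A, masks$B)), collapse = ""))
}

# grow a spec to a higher order (or larger input bounds), keeping flags
spec_extend <- function(spec, order = spec$order) {
  if (order < spec$order) stop("cannot shrink a model spec")
  out <- model_spec(spec$p, order, spec$labels, spec$n_u,
                    spec$f, spec$g, spec$h, spec$bilinear)
  out$free_A <- spec$free_A
  for (q in seq_len(spec$order)) out$free_Phi[[q]] <- spec$free_Phi[[q]]
  out$free_gamma <- spec$free_gamma
  out$free_tau <- spec$free_tau
  out
}

# union of free flags of two specs sharing p (orders may differ)
spec_union <- function(s1, s2) {
  out <- spec_extend(if (s1$order >= s2$order) s1 else s2)
  other <- if (s1$order >= s2$order) s2 else s1
  out$free_A <- out$free_A | other$free_A
  for (q in seq_len(other$order))
    out$free_Phi[[q]] <- out$free_Phi[[q]] | other$free_Phi[[q]]
  if (length(other$free_gamma))
    for (r in seq_along(other$free_gamma))
      out$free_gamma[[r]] <- out$free_gamma[[r]] | other$free_gamma[[r]]
  if (length(other$free_tau))
    for (i in seq_along(other$free_tau))
      out$free_tau[[i]] <- out$free_tau[[i]] | other$free_tau[[i]]
  out
}

# does s2 contain every free flag of s1?
spec_contains <- function(s2, s1) {
  if (s1$order > s2$order) {
    extra <- vapply(seq(s2$order + 1, s1$order), function(q)
      sum(s1$free_Phi[[q]]), 0)
    if (any(extra > 0)) return(FALSE)
  }
  if (any(s1$free_A & !s2$free_A)) return(FALSE)
  for (q in seq_len(min(s1$order, s2$order)))
    if (any(s1$free_Phi[[q]] & !s2$free_Phi[[q]])) return(FALSE)
  for (r in seq_along(s1$free_gamma))
    if (any(s1$free_gamma[[r]] & !s2$free_gamma[[r]])) return(FALSE)
  for (i in seq_along(s1$free_tau))
    if (any(s1$free_tau[[i]] & !s2$free_tau[[i]])) return(FALSE)
  TRUE
}
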