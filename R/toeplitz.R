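#' Block-Toeplitz lagged covariance matrix
#'
#' Arranges the lag-0..order cross-covariance blocks of a centered
#' multivariate series into the banded symmetric (block-Toeplitz) matrix
#' on which uSEM-family models are estimated as covariance-structure
#' models.  The lag-l block is the full-overlap estimator
#' \eqn{C(l) = (T-l)^{-1} \sum_t y(t) y(t+l)'}, so block (j, k) depends
#' only on k - j and the Toeplitz structure holds exactly.
#'
#' When a task input is supplied, lagged input columns (r = 0..f) and --
#' if \code{bilinear} -- product regressors \eqn{y_j(t-q) u(t-r)} are
#' appended as additional exogenous variables; their covariances are
#' computed from the embedded data rows.
#'
#' @param ts a centered \code{\link{roi_ts}}.
#' @param order maximum lag a >= 0.
#' @param input optional convolved \code{\link{input_series}}.
#' @param f,g,h input lag bounds (used only when \code{input} given).
#' @param bilinear append bilinear product regressors (single input only).
#' @return an object of class \code{"lagged_cov"} with elements \code{S}
#'   (m x m), \code{order}, \code{n_eff}, \code{p}, \code{m},
#'   \code{n_extra}, \code{var_names}, \code{block_labels}.
#' @export
block_toeplitz_cov <- function(ts, order, input = NULL,
                               f = 1, g = 1, h = 1,
                               bilinear = !is.null(input)) {
  stopifnot(inherits(ts, "roi_ts"), order >= 0)
  if (!ts$centered) stop("series must be centered first (see center())")
  y <- ts$values
  p <- nrow(y); T <- ncol(y)
  if (T <= p * (order + 1))
    stop("series too short: T = ", T, " but need T > p*(order+1) = ",
         p * (order + 1))
  Cl <- lapply(0:order, function(l) {
    if (l == 0) tcrossprod(y) / T
    else tcrossprod(y[, seq_len(T - l), drop = FALSE],
                    y[, (1 + l):T, drop = FALSE]) / (T - l)
  })
  m_roi <- p * (order + 1)
  S <- matrix(0, m_roi, m_roi)
  for (i in 0:order) for (j in 0:order) {
    S[i * p + seq_len(p), j * p + seq_len(p)] <-
      if (j >= i) Cl[[j - i + 1]] else t(Cl[[i - j + 1]])
  }
  lags <- if (order > 0) order:0 else 0
  var_names <- as.vector(vapply(lags, function(q)
    if (q == 0) ts$labels else paste0(ts$labels, ".l", q),
    character(p)))
  block_labels <- rep(lags, each = p)
  n_extra <- 0L
  maxlag <- order
  if (!is.null(input)) {
    if (is.null(input$convolved))
      stop("input must be convolved with an HRF kernel first (see convolve_input())")
    n_u <- nrow(input$convolved)
    if (bilinear && n_u != 1)
      stop("bilinear product regressors require a single input vector")
    des <- .design_extras(y, input$convolved, order, f, g, h, bilinear,
                          labels = ts$labels)
    maxlag <- des$maxlag
    Xe <- des$extras                      # rows x n_extra, centered
    Xr <- des$roi_lags                    # rows x m_roi, roi lag cols + current
    n_extra <- ncol(Xe)
    nr <- nrow(Xe)
    S_xe <- crossprod(Xr, Xe) / nr        # m_roi x n_extra
    S_ee <- crossprod(Xe) / nr
    # insert extras between the lagged ROI block and the lag-0 block so the
    # exogenous x-block [roi lags, extras] stays contiguous
    i_lag <- seq_len(p * order); i_cur <- p * order + seq_len(p)
    Sfull <- rbind(
      cbind(S[i_lag, i_lag, drop = FALSE], S_xe[i_lag, , drop = FALSE],
            S[i_lag, i_cur, drop = FALSE]),
      cbind(t(S_xe[i_lag, , drop = FALSE]), S_ee, t(S_xe[i_cur, , drop = FALSE])),
      cbind(S[i_cur, i_lag, drop = FALSE], S_xe[i_cur, , drop = FALSE],
            S[i_cur, i_cur, drop = FALSE]))
    S <- Sfull
    var_names <- c(var_names[i_lag], des$extra_names, var_names[i_cur])
    block_labels <- c(block_labels[i_lag], rep(NA_integer_, n_extra),
                      block_labels[i_cur])
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- list(var_names, var_names)
  m <- nrow(S)
  if (qr(S)$rank < m)
    warning("lagged covariance matrix is singular (rank < ", m,
            "); estimation may be unstable")
  structure(list(S = S, order = order, n_eff = T - maxlag, p = p, m = m,
                 n_extra = n_extra, var_names = var_names,
                 block_labels = block_labels, T = T),
            class = "lagged_cov")
}

# embedded-data design for appended input / product variables; also used to
# compute one-step-ahead prediction errors
.design_extras <- function(y, uconv, order, f, g, h, bilinear, labels) {
  p <- nrow(y); T <- ncol(y); n_u <- nrow(uconv)
  maxlag <- max(order, if (bilinear) g else 0L,
                f, if (bilinear) h else 0L)
  rows <- (maxlag + 1):T
  roi_cols <- list(); roi_names <- character(0)
  lags <- if (order > 0) order:0 else 0
  for (q in lags) {
    roi_cols[[length(roi_cols) + 1]] <- t(y[, rows - q, drop = FALSE])
    roi_names <- c(roi_names,
                   if (q == 0) labels else paste0(labels, ".l", q))
  }
  Xr <- do.call(cbind, roi_cols)
  colnames(Xr) <- roi_names
  ex <- list(); ex_names <- character(0)
  for (r in 0:f) {
    M <- t(uconv[, rows - r, drop = FALSE])
    ex[[length(ex) + 1]] <- M
    ex_names <- c(ex_names, paste0("u", seq_len(n_u), ".l", r))
  }
  if (bilinear) {
    u1 <- uconv[1, ]
    for (q in seq_len(g)) for (r in seq_len(h)) {
      M <- t(y[, rows - q, drop = FALSE] *
               rep(u1[rows - r], each = p))
      ex[[length(ex) + 1]] <- M
      ex_names <- c(ex_names, paste0(labels, ".l", q, ".x.u.l", r))
    }
  }
  Xe <- do.call(cbind, ex)
  Xe <- sweep(Xe, 2, colMeans(Xe))
  colnames(Xe) <- ex_names
  list(roi_lags = Xr, extras = Xe, extra_names = ex_names,
       maxlag = maxlag, rows = rows)
}

#' @export
print.lagged_cov <- function(x, ...) {
  cat("block-Toeplitz lagged covariance: m =", x$m, "(p =", x$p,
      ", order =", x$order,
      if (x$n_extra > 0) paste0(", +", x$n_extra, " input/product vars") else "",
      "), n_eff =", x$n_eff, "\n")
  invisible(x)
}

#' @export
#' @method as.matrix lagged_cov
as.matrix.lagged_cov <- function(x, ...) x$S

#' Write a lagged covariance matrix to TSV for inspection
#'
#' @param lc a \code{\link{block_toeplitz_cov}} result.
#' @param path output file.
#' @export
write_lagged_cov <- function(lc, path) {
  m <- lc$S
  write.table(cbind(variable = rownames(m), as.data.frame(m)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
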