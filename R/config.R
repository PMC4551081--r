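#' Configuration for uSEM-family model search and validation
#'
#' Collects every tunable threshold of the model search, the 2-of-4
#' excellent-fit rule, the GIMME grouping criterion, and the a posteriori
#' order-validation policy in one place.  Defaults follow common practice
#' for this model family: excellent fit is declared when at least
#' \code{n_pass} of the four alternative indices pass (RMSEA <= 0.05,
#' SRMR <= 0.05, CFI >= 0.95, NNFI >= 0.95), modification indices are
#' judged against chi-square(1) at \code{mi_alpha}, and a group-level
#' connection requires significance in at least 75\% of subjects.
#'
#' @param order model order (maximum lag) for search; default 1.
#' @param mi_alpha significance level for modification-index freeing and
#'   Wald trimming; default 0.05 (uncorrected).
#' @param rmsea_max,srmr_max,cfi_min,nnfi_min excellent-fit thresholds.
#' @param n_pass how many of the four index tests must pass (1..4).
#' @param criterion GIMME grouping criterion: fraction of subjects for
#'   which a candidate must be significant to enter the group model.
#' @param max_free cap on the number of freed parameters per search
#'   (\code{Inf} = limited only by remaining degrees of freedom).
#' @param f maximum lag of direct input effects \code{gamma_r}, r = 0..f.
#' @param g,h maximum ROI lag and input lag of bilinear terms
#'   \code{tau_qr}, q = 1..g, r = 1..h.
#' @param L order of the white-noise VAR null fitted to the prediction
#'   errors; default 3.
#' @param max_order highest model order the validation loop may escalate
#'   to before giving up; default 3.
#' @param few_threshold "a few" significant residual modification indices:
#'   at most this many triggers a confirmatory revision (option a),
#'   more triggers a data-driven re-search at the next order (option b).
#' @param allow_subdivision logical; permit the manual series-subdivision
#'   option (option c).  Never auto-selected.
#' @param standardize logical; also scale each series to unit variance
#'   when centering.  Default \code{FALSE}: the model constrains only the
#'   mean.
#'
#' @return a list of class \code{"usem_config"}.
#' @export
#' @examples
#' cfg <- usem_config(order = 2)
#' cfg$criterion
usem_config <- function(order = 1,
                        mi_alpha = 0.05,
                        rmsea_max = 0.05, srmr_max = 0.05,
                        cfi_min = 0.95, nnfi_min = 0.95,
                        n_pass = 2,
                        criterion = 0.75,
                        max_free = Inf,
                        f = 1, g = 1, h = 1,
                        L = 3,
                        max_order = 3,
                        few_threshold = 3,
                        allow_subdivision = FALSE,
                        standardize = FALSE) {
  stopifnot(order >= 0, mi_alpha > 0, mi_alpha < 1,
            criterion > 0, criterion <= 1,
            n_pass %in% 1:4, L >= 0, max_order >= 1, few_threshold >= 0)
  structure(list(order = order, mi_alpha = mi_alpha,
                 rmsea_max = rmsea_max, srmr_max = srmr_max,
                 cfi_min = cfi_min, nnfi_min = nnfi_min,
                 n_pass = n_pass, criterion = criterion,
                 max_free = max_free,
                 f = f, g = g, h = h,
                 L = L, max_order = max_order,
                 few_threshold = few_threshold,
                 allow_subdivision = allow_subdivision,
                 standardize = standardize),
            class = "usem_config")
}

#' Smallest subject count satisfying the grouping criterion
#'
#' The number of subjects for which a candidate connection must be
#' significant in order to be freed at the group level: the smallest
#' integer not below \code{criterion * n}.  With 32 subjects and the
#' usual 75\% criterion this is 24.
#'
#' @param n number of subjects (>= 1).
#' @param criterion grouping fraction in (0, 1].
#' @return an integer count.
#' @export
#' @examples
#' group_threshold_count(32, 0.75)  # 24
group_threshold_count <- function(n, criterion = 0.75) {
  stopifnot(n >= 1, criterion > 0, criterion <= 1)
  as.integer(ceiling(criterion * n - 1e-12))
}
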