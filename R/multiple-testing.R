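#' Bonferroni per-test threshold
#'
#' The familywise error rate over `m` tests is bounded by `alpha` when
#' each test uses the level `alpha / m`.
#'
#' @param alpha genome-wide significance level in (0, 1).
#' @param m number of hypotheses (>= 1).
#' @return list: `threshold` = alpha/m and `neg_log10` = -log10(alpha/m).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a count >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  thr <- alpha / m
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Benjamini-Hochberg step-up selection
#'
#' Implements the classic step-up rule on raw p-values: with sorted
#' `p_(1) <= ... <= p_(m)`, find the largest `k` with
#' `p_(k) <= k q / m`; all tests with `p <= p_(k)` are selected (so the
#' realized per-test threshold `alpha'` satisfies
#' `alpha' m / R(alpha') <= q`).  Ties are selected together.  BH-adjusted
#' p-values (`stats::p.adjust`) are returned alongside for convenience.
#'
#' @param p numeric p-values in [0, 1].
#' @param q target false discovery rate in (0, 1).
#' @param ids optional identifiers (default positional).
#' @return list of class `mt_result`: `method`, `q`, `m`, `threshold`
#'   (the realized per-test level `p_(k)`, 0 if nothing selected),
#'   `selected` (ids), `n_selected`, `adjusted_p` (named).
#' @export
bh_select <- function(p, q = 0.05, ids = NULL) {
  if (any(is.na(p))) {
    keep <- !is.na(p)
    if (is.null(ids)) ids <- as.character(seq_along(p))
    ids <- ids[keep]
    p <- p[keep]
  } else if (is.null(ids)) ids <- as.character(seq_along(p))
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  if (m == 0)
    return(structure(list(method = "BH", q = q, m = 0L, threshold = 0,
                          selected = character(), n_selected = 0L,
                          adjusted_p = numeric()), class = "mt_result"))
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_len(m) * q / m
  thr <- if (any(ok)) unname(ps[max(which(ok))]) else 0
  sel <- ids[p <= thr & any(ok)]
  structure(list(method = "BH", q = q, m = m, threshold = thr,
                 selected = sel, n_selected = length(sel),
                 adjusted_p = stats::setNames(stats::p.adjust(p, "BH"), ids)),
            class = "mt_result")
}

#' Bonferroni selection at a genome-wide level
#'
#' @inheritParams bh_select
#' @param alpha genome-wide level.
#' @return list of class `mt_result` with the per-test threshold
#'   `alpha/m` and the selected identifiers.
#' @export
bonferroni_select <- function(p, alpha = 0.05, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(p))
  keep <- !is.na(p)
  ids <- ids[keep]
  p <- p[keep]
  m <- length(p)
  thr <- if (m > 0) bonferroni_threshold(alpha, m)$threshold else 0
  sel <- ids[p <= thr]
  structure(list(method = "bonferroni", q = alpha, m = m, threshold = thr,
                 selected = sel, n_selected = length(sel),
                 adjusted_p = stats::setNames(pmin(p * m, 1), ids)),
            class = "mt_result")
}
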