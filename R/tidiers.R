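#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-TE fit
#'
#' @param x a `"te_fit"` from [differential_te()].
#' @param ... unused.
#' @return broom-style tibble: `gene_id`, `estimate` (delta log2 TE),
#'   `statistic`, `df`, `p.value`, `q.value`.
#' @method tidy te_fit
#' @export
tidy.te_fit <- function(x, ...) {
  tibble(gene_id = x$gene_id,
         estimate = x$delta_log2_te,
         statistic = x$statistic,
         df = x$df,
         p.value = x$p_value,
         q.value = x$q_value)
}

#' One-row summary of a differential-TE fit
#'
#' @inheritParams tidy.te_fit
#' @param q_threshold significance cutoff on BH-adjusted p-values.
#' @return tibble: `n_genes`, `n_altered`, `q_threshold`, `ref`, `alt`.
#' @method glance te_fit
#' @export
glance.te_fit <- function(x, q_threshold = 0.05, ...) {
  cond <- attr(x, "conditions")
  tibble(n_genes = nrow(x),
         n_altered = sum(x$q_value <= q_threshold, na.rm = TRUE),
         q_threshold = q_threshold,
         ref = unname(cond["ref"]), alt = unname(cond["alt"]))
}

#' Tidy a pause-expression correlation
#'
#' @param x a `"pause_cor"` from [correlate_pause_with_expression()].
#' @param ... unused.
#' @return one-row tibble: `estimate` (Spearman rho), `p.value`, `n`,
#'   `method`.
#' @method tidy pause_cor
#' @export
tidy.pause_cor <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname tidy.pause_cor
#' @method glance pause_cor
#' @export
glance.pause_cor <- function(x, ...) tidy.pause_cor(x)
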