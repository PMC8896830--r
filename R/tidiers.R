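#' Tidiers for epicoloc result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-draw or per-gene detail, `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name epicoloc-tidiers
NULL

#' @rdname epicoloc-tidiers
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(iteration = seq_along(x$null), null_stat = x$null)
}

#' @rdname epicoloc-tidiers
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic_name, observed = x$observed,
    shared_bp = x$shared_bp, null_mean = mean(x$null), null_sd = sd(x$null),
    p_value = x$p_value, p_raw = x$p_raw, n_shuffles = x$n_shuffles,
    alternative = x$alternative, seed = x$seed
  )
}

#' @rdname epicoloc-tidiers
#' @method tidy readthrough_comparison
#' @export
tidy.readthrough_comparison <- function(x, ...) x$table

#' @rdname epicoloc-tidiers
#' @method glance readthrough_comparison
#' @export
glance.readthrough_comparison <- function(x, ...) {
  tibble(
    mw_u = x$mw_u, v_statistic = x$v_statistic, p_value = x$p_value,
    p_ranksum = x$p_ranksum, n = x$n,
    n_enriched = length(x$enriched), margin = x$margin,
    min_index = x$min_index
  )
}

#' @rdname epicoloc-tidiers
#' @method glance gene_mark_table
#' @export
glance.gene_mark_table <- function(x, ...) {
  n <- nrow(x)
  n_both <- sum(x$has_both)
  n_h_only <- sum(x$has_5hmc & !x$has_both)
  n_r_only <- sum(x$has_rloop & !x$has_both & !x$has_5hmc)
  n_neither <- sum(!x$has_5hmc & !x$has_rloop)
  pct <- function(k) if (n > 0) 100 * k / n else NA_real_
  tibble(
    n_active = n, n_5hmc = sum(x$has_5hmc), n_rloop = sum(x$has_rloop),
    n_both = n_both, n_5hmc_only = n_h_only, n_rloop_only = n_r_only,
    n_neither = n_neither,
    pct_5hmc = pct(sum(x$has_5hmc)), pct_rloop = pct(sum(x$has_rloop)),
    pct_both = pct(n_both), pct_neither = pct(n_neither)
  )
}
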