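#' Per-gene equivalence screening
#'
#' Runs the model-averaged equivalence test gene by gene on a long-format
#' expression table, using a range-relative margin: for gene `g` the
#' absolute margin is `epsilon_rel` times the range of the fitted
#' response values of both groups, and the scaled bound
#' `u_scaled = u / range` can be compared with `epsilon_rel` directly
#' (the two decision rules coincide).  No multiple-testing adjustment is
#' applied by default; genes are tested marginally.
#'
#' @param data Long tibble with gene, group, covariate and response
#'   columns (see [read_curve_data()]).
#' @param families Candidate families, default all six.
#' @param weights Weighting scheme, see [ma_fit()].
#' @param epsilon_rel Margin as a fraction of each gene's fitted response
#'   range (default 0.2); alternatively give an absolute `epsilon`.
#' @param epsilon Optional absolute margin applied to every gene.
#' @param alpha Significance level.
#' @param n_boot Bootstrap replicates per gene.
#' @param ci `"hybrid"` (default) or `"percentile"`.
#' @param p_adjust Optional multiplicity adjustment of the per-gene
#'   decisions is deliberately not performed; the flag is accepted for
#'   interface compatibility and only `"none"` is implemented.
#' @param gene,group,x,y Column names.
#' @param seed Integer master seed; each gene gets a derived substream,
#'   so the result is independent of iteration order and `threads`.
#' @param threads Worker processes.
#' @return Tibble with one row per gene (sorted by gene id): `d_hat`,
#'   `se_hat`, `u`, `epsilon_used`, `u_scaled`, `reject`, bookkeeping
#'   columns, and a nested `weights` tibble (group x family).
#' @export
equiv_screen <- function(data, families = curve_families(),
                         weights = "bic", epsilon_rel = 0.2,
                         epsilon = NULL, alpha = 0.05, n_boot = 500L,
                         ci = "hybrid", p_adjust = "none",
                         gene = "gene", group = "group", x = "x", y = "y",
                         seed = NULL, threads = 1L) {
  if (!p_adjust %in% "none") {
    stop("only p_adjust = 'none' is supported: genes are screened marginally",
         call. = FALSE)
  }
  if (is.null(data[[gene]])) stop("column '", gene, "' is required",
                                  call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  ids <- sort(unique(as.character(data[[gene]])))
  run1 <- function(i) {
    gid <- ids[i]
    di <- data[data[[gene]] == gid, , drop = FALSE]
    tst <- equiv_test(di, families = families, weights = weights,
                      epsilon = epsilon,
                      epsilon_rel = if (is.null(epsilon)) epsilon_rel else NULL,
                      alpha = alpha, n_boot = n_boot, ci = ci,
                      group = group, x = x, y = y,
                      seed = derive_seed(seed, i))
    out <- glance(tst)
    out$gene <- gid
    out$weights <- list(tidy(tst)[, c("group", "family", "weight")])
    out
  }
  res <- if (threads > 1L) {
    parallel::mclapply(seq_along(ids), run1, mc.cores = threads)
  } else {
    lapply(seq_along(ids), run1)
  }
  dplyr::relocate(dplyr::bind_rows(res), "gene")
}
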