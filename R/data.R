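#' Simulate two-group response data around known curves
#'
#' Generates Gaussian responses around two true mean curves at a fixed
#' design.  The default design is the five-level layout `x = 0..4` with
#' equal per-level replicate counts `n/5`, the standard setting for
#' dose-response simulation benchmarks; arbitrary designs can be given as
#' data frames of levels and counts.
#'
#' @param truth1,truth2 True curves as [curve_params()] objects.
#' @param sigma2 Length-2 numeric: error variances of groups 1 and 2.
#' @param n Length-2 integer: total observations per group (split equally
#'   over `x_levels`; must be divisible by the number of levels).  Ignored
#'   when `design1`/`design2` are supplied.
#' @param x_levels Design points (default `0:4`).
#' @param design1,design2 Optional data frames with columns `x` and `n`
#'   (per-level counts), overriding `n`/`x_levels` per group.
#' @param group_labels Labels for the two groups.
#' @param seed Integer seed; same seed, same table.
#' @return Long tibble with columns `group`, `x`, `y`.
#' @examples
#' simulate_curve_data(curve_params("emax", c(1, 2, 1)),
#'                     curve_params("exponential", c(0.25, 2.2, 8)),
#'                     sigma2 = c(0.25, 0.25), n = c(10, 10), seed = 1)
#' @export
simulate_curve_data <- function(truth1, truth2, sigma2, n = c(50L, 50L),
                                x_levels = 0:4,
                                design1 = NULL, design2 = NULL,
                                group_labels = c("1", "2"), seed = NULL) {
  stopifnot(length(sigma2) == 2, all(sigma2 >= 0))
  truths <- list(truth1, truth2)
  designs <- list(design1, design2)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", 2L)
  for (gi in 1:2) {
    des <- designs[[gi]]
    if (is.null(des)) {
      if (n[gi] %% length(x_levels) != 0) {
        stop("n[", gi, "] must be divisible by the number of design levels",
             call. = FALSE)
      }
      des <- data.frame(x = x_levels, n = n[gi] / length(x_levels))
    }
    xv <- rep(des$x, des$n)
    mu <- predict(truths[[gi]], xv)
    out[[gi]] <- tibble::tibble(
      group = group_labels[gi], x = xv,
      y = mu + stats::rnorm(length(xv), 0, sqrt(sigma2[gi]))
    )
  }
  dplyr::bind_rows(out)
}

#' Read / write long-format curve data
#'
#' Delimited text (comma default, tab accepted) with a header.  The
#' reader validates that the mapped columns exist, that covariate and
#' response are numeric and finite, and that at least two groups are
#' present; offending rows are reported.
#'
#' @param path File path.
#' @param group,x,y Column names in the file.
#' @param gene Optional per-response identifier column for multi-gene
#'   screening data (`NULL` if absent).
#' @param delim Field delimiter; `","` or `"\t"`.
#' @return A tibble with standardized column names `group`, `x`, `y`
#'   (and `gene` when present), rows ordered by gene then group.
#' @export
read_curve_data <- function(path, group = "group", x = "x", y = "y",
                            gene = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c(group, x, y, gene)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    group = as.character(raw[[group]]),
    x = suppressWarnings(as.numeric(raw[[x]])),
    y = suppressWarnings(as.numeric(raw[[y]]))
  )
  if (!is.null(gene)) out$gene <- as.character(raw[[gene]])
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite x/y in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  if (length(unique(out$group)) < 2) {
    stop("two groups required, found ", length(unique(out$group)),
         call. = FALSE)
  }
  if (!is.null(gene)) out <- dplyr::arrange(out, .data$gene, .data$group)
  out
}

#' @rdname read_curve_data
#' @param data Tibble to write.
#' @export
write_curve_data <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Default time-course designs for the gene-screening generator
#'
#' Two unbalanced observation schedules typical of a chronic-feeding
#' toxicology study: a "western diet" arm observed at nine time points
#' and a "standard diet" arm observed at six, with unequal per-time
#' replicate counts.  Time zero denotes the first sampled week of the
#' study.
#'
#' @return A named list of two data frames (`wd`, `sd`) with columns
#'   `x` (time) and `n` (replicates).
#' @export
gene_screen_designs <- function() {
  list(
    wd = data.frame(x = c(0, 3, 9, 15, 21, 27, 33, 39, 45),
                    n = c(5, 5, 5, 5, 5, 5, 5, 4, 8)),
    sd = data.frame(x = c(0, 3, 27, 33, 39, 45),
                    n = c(7, 5, 5, 7, 3, 5))
  )
}

#' Simulate multi-gene time-course expression data
#'
#' Emulates log2-scale normalized expression for `n_genes` genes observed
#' in two groups on (possibly unbalanced) time designs.  Each gene gets a
#' true curve drawn from the candidate families with gene-varying
#' parameters; a configurable fraction of genes is planted as equivalent
#' (identical curves in both groups), the remainder differ by a vertical
#' shift of known size, so a screening run can be checked against the
#' planted truth.  Values are Gaussian on the log2 scale (counts are
#' not simulated).
#'
#' @param n_genes Number of genes.
#' @param fraction_equivalent Fraction of genes with identical true
#'   curves in both groups.
#' @param families Families the true curves are drawn from.
#' @param design1,design2 Per-group designs (data frames with `x`, `n`);
#'   defaults are the two [gene_screen_designs()].
#' @param shift_range Range of the planted absolute curve shift for
#'   non-equivalent genes.
#' @param sigma_range Range of per-gene residual standard deviations
#'   (log2 scale).
#' @param seed Integer seed.
#' @return A list with `data` (long tibble: `gene`, `group`, `x`, `y`)
#'   and `truth` (tibble: `gene`, `family`, `d_true`, `equivalent`).
#' @export
simulate_gene_data <- function(n_genes = 50L, fraction_equivalent = 0.5,
                               families = c("linear", "emax", "exponential",
                                            "quadratic"),
                               design1 = gene_screen_designs()$wd,
                               design2 = gene_screen_designs()$sd,
                               shift_range = c(1.5, 4),
                               sigma_range = c(0.2, 0.6),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  families <- match_family(families)
  tmax <- max(design1$x, design2$x)
  rows <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  n_equiv <- round(fraction_equivalent * n_genes)
  for (g in seq_len(n_genes)) {
    fam <- sample(families, 1)
    b0 <- stats::runif(1, 6, 12)
    b1 <- sample(c(-1, 1), 1) * stats::runif(1, 1, 4)
    theta <- switch(fam,
      linear      = c(b0, b1 / tmax),
      quadratic   = c(b0, b1 / tmax, -0.5 * b1 / tmax^2),
      emax        = c(b0, b1, stats::runif(1, 0.1, 0.6) * tmax),
      exponential = c(b0, b1 * 0.5, stats::runif(1, 0.4, 1.5) * tmax),
      sigemax     = c(b0, b1, stats::runif(1, 0.2, 0.6) * tmax,
                      stats::runif(1, 1, 4)),
      beta        = c(b0, b1, stats::runif(1, 0.5, 2), stats::runif(1, 0.5, 2))
    )
    scal <- if (fam == "beta") 1.2 * tmax else NULL
    p1 <- curve_params(fam, theta, scal)
    equivalent <- g <= n_equiv
    shift <- if (equivalent) 0 else
      sample(c(-1, 1), 1) * stats::runif(1, shift_range[1], shift_range[2])
    theta2 <- theta
    theta2[1] <- theta2[1] + shift
    p2 <- curve_params(fam, theta2, scal)
    sig <- stats::runif(1, sigma_range[1], sigma_range[2])
    d <- simulate_curve_data(p1, p2, sigma2 = c(sig^2, sig^2),
                             design1 = design1, design2 = design2,
                             group_labels = c("wd", "sd"))
    d$gene <- sprintf("gene%04d", g)
    rows[[g]] <- d
    truth[[g]] <- tibble::tibble(gene = d$gene[1], family = fam,
                                 d_true = abs(shift),
                                 equivalent = equivalent)
  }
  list(
    data = dplyr::relocate(dplyr::bind_rows(rows), "gene"),
    truth = dplyr::bind_rows(truth)
  )
}
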