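# PolyA-status classification. mRNAs lacking polyA tails are enriched in
# rRNA-depleted (total) RNA-seq relative to polyA-selected RNA-seq; the
# regression line of spliceosomal-RNA points in (log2 polyA TPM+1,
# log2 total TPM+1) space defines the boundary, and the association between
# polyA status and sRNA production is tested by Wilcoxon rank-sum.

#' Fit the spliceosomal regression baseline
#'
#' Ordinary least squares of `y` (log2 total-RNA-seq TPM+1) on `x`
#' (log2 polyA-selected TPM+1) over the spliceosomal points.
#'
#' @param points Data frame with columns `x`, `y` and optionally `role`
#'   (rows with `role != "spliceosomal"` are dropped when present).
#' @return A `baseline_fit`: list with `slope`, `intercept`, `n`.
#' @export
fit_spliceosomal_baseline <- function(points) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if ("role" %in% names(points))
    points <- points[points$role == "spliceosomal", , drop = FALSE]
  if (nrow(points) < 2L) stop("need at least 2 spliceosomal points")
  if (length(unique(points$x)) < 2L)
    stop("all x values identical; baseline slope is undefined")
  fit <- stats::lm(y ~ x, data = points)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = nrow(points)),
            class = "baseline_fit")
}

#' Classify coding genes by polyA status against the baseline
#'
#' A gene strictly above the baseline (residual `y - (intercept + slope*x)`
#' greater than `margin`) is polyA(-); the rest are polyA(+). To match
#' expression levels between the groups, the minimum `y` among polyA(-)
#' genes defines a cutoff, and polyA(+) genes at or below it are marked
#' `"excluded"` (not used in downstream comparisons). If no gene falls
#' above the baseline, the cutoff is undefined and exclusion is skipped
#' with a warning.
#'
#' @param points Data frame of coding genes with columns `gene_id`, `x`,
#'   `y` (rows with `role != "coding"` are dropped when a `role` column is
#'   present).
#' @param baseline A `baseline_fit` from [fit_spliceosomal_baseline()].
#' @param margin Extra residual margin above the line required for a
#'   polyA(-) call; default 0.
#' @return Data frame with columns `gene_id`, `x`, `y`, `residual` and
#'   `class` (`"polyA_minus"`, `"polyA_plus"` or `"excluded"`), with the
#'   expression cutoff in `attr(, "cutoff")`.
#' @export
classify_polya <- function(points, baseline, margin = 0) {
  stopifnot(inherits(baseline, "baseline_fit"), is.data.frame(points),
            all(c("gene_id", "x", "y") %in% names(points)))
  if ("role" %in% names(points))
    points <- points[points$role == "coding", , drop = FALSE]
  res <- points$y - (baseline$intercept + baseline$slope * points$x)
  cls <- ifelse(res > margin, "polyA_minus", "polyA_plus")
  cutoff <- NA_real_
  if (any(cls == "polyA_minus")) {
    cutoff <- min(points$y[cls == "polyA_minus"])
    cls[cls == "polyA_plus" & points$y <= cutoff] <- "excluded"
  } else {
    warning("no genes above the baseline; expression cutoff undefined, ",
            "no polyA(+) genes excluded")
  }
  out <- data.frame(gene_id = points$gene_id, x = points$x, y = points$y,
                    residual = res, class = cls, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Compare sRNA production between polyA classes
#'
#' Two-sided Wilcoxon rank-sum test of per-gene sRNA levels
#' (log2(RPM + 1)) between polyA(-) genes and the retained (non-excluded)
#' polyA(+) genes. The exact null distribution is used for moderate group
#' sizes without ties; the tie-corrected normal approximation otherwise.
#'
#' @param calls Classification data frame from [classify_polya()].
#' @param srna_levels Named numeric vector of log2(RPM+1) sRNA levels,
#'   names matching `gene_id`. Genes without a level are dropped.
#' @return A list with `statistic` (rank-sum W), `p_value`, `direction`
#'   (`"polyA_minus_higher"`, `"polyA_plus_higher"` or `"none"`),
#'   `n_minus` and `n_plus`.
#' @export
compare_srna_production <- function(calls, srna_levels) {
  stopifnot(is.data.frame(calls), all(c("gene_id", "class") %in% names(calls)))
  minus <- srna_levels[calls$gene_id[calls$class == "polyA_minus"]]
  plus <- srna_levels[calls$gene_id[calls$class == "polyA_plus"]]
  minus <- minus[!is.na(minus)]
  plus <- plus[!is.na(plus)]
  if (length(minus) == 0L || length(plus) == 0L)
    stop("both polyA classes must be non-empty after exclusion")
  wt <- suppressWarnings(stats::wilcox.test(minus, plus,
                                            alternative = "two.sided"))
  dm <- stats::median(minus)
  dp <- stats::median(plus)
  direction <- if (dm > dp) "polyA_minus_higher"
               else if (dp > dm) "polyA_plus_higher" else "none"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = direction, n_minus = length(minus),
       n_plus = length(plus))
}
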