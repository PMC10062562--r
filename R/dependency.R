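# Knockdown dependency analysis: loci x conditions RPM matrix, expression
# filtering, the >40%-reduction dependency rule, and factor-combination
# tabulation (UpSet-style counts).

#' Build a loci x conditions RPM matrix
#'
#' Rows are loci of the scoped category (union over all libraries); entries
#' are RPM of reads within the length window, each library normalised to its
#' own total of mapped copies. A locus absent from a library gets 0.
#'
#' @param results Named list of `srna_classification`, one per condition;
#'   names are the condition labels.
#' @param control Control condition label; must be among the names.
#' @param category Optional category to scope rows to (e.g. `"repeat"`).
#' @param ref_ids Optional explicit locus set.
#' @param length_window Optional inclusive read-length window, e.g.
#'   `c(25, 30)` for the piRNA-sized fraction.
#' @return An object of class `locus_rpm_matrix`: a list with `rpm` (numeric
#'   matrix, control column first), `control`, `category`, `length_window`.
#' @export
build_matrix <- function(results, control, category = NULL, ref_ids = NULL,
                         length_window = NULL) {
  if (is.null(names(results)) || anyDuplicated(names(results)))
    stop("'results' must be uniquely named by condition")
  if (!control %in% names(results))
    stop("control condition '", control, "' missing from results")
  counts <- lapply(results, locus_counts, category = category,
                   ref_ids = ref_ids, length_window = length_window)
  loci <- sort(unique(unlist(lapply(counts, names))))
  conds <- c(control, setdiff(names(results), control))
  m <- matrix(0, length(loci), length(conds), dimnames = list(loci, conds))
  for (cond in conds) {
    v <- counts[[cond]]
    m[names(v), cond] <- rpm(v, results[[cond]]$total_mapped)
  }
  structure(list(rpm = m, control = control, category = category,
                 length_window = length_window),
            class = "locus_rpm_matrix")
}

#' Filter loci by mean expression
#'
#' Retains loci whose mean RPM across all conditions is strictly greater
#' than the threshold (the convention "> t RPM on average across the
#' libraries"; a row averaging exactly the threshold is dropped).
#'
#' @param matrix A `locus_rpm_matrix`.
#' @param min_mean_rpm Non-negative threshold (35 for coding loci, 800 for
#'   repeat families in the reference analysis).
#' @return The filtered `locus_rpm_matrix`.
#' @export
filter_expressed <- function(matrix, min_mean_rpm) {
  stopifnot(inherits(matrix, "locus_rpm_matrix"), min_mean_rpm >= 0)
  keep <- rowMeans(matrix$rpm) > min_mean_rpm
  matrix$rpm <- matrix$rpm[keep, , drop = FALSE]
  matrix
}

#' Call factor dependencies by the >40% reduction rule
#'
#' For each locus and knockdown condition the fold change is
#' `RPM_kd / RPM_control`; the locus is dependent on a factor when the fold
#' change in any of that factor's knockdown libraries is strictly below
#' `1 - reduction` (default: reduced by more than 40%, i.e. fold < 0.6).
#' By default the two AGO3 dsRNA conditions are merged into the single
#' factor `"AGO3"` (dependent if either library shows the reduction). Loci
#' with zero control RPM have undefined fold changes and are flagged and
#' excluded from calls.
#'
#' @param matrix A `locus_rpm_matrix` (typically after [filter_expressed()]).
#' @param reduction Fractional reduction threshold in (0, 1); default 0.4.
#' @param factor_map Named character vector mapping knockdown condition ->
#'   factor label; defaults to stripping the `"ds"` prefix and merging
#'   AGO3-1/AGO3-2. Set `merge_ago3 = FALSE` for the unmerged map.
#' @param merge_ago3 Merge the two AGO3 conditions into one factor.
#' @return An object of class `dependency_calls`: a list with `calls` (data
#'   frame: `locus_id`, `control_rpm`, `dependency_set` (comma-joined sorted
#'   factors, `""` if none), `undefined`), `folds` (loci x knockdown-condition
#'   fold-change matrix), `factor_map` and `reduction`.
#' @export
call_dependencies <- function(matrix, reduction = 0.4, factor_map = NULL,
                              merge_ago3 = TRUE) {
  stopifnot(inherits(matrix, "locus_rpm_matrix"))
  if (reduction <= 0 || reduction >= 1) stop("reduction must be in (0, 1)")
  m <- matrix$rpm
  kd <- setdiff(colnames(m), matrix$control)
  if (is.null(factor_map)) {
    factor_map <- setNames(if (merge_ago3) condition_factor(kd)
                           else sub("^ds", "", kd), kd)
  }
  if (!all(names(factor_map) %in% kd))
    stop("factor_map names unknown condition: ",
         setdiff(names(factor_map), kd)[1L])
  ctrl <- m[, matrix$control]
  folds <- m[, names(factor_map), drop = FALSE] / ctrl
  undefined <- ctrl == 0
  threshold <- 1 - reduction
  sets <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (undefined[i]) { sets[i] <- NA_character_; next }
    dep <- unique(factor_map[folds[i, ] < threshold])
    sets[i] <- paste(sort(dep), collapse = ",")
  }
  calls <- data.frame(locus_id = rownames(m), control_rpm = unname(ctrl),
                      dependency_set = sets, undefined = unname(undefined),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, folds = folds, factor_map = factor_map,
                 reduction = reduction),
            class = "dependency_calls")
}

#' Tabulate factor-combination counts
#'
#' Exact-set counts for an UpSet-style summary: each locus with defined fold
#' changes is counted once under its full dependent factor set, plus
#' marginal per-factor counts and the number of loci with no dependency.
#'
#' @param deps A `dependency_calls` object.
#' @return A list with `combinations` (data frame `set`, `n`, decreasing by
#'   `n`; `set` is the comma-joined sorted factor combination), `marginals`
#'   (data frame `factor`, `n`), `n_independent` (loci with empty dependent
#'   sets) and `n_called` (loci with defined folds).
#' @export
tabulate_combinations <- function(deps) {
  stopifnot(inherits(deps, "dependency_calls"))
  sets <- deps$calls$dependency_set[!deps$calls$undefined]
  nonempty <- sets[sets != ""]
  comb <- if (length(nonempty) > 0L) {
    t <- table(nonempty)
    data.frame(set = names(t), n = as.integer(t), stringsAsFactors = FALSE)
  } else data.frame(set = character(), n = integer(), stringsAsFactors = FALSE)
  comb <- comb[order(-comb$n, comb$set), ]
  rownames(comb) <- NULL
  factors <- unlist(strsplit(nonempty, ","))
  marg <- if (length(factors) > 0L) {
    t <- table(factors)
    data.frame(factor = names(t), n = as.integer(t), stringsAsFactors = FALSE)
  } else data.frame(factor = character(), n = integer(),
                    stringsAsFactors = FALSE)
  list(combinations = comb, marginals = marg,
       n_independent = sum(sets == ""), n_called = length(sets))
}

#' Log2 fold-change table against the control
#'
#' Pseudo-counted log2 ratios for scatter/heat displays:
#' `log2((kd + pseudo) / (control + pseudo))` for every locus and knockdown
#' condition. Unlike [call_dependencies()] (raw ratios with the zero-control
#' exclusion), the symmetric pseudo-count keeps zero-count loci defined.
#'
#' @param matrix A `locus_rpm_matrix`.
#' @param pseudo Positive pseudo-RPM added to numerator and denominator;
#'   default 0.5.
#' @return Loci x knockdown-condition matrix of log2 fold changes.
#' @export
fold_change_table <- function(matrix, pseudo = 0.5) {
  stopifnot(inherits(matrix, "locus_rpm_matrix"))
  if (pseudo <= 0) stop("pseudo must be > 0")
  m <- matrix$rpm
  kd <- setdiff(colnames(m), matrix$control)
  log2((m[, kd, drop = FALSE] + pseudo) / (m[, matrix$control] + pseudo))
}
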