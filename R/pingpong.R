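# Ping-pong amplification signature: 5'-5' overlap counts between sense and
# antisense reads over distances 1-25 nt, standardised Z-scores, and the
# significance call at the canonical 10-nt overlap produced by PIWI slicing
# opposite the guide's 10th/11th nucleotides.

#' Count-weighted 5'-5' overlap scores
#'
#' For each locus, every sense 5'-end position `p` (summed count `c+`) is
#' paired with every antisense 5'-end position `q` (summed count `c-`); the
#' pair contributes `c+ * c-` to the score at overlap distance
#' `d = q - p + 1` (so a complete 10-nt 5' overlap scores at d = 10).
#' Scores are summed over loci. Positions are the `pos5` values of
#' classification profiles, i.e. 5' ends in reference coordinates on both
#' strands.
#'
#' @param profiles Profile data frame as in `srna_classification$profiles`
#'   (columns `ref_id`, `strand`, `pos5`, `length`, `count`), or an
#'   `srna_classification` whose profiles are used.
#' @param category Optional category restriction.
#' @param ref_ids Optional locus restriction.
#' @param length_window Inclusive read-length window; default `c(25, 30)`,
#'   the piRNA-sized fraction.
#' @param dmax Maximum overlap distance scanned (default 25).
#' @return An object of class `overlap_signature`: a list with `scores`
#'   (named numeric, d = 1..dmax), `zscores` (`NULL` until
#'   [overlap_zscores()] is applied), `n_pairs`, `length_window` and
#'   `degenerate`.
#' @export
overlap_counts <- function(profiles, category = NULL, ref_ids = NULL,
                           length_window = c(25L, 30L), dmax = 25L) {
  if (inherits(profiles, "srna_classification")) profiles <- profiles$profiles
  p <- profiles
  if (!is.null(category)) p <- p[p$category %in% category, , drop = FALSE]
  if (!is.null(ref_ids)) p <- p[p$ref_id %in% ref_ids, , drop = FALSE]
  if (!is.null(length_window))
    p <- p[p$length >= length_window[1L] & p$length <= length_window[2L], ,
           drop = FALSE]
  scores <- setNames(numeric(dmax), seq_len(dmax))
  if (nrow(p) > 0L) {
    for (id in unique(p$ref_id)) {
      q <- p[p$ref_id == id, , drop = FALSE]
      sp <- rowsum(q$count[q$strand == "sense"], q$pos5[q$strand == "sense"])
      ap <- rowsum(q$count[q$strand == "antisense"],
                   q$pos5[q$strand == "antisense"])
      if (is.null(dim(sp)) || nrow(sp) == 0L || nrow(ap) == 0L) next
      spos <- as.integer(rownames(sp)); sc <- as.numeric(sp[, 1L])
      apos <- as.integer(rownames(ap)); ac <- as.numeric(ap[, 1L])
      for (d in seq_len(dmax)) {
        j <- match(spos + d - 1L, apos)
        ok <- !is.na(j)
        if (any(ok)) scores[d] <- scores[d] + sum(sc[ok] * ac[j[ok]])
      }
    }
  }
  structure(list(scores = scores, zscores = NULL, n_pairs = sum(scores),
                 length_window = length_window, degenerate = NA),
            class = "overlap_signature")
}

#' Standardise overlap scores to Z-scores
#'
#' `z(d) = (s(d) - mean(s)) / sd(s)` with the population standard deviation
#' (divisor n) over all scanned distances — the scanned distances are the
#' full population of interest, and the focal distance is not excluded from
#' the background. If the scores have zero variance all Z-scores are set to
#' 0 and the signature is flagged degenerate.
#'
#' @param signature An `overlap_signature` from [overlap_counts()], or a
#'   bare numeric vector of scores.
#' @param exclude_d0 Optional distance to exclude from the mean/sd
#'   background (default `NULL`: include all distances).
#' @return The `overlap_signature` with `zscores` and `degenerate` filled in.
#' @export
overlap_zscores <- function(signature, exclude_d0 = NULL) {
  if (is.numeric(signature))
    signature <- structure(list(scores = setNames(signature,
                                                  seq_along(signature)),
                                zscores = NULL, n_pairs = sum(signature),
                                length_window = NULL, degenerate = NA),
                           class = "overlap_signature")
  s <- signature$scores
  bg <- if (is.null(exclude_d0)) s else s[-exclude_d0]
  mu <- mean(bg)
  sdev <- sqrt(mean((bg - mu)^2))
  if (sdev == 0) {
    signature$zscores <- setNames(rep(0, length(s)), names(s))
    signature$degenerate <- TRUE
  } else {
    signature$zscores <- (s - mu) / sdev
    signature$degenerate <- FALSE
  }
  signature
}

#' Test for a significant ping-pong signal
#'
#' Significant when the Z-score at the focal overlap distance strictly
#' exceeds the critical value (default 2.58, the two-sided standard-normal
#' critical value at p = 0.01). Degenerate signatures are never significant.
#'
#' @param signature An `overlap_signature` with Z-scores (computed on the
#'   fly if absent).
#' @param d0 Focal overlap distance; default 10, the slicer geometry.
#' @param zcrit Critical Z value; default 2.58.
#' @return A list with `significant`, `z_at_d0`, `d0`, `zcrit` and
#'   `degenerate`.
#' @export
pingpong_test <- function(signature, d0 = 10L, zcrit = 2.58) {
  stopifnot(inherits(signature, "overlap_signature"))
  if (is.null(signature$zscores)) signature <- overlap_zscores(signature)
  z <- unname(signature$zscores[as.character(d0)])
  list(significant = !isTRUE(signature$degenerate) && z > zcrit,
       z_at_d0 = z, d0 = d0, zcrit = zcrit,
       degenerate = isTRUE(signature$degenerate))
}

#' @export
print.overlap_signature <- function(x, ...) {
  cat(sprintf("overlap_signature: %s weighted pairs over d = 1..%d\n",
              format(x$n_pairs), length(x$scores)))
  if (!is.null(x$zscores))
    cat(sprintf("  max Z = %.3f at d = %s\n", max(x$zscores),
                names(x$zscores)[which.max(x$zscores)]))
  invisible(x)
}
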