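# Terminal chemical-structure inference. Periodate oxidation destroys 3'
# ends with vicinal 2',3'-OH groups, so 2'-O-methylated species are
# overrepresented in an oxidised library; terminator-exonuclease treatment
# removes 5'-monoP species, so 5'-di/tri-phosphorylated species are
# overrepresented in the 5'-polyP-enriched library. Enrichment or depletion
# of a class between the standard and treated libraries therefore reports
# its terminal state.

#' Compare a class between standard and treated libraries
#'
#' Computes the RPM of the scoped class in each library (each normalised to
#' its own mapped total, so calls are depth-invariant), forms the
#' pseudo-counted ratio `(rpm_treated + eps) / (rpm_standard + eps)`, and
#' calls the class `"enriched"`, `"depleted"` or `"unchanged"` against
#' symmetric fold thresholds.
#'
#' @param standard `srna_classification` of the standard library.
#' @param treated `srna_classification` of the treated library.
#' @param category Optional category scope.
#' @param ref_ids Optional locus scope.
#' @param eps Pseudo-RPM added to both sides; default 1.
#' @param enrich_fold Ratio at or above which the class is enriched
#'   (default 2).
#' @param deplete_fold Ratio at or below which the class is depleted
#'   (default 0.5).
#' @return A `treatment_comparison`: list with `scope`, `treatment`,
#'   `rpm_standard`, `rpm_treated`, `ratio`, `call`.
#' @export
class_enrichment <- function(standard, treated, category = NULL,
                             ref_ids = NULL, eps = 1,
                             enrich_fold = 2, deplete_fold = 0.5) {
  stopifnot(inherits(standard, "srna_classification"),
            inherits(treated, "srna_classification"))
  if (is.null(category) && is.null(ref_ids))
    stop("provide a category or a set of ref_ids")
  cs <- sum(locus_counts(standard, category = category, ref_ids = ref_ids))
  ct <- sum(locus_counts(treated, category = category, ref_ids = ref_ids))
  if (cs == 0 && ct == 0)
    stop("scope is empty in both libraries")
  rs <- rpm(cs, standard$total_mapped)
  rt <- rpm(ct, treated$total_mapped)
  ratio <- (rt + eps) / (rs + eps)
  call <- if (ratio >= enrich_fold) "enriched"
          else if (ratio <= deplete_fold) "depleted"
          else "unchanged"
  structure(list(scope = if (is.null(ref_ids)) category else ref_ids,
                 treatment = treated$treatment,
                 rpm_standard = rs, rpm_treated = rt,
                 ratio = ratio, call = call),
            class = "treatment_comparison")
}

#' Infer 3' and 5' terminal states of an sRNA class
#'
#' The 3' state follows the oxidised-library comparison: enrichment implies
#' a 2'-O-methylated 3' end (protected from periodate), depletion implies
#' free vicinal 2',3'-OH groups, anything else is indeterminate. The 5'
#' state follows the 5'-polyP-enriched library: enrichment implies 5'
#' di/tri-phosphate; depletion or no change implies 5'-monophosphate, but
#' only when the class is adequately abundant in the standard library
#' (absence of enrichment is uninformative for scarce species).
#'
#' @param ox `treatment_comparison` against the oxidised library.
#' @param polyp `treatment_comparison` against the 5'-polyP library.
#' @param min_standard_rpm Minimum standard-library RPM for a monoP call;
#'   default 10.
#' @return A `terminal_structure_call`: list with `scope`, `three_prime`
#'   (`"two_prime_O_me"`, `"two_prime_OH"` or `"indeterminate"`) and
#'   `five_prime` (`"polyP"`, `"monoP"` or `"indeterminate"`).
#' @export
infer_terminal_structure <- function(ox, polyp, min_standard_rpm = 10) {
  stopifnot(inherits(ox, "treatment_comparison"),
            inherits(polyp, "treatment_comparison"))
  if (!identical(ox$scope, polyp$scope))
    stop("the two comparisons must share the same scope")
  three <- switch(ox$call,
                  enriched = "two_prime_O_me",
                  depleted = "two_prime_OH",
                  "indeterminate")
  five <- if (polyp$call == "enriched") "polyP"
          else if (polyp$rpm_standard > min_standard_rpm) "monoP"
          else "indeterminate"
  structure(list(scope = ox$scope, three_prime = three, five_prime = five),
            class = "terminal_structure_call")
}
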