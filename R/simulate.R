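# Synthetic reference sets and knockdown library panels with planted ground
# truth: category-structured read origins, strand asymmetries, planted
# factor dependencies, ping-pong read pairs and per-class terminal chemical
# states. The generator gives every downstream stage an exact oracle.

#' Define a simulated small-RNA class
#'
#' A class bundles everything the generator needs to emit reads for one
#' biological sRNA population: its hierarchy category, locus count, length
#' distribution, strand mix, 5'-nucleotide bias, the biogenesis factors it
#' depends on, its terminal chemical states, the fraction of reads emitted
#' as ping-pong pairs, and its expected abundance per locus in the control
#' condition.
#'
#' @param name Class identifier.
#' @param category Hierarchy category label its loci belong to.
#' @param n_loci Number of reference loci (>= 1).
#' @param length_distribution Named numeric vector of probabilities over
#'   read lengths within 18-30 nt; must sum to 1.
#' @param strand_mix Fraction of reads drawn antisense, in \[0, 1\].
#' @param five_prime_bias Named probabilities over `c("A","C","G","T")` for
#'   the read's 5' nucleotide; must sum to 1. Realised by weighting start
#'   positions, so reads remain exact substrings of their locus.
#' @param dependencies Character vector of factor labels (e.g. `"RdRP1"`,
#'   `"AGO3"`) whose knockdown reduces this class.
#' @param three_prime_state `"two_prime_OH"` or `"two_prime_O_me"` (3'
#'   terminal 2'-position state).
#' @param five_prime_state `"monoP"` or `"polyP"` (5' phosphorylation).
#' @param pingpong_fraction Fraction of reads emitted as 10-nt-overlap
#'   sense/antisense pairs; > 0 requires `strand_mix` strictly inside (0,1).
#' @param abundance Expected read copies per locus in the control library.
#' @return A `sim_class` object.
#' @export
sim_class <- function(name, category, n_loci,
                      length_distribution,
                      strand_mix = 0,
                      five_prime_bias = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      dependencies = character(),
                      three_prime_state = c("two_prime_OH", "two_prime_O_me"),
                      five_prime_state = c("monoP", "polyP"),
                      pingpong_fraction = 0,
                      abundance = 500) {
  three_prime_state <- match.arg(three_prime_state)
  five_prime_state <- match.arg(five_prime_state)
  lens <- as.integer(names(length_distribution))
  if (anyNA(lens) || any(lens < 18L) || any(lens > 30L))
    stop("length_distribution must be named by lengths within 18-30")
  if (abs(sum(length_distribution) - 1) > 1e-9)
    stop("length_distribution must sum to 1")
  if (abs(sum(five_prime_bias) - 1) > 1e-9)
    stop("five_prime_bias must sum to 1")
  if (!all(c("A", "C", "G", "T") %in% names(five_prime_bias)))
    stop("five_prime_bias must be named A, C, G, T")
  if (strand_mix < 0 || strand_mix > 1) stop("strand_mix must be in [0,1]")
  if (pingpong_fraction > 0 && (strand_mix <= 0 || strand_mix >= 1))
    stop("pingpong_fraction > 0 requires strand_mix strictly inside (0,1)")
  if (n_loci < 1L) stop("n_loci must be >= 1")
  structure(list(name = name, category = category, n_loci = as.integer(n_loci),
                 length_distribution = length_distribution,
                 strand_mix = strand_mix,
                 five_prime_bias = five_prime_bias[c("A", "C", "G", "T")],
                 dependencies = as.character(dependencies),
                 three_prime_state = three_prime_state,
                 five_prime_state = five_prime_state,
                 pingpong_fraction = pingpong_fraction,
                 abundance = abundance),
            class = "sim_class")
}

peak_dist <- function(center, spread = c(0.15, 0.7, 0.15)) {
  setNames(spread, center + seq_along(spread) - 1L - (length(spread) %/% 2L))
}

#' The ten knockdown conditions of the study design
#'
#' One dsGFP control plus nine factor knockdowns (four AGO-clade Argonautes,
#' two PIWI-clade genes with AGO3 targeted by two independent dsRNAs, and
#' two RdRPs).
#'
#' @return Character vector of condition labels, control first.
#' @export
default_conditions <- function() {
  c("dsGFP", "dsAgo-16", "dsAgo-30", "dsAgo-78", "dsAgo-96", "dsAub",
    "dsAGO3-1", "dsAGO3-2", "dsRdRP1", "dsRdRP3")
}

#' Default simulated class panel
#'
#' Five classes mirroring the main endogenous sRNA populations of tick
#' cells: a 5'U-biased 22-nt miRNA class depending on Ago-78; a
#' double-stranded 22-nt class from RNAP III-transcribed genes depending on
#' RdRP1 and Ago-30 (2'-OH, 5'-monoP); a repeat-derived 22-nt siRNA class
#' depending on RdRP3 and Ago-16; a repeat-derived 25-30 nt piRNA class
#' depending on Aub and AGO3 (2'-O-me, ping-pong fraction 0.3); and a
#' factor-independent 22-nt viral siRNA class.
#'
#' @return Named list of [sim_class()] objects.
#' @export
default_sim_classes <- function() {
  list(
    miRNA = sim_class("miRNA", "miRNA", n_loci = 4,
      length_distribution = peak_dist(22L),
      strand_mix = 0,
      five_prime_bias = c(A = 0.1, C = 0.1, G = 0.1, T = 0.7),
      dependencies = "Ago-78", abundance = 800),
    RNAPIII_siRNA = sim_class("RNAPIII_siRNA", "RNAPIII", n_loci = 3,
      length_distribution = peak_dist(22L),
      strand_mix = 0.5,
      dependencies = c("RdRP1", "Ago-30"), abundance = 700),
    repeat_siRNA = sim_class("repeat_siRNA", "repeat", n_loci = 3,
      length_distribution = peak_dist(22L),
      strand_mix = 0.5,
      dependencies = c("RdRP3", "Ago-16"), abundance = 700),
    repeat_piRNA = sim_class("repeat_piRNA", "repeat", n_loci = 3,
      length_distribution = c(`25` = 0.10, `26` = 0.25, `27` = 0.30,
                              `28` = 0.20, `29` = 0.10, `30` = 0.05),
      strand_mix = 0.5,
      five_prime_bias = c(A = 0.1, C = 0.1, G = 0.1, T = 0.7),
      dependencies = c("Aub", "AGO3"),
      three_prime_state = "two_prime_O_me",
      pingpong_fraction = 0.3, abundance = 1000),
    viral_siRNA = sim_class("viral_siRNA", "virus", n_loci = 1,
      length_distribution = peak_dist(22L),
      strand_mix = 0.5, abundance = 500)
  )
}

#' Define a knockdown panel design
#'
#' @param conditions Ordered condition labels, control first (exactly once).
#'   Default: the ten-library design of [default_conditions()].
#' @param knockdown_efficiency Fractional reduction applied to dependent
#'   classes in their knockdown library, in (0, 1\].
#' @param depth Optional target total read copies per library; `NULL` (the
#'   default) lets per-locus abundances define the depth. When given, all
#'   expected counts are rescaled uniformly so the control totals `depth`.
#' @param seed Integer RNG seed for library generation.
#' @return A `sim_design` object.
#' @export
sim_design <- function(conditions = default_conditions(),
                       knockdown_efficiency = 0.8, depth = NULL, seed = 1L) {
  control <- conditions[1L]
  if (sum(conditions == control) != 1L)
    stop("the control label must appear exactly once, first")
  if (knockdown_efficiency <= 0 || knockdown_efficiency > 1)
    stop("knockdown_efficiency must be in (0, 1]")
  structure(list(conditions = conditions, control = control,
                 knockdown_efficiency = knockdown_efficiency,
                 depth = depth, seed = as.integer(seed)),
            class = "sim_design")
}

# Factor targeted by a knockdown condition; the two AGO3 dsRNAs target the
# single AGO3 gene.
condition_factor <- function(condition) {
  f <- sub("^ds", "", condition)
  ifelse(f %in% c("AGO3-1", "AGO3-2"), "AGO3", f)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

canonical_kmers <- function(seq, k = 18L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  rc <- revcomp(km)
  unique(pmin(km, rc))
}

#' Generate synthetic reference sequences with planted truth
#'
#' Draws random locus sequences for each simulated class plus a genome
#' background, screening at construction time so that no 18-mer (on either
#' strand) is shared between any two sequences: every generated read of
#' >= 18 nt therefore maps to exactly one locus. Classes in category
#' `"virus"` are collected into a separate reference set for independent
#' remapping, mirroring how viral references are handled in practice.
#'
#' @param classes List of [sim_class()] objects.
#' @param background_length Genome-background length (>= 1000).
#' @param locus_length Length of each simulated locus (default 200 nt).
#' @param seed Integer RNG seed.
#' @param max_retries Per-sequence redraw attempts before giving up.
#' @return A list with elements `refset` (a [reference_set()] over the
#'   annotated categories), `virus` (a `reference_set` for viral classes, or
#'   `NULL`), and `truth` (data frame, one row per locus: `locus_id`,
#'   `class`, `category`, `dependencies` (comma-joined), `three_prime_state`,
#'   `five_prime_state`, `pingpong_fraction`, `abundance`, `strand_mix`,
#'   `sequence`); the class objects are attached as `attr(truth, "classes")`.
#' @export
generate_references <- function(classes, background_length = 5000L,
                                locus_length = 200L, seed = 1L,
                                max_retries = 50L) {
  if (background_length < 1000L)
    stop("background_length must be >= 1000")
  stopifnot(all(vapply(classes, inherits, logical(1), "sim_class")))
  set.seed(seed)
  seen <- character(0)
  draw_unique <- function(n) {
    for (i in seq_len(max_retries)) {
      s <- random_seq(n)
      km <- canonical_kmers(s)
      if (length(km) == length(unique(km)) && !any(km %in% seen)) {
        seen <<- c(seen, km)
        return(s)
      }
    }
    stop("could not draw a k-mer-unique sequence after ", max_retries,
         " attempts; use longer or more diverse references")
  }
  rows <- list()
  for (cl in classes) {
    for (j in seq_len(cl$n_loci)) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = sprintf("%s_locus%02d", cl$name, j),
        class = cl$name, category = cl$category,
        dependencies = paste(cl$dependencies, collapse = ","),
        three_prime_state = cl$three_prime_state,
        five_prime_state = cl$five_prime_state,
        pingpong_fraction = cl$pingpong_fraction,
        abundance = cl$abundance, strand_mix = cl$strand_mix,
        sequence = draw_unique(locus_length),
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  background <- c(genome_bg = draw_unique(background_length))
  names(classes) <- vapply(classes, `[[`, character(1), "name")
  attr(truth, "classes") <- classes

  is_virus <- truth$category == "virus"
  main <- truth[!is_virus, , drop = FALSE]
  refset <- reference_set(
    data.frame(ref_id = main$locus_id, category = main$category,
               sequence = main$sequence, stringsAsFactors = FALSE),
    hierarchy = intersect(default_hierarchy(), unique(main$category)),
    background = background)
  virus <- NULL
  if (any(is_virus)) {
    v <- truth[is_virus, , drop = FALSE]
    virus <- reference_set(
      data.frame(ref_id = v$locus_id, category = "virus",
                 sequence = v$sequence, stringsAsFactors = FALSE),
      hierarchy = "virus")
  }
  list(refset = refset, virus = virus, truth = truth)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# Sample `n` reads of one length/strand from a locus, weighting start
# positions by the class 5'-nucleotide bias so reads stay exact substrings.
sample_reads <- function(ref, n, len, antisense, bias) {
  L <- nchar(ref)
  n_starts <- L - len + 1L
  if (n_starts < 1L) return(character(0))
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  nt5 <- if (!antisense) chars[seq_len(n_starts)]
         else unname(comp_base[chars[seq_len(n_starts) + len - 1L]])
  w <- bias[nt5]
  if (sum(w) <= 0) w <- rep(1, n_starts)
  starts <- sample.int(n_starts, n, replace = TRUE, prob = w) - 1L
  reads <- substring(ref, starts + 1L, starts + len)
  if (antisense) reads <- revcomp(reads)
  reads
}

# Emit `n_pairs` ping-pong pairs: a sense guide and an antisense partner
# whose 5' end sits opposite the guide's 10th nucleotide, giving the
# canonical 10-nt 5'-5' overlap.
sample_pairs <- function(ref, n_pairs, lens, probs, bias) {
  L <- nchar(ref)
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (i in seq_len(n_pairs)) {
    Ls <- lens[sample.int(length(lens), 1L, prob = probs)]
    La <- lens[sample.int(length(lens), 1L, prob = probs)]
    lo <- max(0L, La - 10L)
    hi <- L - max(Ls, 10L)
    if (hi < lo) next
    starts <- lo:hi
    w <- bias[chars[starts + 1L]]
    if (sum(w) <= 0) w <- rep(1, length(starts))
    s <- starts[sample.int(length(starts), 1L, prob = w)]
    guide <- substring(ref, s + 1L, s + Ls)
    partner <- revcomp(substring(ref, s + 10L - La + 1L, s + 10L))
    out <- c(out, guide, partner)
  }
  out
}

#' Generate a panel of knockdown libraries from planted truth
#'
#' For each condition, each locus's expected copy count is its class
#' abundance, multiplied by `1 - knockdown_efficiency` when the class
#' depends on the factor targeted in that condition (pure multiplicative
#' knockdown; the two AGO3 dsRNA conditions both target the AGO3 factor).
#' Realised per-locus counts are Poisson. Reads are exact substrings of
#' their locus (sense) or reverse complements of substrings (antisense),
#' with lengths drawn from the class distribution and 5' nucleotides biased
#' by weighted start-position sampling; classes with a positive ping-pong
#' fraction emit that fraction of reads as 10-nt-overlap sense/antisense
#' pairs. Planted dependency factors not targeted by any knockdown condition
#' trigger a warning (their effect can never be observed); control-only
#' designs are silent.
#'
#' @param refs Result of [generate_references()] (or a list with a `truth`
#'   element of the same shape).
#' @param design A [sim_design()].
#' @return A list with elements `libraries` (named list of
#'   [read_library()], one per condition), `expected` and `realized`
#'   (loci x conditions matrices of expected and realised copy counts).
#' @export
generate_libraries <- function(refs, design) {
  stopifnot(inherits(design, "sim_design"))
  truth <- refs$truth
  classes <- attr(truth, "classes")
  kd_factors <- condition_factor(setdiff(design$conditions, design$control))
  planted <- unique(unlist(strsplit(truth$dependencies[truth$dependencies != ""],
                                    ",")))
  missing <- setdiff(planted, kd_factors)
  if (length(missing) > 0L && length(kd_factors) > 0L)
    warning("planted dependency factor(s) not covered by the design ",
            "(their knockdown effect cannot be observed): ",
            paste(missing, collapse = ", "))

  set.seed(design$seed)
  n_cond <- length(design$conditions)
  expected <- matrix(0, nrow(truth), n_cond,
                     dimnames = list(truth$locus_id, design$conditions))
  for (ci in seq_len(n_cond)) {
    cond <- design$conditions[ci]
    f <- condition_factor(cond)
    for (li in seq_len(nrow(truth))) {
      deps <- strsplit(truth$dependencies[li], ",")[[1L]]
      hit <- cond != design$control && f %in% deps
      expected[li, ci] <- truth$abundance[li] *
        (if (hit) 1 - design$knockdown_efficiency else 1)
    }
  }
  if (!is.null(design$depth)) {
    sc <- design$depth / sum(expected[, design$control])
    expected <- expected * sc
  }
  if (sum(expected[, design$control]) < 10 * nrow(truth))
    warning("expected control depth is below 10 reads per locus; ",
            "classes may not all be realised")

  realized <- expected
  libraries <- vector("list", n_cond)
  names(libraries) <- design$conditions
  for (ci in seq_len(n_cond)) {
    all_reads <- character(0)
    for (li in seq_len(nrow(truth))) {
      cl <- classes[[truth$class[li]]]
      ref <- truth$sequence[li]
      n <- stats::rpois(1L, expected[li, ci])
      realized[li, ci] <- n
      if (n == 0L) next
      lens <- as.integer(names(cl$length_distribution))
      probs <- as.numeric(cl$length_distribution)
      n_pairs <- 0L
      if (cl$pingpong_fraction > 0 && n >= 2L)
        n_pairs <- stats::rbinom(1L, n %/% 2L, cl$pingpong_fraction)
      n_single <- n - 2L * n_pairs
      reads <- character(0)
      if (n_single > 0L) {
        anti <- stats::rbinom(n_single, 1L, cl$strand_mix) == 1L
        rl <- lens[sample.int(length(lens), n_single, replace = TRUE,
                              prob = probs)]
        for (a in c(FALSE, TRUE)) for (len in unique(rl[anti == a])) {
          k <- sum(anti == a & rl == len)
          reads <- c(reads, sample_reads(ref, k, len, a, cl$five_prime_bias))
        }
      }
      if (n_pairs > 0L)
        reads <- c(reads,
                   sample_pairs(ref, n_pairs, lens, probs, cl$five_prime_bias))
      all_reads <- c(all_reads, reads)
    }
    tab <- table(all_reads)
    libraries[[ci]] <- read_library(names(tab), as.integer(tab),
                                    label = design$conditions[ci])
  }
  list(libraries = libraries, expected = expected, realized = realized)
}

#' Default chemical-treatment retention probabilities
#'
#' Per-state survival probabilities of a read copy under each treatment:
#' periodate oxidation retains 2'-O-methylated 3' ends (0.95) and removes
#' species with vicinal 2',3'-OH groups (0.05); the terminator-exonuclease
#' 5'-polyP enrichment retains 5'-di/tri-phosphorylated species (0.9) and
#' removes 5'-monoP species (0.05).
#'
#' @return Named list of named numeric vectors, one per treatment.
#' @export
default_retention <- function() {
  list(oxidized = c(two_prime_O_me = 0.95, two_prime_OH = 0.05),
       five_prime_polyP = c(polyP = 0.9, monoP = 0.05))
}

#' Apply a chemical treatment to a simulated library
#'
#' Each read copy survives the treatment independently: counts are thinned
#' binomially with the survival probability of the read's planted terminal
#' state (looked up by locating the read in the truth table's locus
#' sequences). Reads not attributable to a planted locus are treated as
#' 2'-OH / 5'-monoP.
#'
#' @param lib A [read_library()] (standard treatment).
#' @param truth Truth table from [generate_references()].
#' @param treatment `"oxidized"` or `"five_prime_polyP"`.
#' @param retention Retention table as from [default_retention()].
#' @param seed Integer RNG seed.
#' @return A [read_library()] labelled with the treatment.
#' @export
apply_chemical_treatment <- function(lib, truth,
                                     treatment = c("oxidized", "five_prime_polyP"),
                                     retention = default_retention(),
                                     seed = 1L) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(lib, "read_library"))
  ret <- retention[[treatment]]
  state_col <- if (treatment == "oxidized") "three_prime_state"
               else "five_prime_state"
  default_state <- if (treatment == "oxidized") "two_prime_OH" else "monoP"
  set.seed(seed)
  reads <- lib$reads
  surv <- integer(nrow(reads))
  for (k in seq_len(nrow(reads))) {
    sq <- reads$sequence[k]
    hit <- which(vapply(truth$sequence, function(ref)
      grepl(sq, ref, fixed = TRUE) || grepl(revcomp(sq), ref, fixed = TRUE),
      logical(1)))[1L]
    state <- if (is.na(hit)) default_state else truth[[state_col]][hit]
    p <- ret[[state]]
    if (is.null(p)) stop("retention table lacks state: ", state)
    surv[k] <- stats::rbinom(1L, reads$count[k], p)
  }
  keep <- surv > 0L
  if (!any(keep)) stop("no reads survived the ", treatment, " treatment")
  read_library(reads$sequence[keep], surv[keep], label = lib$label,
               treatment = treatment)
}

#' Simulate a polyA-status expression panel
#'
#' Emits log2(TPM+1) expression points for spliceosomal RNAs (which define
#' the regression baseline: enriched in total RNA-seq relative to
#' polyA-selected RNA-seq) and for coding genes, a planted polyA status
#' (genes above the baseline are polyA(-)), and per-gene sRNA production
#' levels in which polyA(-) genes receive `srna_enrichment`-fold more sRNA
#' reads.
#'
#' @param n_spliceosomal Number of spliceosomal baseline points.
#' @param n_minus,n_plus Numbers of polyA(-) and polyA(+) coding genes.
#' @param srna_enrichment Fold sRNA enrichment of polyA(-) genes.
#' @param baseline_noise SD of the noise around the spliceosomal line.
#' @param seed Integer RNG seed.
#' @return A list with `expr` (data frame: `gene_id`, `x`, `y`, `role`),
#'   `srna` (named vector of log2(RPM+1) levels for coding genes) and
#'   `truth` (named vector `"polyA_minus"`/`"polyA_plus"`).
#' @export
simulate_polya_data <- function(n_spliceosomal = 30L, n_minus = 30L,
                                n_plus = 60L, srna_enrichment = 4,
                                baseline_noise = 0.1, seed = 1L) {
  set.seed(seed)
  slope <- 1
  intercept <- 1.5
  xs <- stats::runif(n_spliceosomal, 2, 8)
  spl <- data.frame(gene_id = sprintf("snRNA%03d", seq_len(n_spliceosomal)),
                    x = xs,
                    y = intercept + slope * xs +
                      stats::rnorm(n_spliceosomal, 0, baseline_noise),
                    role = "spliceosomal", stringsAsFactors = FALSE)
  xm <- stats::runif(n_minus, 2, 8)
  minus <- data.frame(gene_id = sprintf("geneM%03d", seq_len(n_minus)),
                      x = xm,
                      y = intercept + slope * xm + stats::runif(n_minus, 0.5, 2.5),
                      role = "coding", stringsAsFactors = FALSE)
  xp <- stats::runif(n_plus, 2, 8)
  plus <- data.frame(gene_id = sprintf("geneP%03d", seq_len(n_plus)),
                     x = xp,
                     y = pmax(0, intercept + slope * xp -
                                stats::runif(n_plus, 0.5, 2.5)),
                     role = "coding", stringsAsFactors = FALSE)
  base_rpm <- stats::rlnorm(n_minus + n_plus, meanlog = 3, sdlog = 1)
  fold <- c(rep(srna_enrichment, n_minus), rep(1, n_plus))
  srna <- setNames(log2(base_rpm * fold + 1),
                   c(minus$gene_id, plus$gene_id))
  truth <- setNames(c(rep("polyA_minus", n_minus), rep("polyA_plus", n_plus)),
                    c(minus$gene_id, plus$gene_id))
  list(expr = rbind(spl, minus, plus), srna = srna, truth = truth)
}
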