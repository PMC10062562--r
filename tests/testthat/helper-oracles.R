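# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (full scans, pairwise enumeration) so they
# stay independent of the implementation paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive exact-match scan: compare the read (and its reverse complement)
# against every position of every reference sequence.
naive_match <- function(sequence, refset) {
  rc <- revcomp(sequence)
  L <- nchar(sequence)
  rows <- list()
  seqs <- c(refset$records$sequence, unname(refset$background))
  ids <- c(refset$records$ref_id, names(refset$background))
  for (i in seq_along(seqs)) {
    ref <- seqs[[i]]
    n <- nchar(ref)
    if (n < L) next
    for (strand in c("sense", "antisense")) {
      pat <- if (strand == "sense") sequence else rc
      for (st in 0:(n - L)) {
        if (substr(ref, st + 1L, st + L) == pat)
          rows[[length(rows) + 1L]] <- data.frame(
            ref_id = ids[i], strand = strand, start = st,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ref_id = character(), strand = character(),
                      start = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Brute-force 5'-5' overlap enumeration over individual read records.
# `reads` has columns ref_id, strand, pos5, count.
brute_overlap <- function(reads, dmax = 25L) {
  scores <- setNames(numeric(dmax), seq_len(dmax))
  s <- reads[reads$strand == "sense", , drop = FALSE]
  a <- reads[reads$strand == "antisense", , drop = FALSE]
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(a))) {
    if (s$ref_id[i] != a$ref_id[j]) next
    d <- a$pos5[j] - s$pos5[i] + 1L
    if (d >= 1L && d <= dmax)
      scores[d] <- scores[d] + s$count[i] * a$count[j]
  }
  scores
}

# A small deterministic reference set with distinguishable categories.
tiny_refset <- function(seed = 42L, n_per_cat = 2L, ref_len = 120L,
                        categories = c("miRNA", "RNAPIII", "repeat"),
                        background_length = 400L) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(categories, function(cat) {
    data.frame(ref_id = sprintf("%s_%d", cat, seq_len(n_per_cat)),
               category = cat,
               sequence = replicate(n_per_cat, random_dna(ref_len)),
               stringsAsFactors = FALSE)
  }))
  reference_set(recs, hierarchy = categories,
                background = c(bg = random_dna(background_length)))
}

# Merge the virus reference set (if any) into the annotated hierarchy so a
# single classification run covers all simulated classes.
combined_refset <- function(refs) {
  if (is.null(refs$virus)) return(refs$refset)
  reference_set(rbind(refs$refset$records, refs$virus$records),
                hierarchy = c(refs$refset$hierarchy, "virus"),
                background = refs$refset$background)
}

# Truth dependency sets in the same comma-joined sorted encoding as
# dependency calls.
truth_sets <- function(truth) {
  setNames(vapply(strsplit(truth$dependencies, ","), function(d)
    paste(sort(d), collapse = ","), character(1)), truth$locus_id)
}

# Compact knockdown panel used by recovery tests: the default five classes
# at reduced locus counts, viral class omitted unless requested.
small_panel_classes <- function(abundance = 500, with_virus = FALSE,
                                pingpong_fraction = 0.3) {
  cl <- list(
    miRNA = sim_class("miRNA", "miRNA", n_loci = 2,
      length_distribution = c(`21` = 0.15, `22` = 0.7, `23` = 0.15),
      strand_mix = 0,
      five_prime_bias = c(A = 0.1, C = 0.1, G = 0.1, T = 0.7),
      dependencies = "Ago-78", abundance = abundance),
    RNAPIII_siRNA = sim_class("RNAPIII_siRNA", "RNAPIII", n_loci = 2,
      length_distribution = c(`21` = 0.15, `22` = 0.7, `23` = 0.15),
      strand_mix = 0.5,
      dependencies = c("RdRP1", "Ago-30"), abundance = abundance),
    repeat_siRNA = sim_class("repeat_siRNA", "repeat", n_loci = 2,
      length_distribution = c(`21` = 0.15, `22` = 0.7, `23` = 0.15),
      strand_mix = 0.5,
      dependencies = c("RdRP3", "Ago-16"), abundance = abundance),
    repeat_piRNA = sim_class("repeat_piRNA", "repeat", n_loci = 2,
      length_distribution = c(`25` = 0.1, `26` = 0.25, `27` = 0.3,
                              `28` = 0.2, `29` = 0.1, `30` = 0.05),
      strand_mix = 0.5,
      five_prime_bias = c(A = 0.1, C = 0.1, G = 0.1, T = 0.7),
      dependencies = c("Aub", "AGO3"),
      three_prime_state = "two_prime_O_me",
      pingpong_fraction = pingpong_fraction, abundance = abundance * 1.5)
  )
  if (with_virus)
    cl$viral_siRNA <- sim_class("viral_siRNA", "virus", n_loci = 1,
      length_distribution = c(`21` = 0.15, `22` = 0.7, `23` = 0.15),
      strand_mix = 0.5, abundance = abundance)
  cl
}

# A pure ping-pong panel: one repeat-piRNA class with no dependencies, for
# overlap-signature tests against a single control library.
pingpong_panel <- function(seed, rho = 0.3, abundance = 2000, n_loci = 3) {
  cls <- list(repeat_piRNA = sim_class(
    "repeat_piRNA", "repeat", n_loci = n_loci,
    length_distribution = c(`25` = 0.1, `26` = 0.25, `27` = 0.3,
                            `28` = 0.2, `29` = 0.1, `30` = 0.05),
    strand_mix = 0.5,
    five_prime_bias = c(A = 0.1, C = 0.1, G = 0.1, T = 0.7),
    pingpong_fraction = rho, abundance = abundance))
  refs <- generate_references(cls, seed = seed)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP",
                                             seed = seed + 1L))
  list(refs = refs, lib = sim$libraries$dsGFP)
}
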