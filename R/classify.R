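# Sequential hierarchical classification of collapsed reads against an
# ordered reference set, with strand-aware per-locus profiles and RPM
# normalisation. Matching is exact on both strands (no mismatches), the
# convention used for small-RNA source annotation.

# All exact occurrences of `pattern` in each of `subjects`; 0-based starts.
locate_all <- function(pattern, subjects) {
  cand <- which(grepl(pattern, subjects, fixed = TRUE))
  if (length(cand) == 0L) return(NULL)
  out <- lapply(cand, function(i) {
    g <- gregexpr(pattern, subjects[[i]], fixed = TRUE)[[1L]]
    as.integer(g) - 1L
  })
  list(idx = cand, starts = out)
}

#' Find all exact mapping hits of a read
#'
#' Scans every reference record and background sequence for exact occurrences
#' of the read (sense hits) and of its reverse complement (antisense hits).
#' Coordinates are 0-based half-open: a hit at `start` covers
#' `[start, start + nchar(sequence))` on the reference.
#'
#' @param sequence Read sequence (>= 15 nt, A/C/G/T).
#' @param refset A [reference_set()].
#' @return Data frame with columns `ref_id`, `category`, `strand`
#'   (`"sense"`/`"antisense"`) and `start`, ordered by reference record,
#'   sense before antisense, then start. Zero rows if the read maps nowhere.
#' @examples
#' rs <- reference_set(data.frame(ref_id = "refA", category = "miRNA",
#'                                sequence = strrep("ACGT", 10)))
#' match_read("ACGTACGTACGTACGTACGT", rs)
#' @export
match_read <- function(sequence, refset) {
  stopifnot(inherits(refset, "reference_set"))
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) < 15L) stop("read must be >= 15 nt")
  seqs <- c(refset$records$sequence, unname(refset$background))
  ids <- c(refset$records$ref_id, names(refset$background))
  cats <- c(refset$records$category,
            rep("genome", length(refset$background)))
  rc <- revcomp(sequence)
  rows <- list()
  sense <- locate_all(sequence, seqs)
  anti <- locate_all(rc, seqs)
  for (i in sort(unique(c(sense$idx, anti$idx)))) {
    if (!is.null(sense) && i %in% sense$idx) {
      st <- sense$starts[[match(i, sense$idx)]]
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = ids[i], category = cats[i], strand = "sense", start = st,
        stringsAsFactors = FALSE)
    }
    if (!is.null(anti) && i %in% anti$idx) {
      st <- anti$starts[[match(i, anti$idx)]]
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = ids[i], category = cats[i], strand = "antisense", start = st,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ref_id = character(), category = character(),
                      strand = character(), start = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assign a read to the first matching hierarchy category
#'
#' Sequential assignment: the read takes the first category in hierarchy
#' order with at least one exact hit on either strand; `"genome"` if only the
#' background matches; `"unmapped"` otherwise.
#'
#' @param sequence Read sequence.
#' @param refset A [reference_set()].
#' @return A single category label.
#' @export
assign_category <- function(sequence, refset) {
  hits <- match_read(sequence, refset)
  if (nrow(hits) == 0L) return("unmapped")
  annotated <- intersect(refset$hierarchy, hits$category)
  if (length(annotated) > 0L) return(annotated[1L])
  "genome"
}

#' Classify a read library against a reference hierarchy
#'
#' Every read within the length window is assigned to the first hierarchy
#' category it hits (sequential mapping); reads hitting only the genome
#' background fall in the `"genome"` sink; the rest are unmapped. A read
#' contributes its copy count exactly once to its category total, but its
#' profile rows are added at every locus of the assigned category that it
#' hits (multi-locus reads are counted fully at each locus). Per-locus
#' profiles record strand, 5'-end reference position, read length and 5'
#' nucleotide. The 5' end of an antisense read is at reference position
#' `start + length - 1`.
#'
#' @param lib A [read_library()].
#' @param refset A [reference_set()].
#' @param length_range Inclusive read-length window; reads outside it are
#'   excluded from all totals. Default `c(18, 30)`.
#' @return An object of class `srna_classification`: a list with elements
#'   `label`, `treatment`, `category_totals` (data frame: `category`,
#'   `n_reads`, `count`, `rpm`), `profiles` (data frame: `ref_id`,
#'   `category`, `strand`, `pos5`, `length`, `nt5`, `count`), `total_mapped`
#'   (summed copies hitting any reference or background), `unmapped_count`
#'   and `length_range`.
#' @export
classify_library <- function(lib, refset, length_range = c(18L, 30L)) {
  stopifnot(inherits(lib, "read_library"), inherits(refset, "reference_set"))
  reads <- lib$reads
  len <- nchar(reads$sequence)
  inwin <- len >= length_range[1L] & len <= length_range[2L]
  reads <- reads[inwin, , drop = FALSE]

  cat_levels <- c(refset$hierarchy,
                  if (!is.null(refset$background)) "genome")
  cat_count <- setNames(numeric(length(cat_levels)), cat_levels)
  cat_nreads <- cat_count
  total_mapped <- 0
  unmapped <- 0

  seqs <- c(refset$records$sequence, unname(refset$background))
  ids <- c(refset$records$ref_id, names(refset$background))
  n_rec <- nrow(refset$records)
  rec_rank <- match(refset$records$category, refset$hierarchy)
  acc_ref <- list(); acc_strand <- list(); acc_pos <- list()
  acc_len <- integer(0); acc_nt5 <- character(0); acc_count <- numeric(0)
  acc_cat <- character(0)

  for (k in seq_len(nrow(reads))) {
    sq <- reads$sequence[k]
    ct <- reads$count[k]
    rc <- revcomp(sq)
    s_hit <- grepl(sq, seqs, fixed = TRUE)
    a_hit <- grepl(rc, seqs, fixed = TRUE)
    any_hit <- s_hit | a_hit
    if (!any(any_hit)) { unmapped <- unmapped + ct; next }
    total_mapped <- total_mapped + ct
    rec_hit <- which(any_hit[seq_len(n_rec)])
    if (length(rec_hit) == 0L) {
      cat_count["genome"] <- cat_count["genome"] + ct
      cat_nreads["genome"] <- cat_nreads["genome"] + 1L
      next
    }
    best <- min(rec_rank[rec_hit])
    cat <- refset$hierarchy[best]
    cat_count[cat] <- cat_count[cat] + ct
    cat_nreads[cat] <- cat_nreads[cat] + 1L
    L <- nchar(sq)
    for (i in rec_hit[rec_rank[rec_hit] == best]) {
      if (s_hit[i]) {
        st <- as.integer(gregexpr(sq, seqs[[i]], fixed = TRUE)[[1L]]) - 1L
        j <- length(acc_ref) + 1L
        acc_ref[[j]] <- rep(ids[i], length(st))
        acc_strand[[j]] <- rep("sense", length(st))
        acc_pos[[j]] <- st
        acc_len <- c(acc_len, rep(L, length(st)))
        acc_nt5 <- c(acc_nt5, rep(substr(sq, 1L, 1L), length(st)))
        acc_count <- c(acc_count, rep(ct, length(st)))
        acc_cat <- c(acc_cat, rep(cat, length(st)))
      }
      if (a_hit[i]) {
        st <- as.integer(gregexpr(rc, seqs[[i]], fixed = TRUE)[[1L]]) - 1L
        j <- length(acc_ref) + 1L
        acc_ref[[j]] <- rep(ids[i], length(st))
        acc_strand[[j]] <- rep("antisense", length(st))
        acc_pos[[j]] <- st + L - 1L
        acc_len <- c(acc_len, rep(L, length(st)))
        acc_nt5 <- c(acc_nt5, rep(substr(sq, 1L, 1L), length(st)))
        acc_count <- c(acc_count, rep(ct, length(st)))
        acc_cat <- c(acc_cat, rep(cat, length(st)))
      }
    }
  }

  if (length(acc_ref) == 0L)
    profiles <- data.frame(ref_id = character(), category = character(),
                           strand = character(), pos5 = integer(),
                           length = integer(), nt5 = character(),
                           count = numeric(), stringsAsFactors = FALSE)
  else {
    profiles <- data.frame(ref_id = unlist(acc_ref), category = acc_cat,
                           strand = unlist(acc_strand),
                           pos5 = unlist(acc_pos), length = acc_len,
                           nt5 = acc_nt5, count = acc_count,
                           stringsAsFactors = FALSE)
    profiles <- stats::aggregate(
      count ~ ref_id + category + strand + pos5 + length + nt5,
      data = profiles, FUN = sum)
    profiles <- profiles[order(profiles$ref_id, profiles$strand,
                               profiles$pos5, profiles$length), ]
    rownames(profiles) <- NULL
  }
  totals <- data.frame(category = cat_levels,
                       n_reads = as.integer(cat_nreads),
                       count = as.numeric(cat_count),
                       stringsAsFactors = FALSE)
  totals$rpm <- if (total_mapped > 0) totals$count / total_mapped * 1e6 else 0
  structure(list(label = lib$label, treatment = lib$treatment,
                 category_totals = totals, profiles = profiles,
                 total_mapped = total_mapped, unmapped_count = unmapped,
                 length_range = as.integer(length_range)),
            class = "srna_classification")
}

#' @export
print.srna_classification <- function(x, ...) {
  cat(sprintf("srna_classification '%s': %s mapped copies, %s unmapped\n",
              x$label, format(x$total_mapped), format(x$unmapped_count)))
  print(x$category_totals)
  invisible(x)
}

#' Reads-per-million normalisation
#'
#' Normalises a summed read count to the library's total of reads mapping to
#' the genomic reference (reads per million genome-mapping reads).
#'
#' @param count Summed read count (copies).
#' @param total_mapped Total mapped copies of the library; must be > 0.
#' @return `count / total_mapped * 1e6`.
#' @export
rpm <- function(count, total_mapped) {
  if (!is.numeric(total_mapped) || any(total_mapped <= 0))
    stop("total_mapped must be > 0")
  count / total_mapped * 1e6
}

#' Per-locus read counts within a length window
#'
#' Sums profile counts per locus, optionally restricted to a read-length
#' window, a category or an explicit locus set. Because profile rows repeat a
#' read at every locus it hits, the same multi-locus counting convention as
#' [classify_library()] applies.
#'
#' @param result An `srna_classification`.
#' @param category Optional category label to restrict to.
#' @param ref_ids Optional locus identifiers to restrict to.
#' @param length_window Optional inclusive length window `c(min, max)`.
#' @return Named numeric vector of summed counts per `ref_id`.
#' @export
locus_counts <- function(result, category = NULL, ref_ids = NULL,
                         length_window = NULL) {
  stopifnot(inherits(result, "srna_classification"))
  p <- result$profiles
  if (!is.null(category)) p <- p[p$category %in% category, , drop = FALSE]
  if (!is.null(ref_ids)) {
    unknown <- setdiff(ref_ids, p$ref_id)
    p <- p[p$ref_id %in% ref_ids, , drop = FALSE]
  }
  if (!is.null(length_window))
    p <- p[p$length >= length_window[1L] & p$length <= length_window[2L], ,
           drop = FALSE]
  if (nrow(p) == 0L) return(setNames(numeric(0), character(0)))
  v <- rowsum(p$count, p$ref_id)
  setNames(as.numeric(v), rownames(v))
}

#' Length x 5'-nucleotide x strand size profile
#'
#' Aggregates the profile of a category or locus selection into the classic
#' small-RNA size-distribution table: for each read length in the
#' classification window, each 5' nucleotide and each strand, the
#' RPM-normalised summed count. Antisense values are stored non-negative;
#' negate them for mirrored plotting.
#'
#' @param result An `srna_classification`.
#' @param category Optional category selector.
#' @param ref_ids Optional locus selector; unknown ids raise an error.
#' @return Data frame with columns `length`, `nt5`, `strand`, `count`, `rpm`.
#' @export
size_profile <- function(result, category = NULL, ref_ids = NULL) {
  stopifnot(inherits(result, "srna_classification"))
  if (is.null(category) && is.null(ref_ids))
    stop("provide a category or a set of ref_ids")
  p <- result$profiles
  if (!is.null(ref_ids)) {
    unknown <- setdiff(ref_ids, unique(p$ref_id))
    if (length(unknown) > 0L)
      stop("unknown ref_id in selector: ", unknown[1L])
    p <- p[p$ref_id %in% ref_ids, , drop = FALSE]
  }
  if (!is.null(category)) p <- p[p$category %in% category, , drop = FALSE]
  grid <- expand.grid(length = seq(result$length_range[1L],
                                   result$length_range[2L]),
                      nt5 = c("A", "C", "G", "T"),
                      strand = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  if (nrow(p) > 0L) {
    agg <- stats::aggregate(count ~ length + nt5 + strand, data = p, FUN = sum)
    grid <- merge(grid, agg, all.x = TRUE, sort = FALSE)
    grid$count[is.na(grid$count)] <- 0
  } else grid$count <- 0
  grid <- grid[order(grid$strand, grid$length, grid$nt5), ]
  rownames(grid) <- NULL
  grid$rpm <- rpm(grid$count, result$total_mapped)
  grid
}
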