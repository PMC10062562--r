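#' srnapipe: small RNA classification, dependency and terminal-structure analysis
#'
#' Analysis of collapsed small-RNA libraries from knockdown panels:
#' hierarchical classification of reads by genomic source, RPM normalisation,
#' per-locus strand/length/5'-nucleotide profiles, knockdown-dependency
#' calling, ping-pong overlap signatures, terminal chemical-structure
#' inference from treated libraries, and polyA-status association, together
#' with a synthetic-library generator that plants ground truth for every
#' stage.
#'
#' @importFrom stats rpois rbinom runif rnorm rlnorm lm coef median
#'   wilcox.test sd setNames aggregate qnorm
#' @importFrom utils write.table head
#' @name srnapipe-package
"_PACKAGE"

VALID_TREATMENTS <- c("standard", "oxidized", "five_prime_polyP")

#' Construct a collapsed read library
#'
#' A read library is the collapsed representation of one sequencing library:
#' each unique sequence appears once, paired with the number of copies
#' observed. Sequences are uppercased and U is normalised to T.
#'
#' @param sequences Character vector of read sequences (A/C/G/T/U).
#' @param counts Integer vector of copy counts, one per sequence, all >= 1.
#' @param label Condition label (e.g. `"dsGFP"`, `"dsRdRP1"`).
#' @param treatment Library treatment: `"standard"`, `"oxidized"` or
#'   `"five_prime_polyP"`.
#' @return An object of class `read_library`: a list with elements `label`,
#'   `treatment`, `reads` (data frame with columns `sequence`, `count`) and
#'   `total_count`.
#' @examples
#' lib <- read_library(c("TACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACG"),
#'                     c(5L, 2L), label = "dsGFP")
#' lib$total_count
#' @export
read_library <- function(sequences, counts, label = "library",
                         treatment = "standard") {
  treatment <- match.arg(treatment, VALID_TREATMENTS)
  if (length(sequences) != length(counts))
    stop("'sequences' and 'counts' must have equal length")
  if (length(sequences) == 0L)
    stop("a read library must contain at least one read")
  sequences <- normalize_seq(sequences)
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 1L))
    stop("all counts must be integers >= 1")
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("sequences contain non-ACGT characters: ",
         paste(utils::head(sequences[bad], 3L), collapse = ", "))
  if (anyDuplicated(sequences)) {
    warning("duplicate sequences merged by summing counts")
    agg <- rowsum(counts, sequences)
    sequences <- rownames(agg)
    counts <- as.integer(agg[, 1L])
  }
  len <- nchar(sequences)
  if (any(len < 15L | len > 35L))
    stop("read lengths must be within 15-35 nt; filter before construction")
  structure(list(label = label, treatment = treatment,
                 reads = data.frame(sequence = sequences, count = counts,
                                    stringsAsFactors = FALSE),
                 total_count = sum(counts)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library '%s' (%s): %d unique reads, %d total copies\n",
              x$label, x$treatment, nrow(x$reads), x$total_count))
  invisible(x)
}

normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Read a collapsed FASTA file
#'
#' Parses the collapsed representation written by read-deduplication tools:
#' each record header carries the copy count of its sequence. Two header
#' dialects are supported: `">name_count"` (underscore-delimited, count last;
#' the default) and `">name count"` (whitespace-delimited).
#'
#' Reads containing non-ACGT characters and reads outside the 15-35 nt parse
#' window are dropped with a message; duplicate sequences are merged by
#' summing counts with a warning.
#'
#' @param path Path to the FASTA file.
#' @param label Condition label for the library; defaults to the file name.
#' @param treatment Treatment label (see [read_library()]).
#' @param dialect `"underscore"` or `"whitespace"` header dialect.
#' @return A [read_library()].
#' @export
read_collapsed_fasta <- function(path, label = NULL, treatment = "standard",
                                 dialect = c("underscore", "whitespace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label))
    label <- sub("\\.(fa|fasta|fas)$", "", basename(path), ignore.case = TRUE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  pat <- if (dialect == "underscore") "_[0-9]+\\s*$" else "[ \t][0-9]+\\s*$"
  m <- regexpr(pat, headers)
  counts <- rep(NA_character_, length(headers))
  counts[m > 0] <- gsub("[^0-9]", "", regmatches(headers, m))
  bad <- is.na(counts) | counts == ""
  if (any(bad))
    stop(sprintf("malformed collapsed header (no trailing count) at record %d: '%s'",
                 which(bad)[1L], headers[which(bad)[1L]]))
  counts <- as.integer(counts)
  seqs <- normalize_seq(as.character(ss))
  keep_nt <- !grepl("[^ACGT]", seqs)
  if (any(!keep_nt))
    message(sum(!keep_nt), " read(s) with ambiguous bases dropped")
  len <- nchar(seqs)
  keep_len <- len >= 15L & len <= 35L
  if (any(keep_nt & !keep_len))
    message(sum(keep_nt & !keep_len), " read(s) outside the 15-35 nt window dropped")
  keep <- keep_nt & keep_len
  if (!any(keep)) stop("no valid reads in ", path)
  read_library(seqs[keep], counts[keep], label = label, treatment = treatment)
}

#' Write a collapsed FASTA file
#'
#' Inverse of [read_collapsed_fasta()]: writes one record per unique
#' sequence with headers `">read<i>_<count>"`. Refuses to write an empty
#' library.
#'
#' @param lib A [read_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "read_library"))
  if (nrow(lib$reads) == 0L) stop("refusing to write an empty library")
  ss <- Biostrings::BStringSet(lib$reads$sequence)
  names(ss) <- sprintf("read%06d_%d", seq_len(nrow(lib$reads)), lib$reads$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Default classification hierarchy
#'
#' The ordered category labels used for sequential read assignment, matching
#' the standard annotation order for tick small-RNA libraries: miRNAs first,
#' then RNA polymerase III transcripts, rRNAs, snoRNAs/mRNAs and repeats.
#' The optional genome background acts as a final `"genome"` sink after all
#' annotated categories.
#'
#' @return Character vector of category labels in precedence order.
#' @export
default_hierarchy <- function() {
  c("miRNA", "RNAPIII", "rRNA", "snoRNA_mRNA", "repeat")
}

#' Construct a reference set
#'
#' A reference set holds the ordered classification hierarchy and the
#' category-annotated reference sequences, plus an optional genome-background
#' sequence collection used as the final `"genome"` sink.
#'
#' @param records Data frame with columns `ref_id`, `category`, `sequence`
#'   (sequences given 5'->3' on the annotated sense strand, >= 18 nt).
#' @param hierarchy Ordered character vector of category labels;
#'   defaults to the categories in `records` ordered by [default_hierarchy()].
#' @param background Optional named character vector of genome-background
#'   sequences.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(records, hierarchy = NULL, background = NULL) {
  stopifnot(is.data.frame(records),
            all(c("ref_id", "category", "sequence") %in% names(records)))
  records$sequence <- normalize_seq(records$sequence)
  records$ref_id <- as.character(records$ref_id)
  records$category <- as.character(records$category)
  if (anyDuplicated(records$ref_id))
    stop("duplicate ref_id in reference set: ",
         records$ref_id[duplicated(records$ref_id)][1L])
  if (any(nchar(records$sequence) < 18L))
    stop("reference sequences must be >= 18 nt")
  if (is.null(hierarchy)) {
    known <- default_hierarchy()
    cats <- unique(records$category)
    hierarchy <- c(intersect(known, cats), setdiff(cats, known))
  }
  if (!all(records$category %in% hierarchy))
    stop("record category not in hierarchy: ",
         setdiff(records$category, hierarchy)[1L])
  if (!is.null(background)) {
    background <- normalize_seq(background)
    if (is.null(names(background)))
      names(background) <- sprintf("background%d", seq_along(background))
  }
  structure(list(hierarchy = hierarchy,
                 records = records[c("ref_id", "category", "sequence")],
                 background = background),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d records in %d categories [%s]%s\n",
              nrow(x$records), length(x$hierarchy),
              paste(x$hierarchy, collapse = " > "),
              if (is.null(x$background)) "" else
                sprintf(" + %d background seq(s)", length(x$background))))
  invisible(x)
}

#' Load a reference set from a YAML manifest
#'
#' The manifest lists per-category FASTA files in hierarchy order, e.g.
#' \preformatted{
#' categories:
#'   miRNA: mirna.fa
#'   RNAPIII: rnap3.fa
#' background: genome.fa   # optional
#' }
#' Relative FASTA paths are resolved against the manifest's directory.
#' Category order in the manifest defines the classification hierarchy.
#'
#' @param manifest Path to the YAML manifest.
#' @return A [reference_set()].
#' @export
load_reference_set <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  cfg <- yaml::read_yaml(manifest)
  if (is.null(cfg$categories) || length(cfg$categories) == 0L)
    stop("manifest must list at least one category under 'categories'")
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  recs <- do.call(rbind, lapply(names(cfg$categories), function(cat) {
    fa <- Biostrings::readBStringSet(resolve(cfg$categories[[cat]]))
    data.frame(ref_id = names(fa), category = cat,
               sequence = as.character(fa), stringsAsFactors = FALSE)
  }))
  background <- NULL
  if (!is.null(cfg$background)) {
    fa <- Biostrings::readBStringSet(resolve(cfg$background))
    background <- setNames(as.character(fa), names(fa))
  }
  reference_set(recs, hierarchy = names(cfg$categories),
                background = background)
}

#' Write a reference set to FASTA files plus manifest
#'
#' @param refset A [reference_set()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_reference_set <- function(refset, dir) {
  stopifnot(inherits(refset, "reference_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cats <- list()
  for (cat in refset$hierarchy) {
    rec <- refset$records[refset$records$category == cat, ]
    if (nrow(rec) == 0L) next
    ss <- Biostrings::BStringSet(setNames(rec$sequence, rec$ref_id))
    fn <- paste0(cat, ".fa")
    Biostrings::writeXStringSet(ss, file.path(dir, fn))
    cats[[cat]] <- fn
  }
  cfg <- list(categories = cats)
  if (!is.null(refset$background)) {
    ss <- Biostrings::BStringSet(refset$background)
    Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
    cfg$background <- "genome.fa"
  }
  manifest <- file.path(dir, "references.yaml")
  yaml::write_yaml(cfg, manifest)
  invisible(manifest)
}

#' Write a tabular result as TSV
#'
#' UTF-8 tab-separated output with a header line; numeric columns are
#' serialised at full precision so that a re-parse reproduces the values.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("'rows' must be a data frame")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
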