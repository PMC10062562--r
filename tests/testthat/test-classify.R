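test_that("match_read reports exact hits with 0-based coordinates on both strands", {
  set.seed(5)
  refA <- random_dna(120)
  refB <- random_dna(120)
  rs <- reference_set(data.frame(ref_id = c("refA", "refB"),
                                 category = c("miRNA", "repeat"),
                                 sequence = c(refA, refB)))
  sense_read <- substr(refA, 11, 32)          # 0-based positions 10..31
  h <- match_read(sense_read, rs)
  expect_equal(h[h$ref_id == "refA", c("strand", "start")],
               data.frame(strand = "sense", start = 10L),
               ignore_attr = TRUE)

  anti_read <- revcomp(substr(refB, 6, 27))   # 0-based start 5
  h <- match_read(anti_read, rs)
  hB <- h[h$ref_id == "refB", ]
  expect_true(any(hB$strand == "antisense" & hB$start == 5L))
})

test_that("palindromic reads hit both strands, sense listed first", {
  pal <- "ACGTACGTACGTACGTACGT"   # reverse complement of itself
  expect_equal(revcomp(pal), pal)
  ref <- paste0("GGGCC", pal, "CCAAG")
  rs <- reference_set(data.frame(ref_id = "r", category = "repeat",
                                 sequence = ref))
  h <- match_read(pal, rs)
  expect_equal(nrow(h), 2L)
  expect_equal(h$strand, c("sense", "antisense"))
  expect_equal(h$start, c(5L, 5L))
})

test_that("match_read agrees with a naive position scan on random instances", {
  set.seed(21)
  for (rep in 1:25) {
    rs <- tiny_refset(seed = rep, n_per_cat = sample(1:3, 1),
                      ref_len = sample(60:200, 1))
    # half planted substrings, half random reads
    planted <- rep %% 2 == 0
    read <- if (planted) {
      ref <- sample(rs$records$sequence, 1)
      L <- sample(18:25, 1)
      st <- sample(nchar(ref) - L + 1, 1)
      s <- substr(ref, st, st + L - 1)
      if (runif(1) < 0.5) revcomp(s) else s
    } else random_dna(sample(15:25, 1))
    got <- match_read(read, rs)
    want <- naive_match(read, rs)
    key <- function(d) sort(paste(d$ref_id, d$strand, d$start))
    expect_equal(key(got), key(want))
  }
})

test_that("sequential assignment follows hierarchy order with genome sink", {
  set.seed(9)
  shared <- random_dna(22)
  mi <- paste0(random_dna(30), shared, random_dna(30))
  rp <- paste0(random_dna(20), shared, random_dna(40))
  bg <- random_dna(300)
  rs <- reference_set(data.frame(ref_id = c("mi1", "rep1"),
                                 category = c("miRNA", "repeat"),
                                 sequence = c(mi, rp)),
                      hierarchy = c("miRNA", "repeat"),
                      background = c(genome = bg))
  expect_equal(assign_category(shared, rs), "miRNA")
  expect_equal(assign_category(substr(bg, 50, 71), rs), "genome")
  expect_equal(assign_category(random_dna(22), rs), "unmapped")
})

test_that("classification bookkeeping: counts, multi-locus profiles, window", {
  set.seed(13)
  core <- random_dna(22)
  repA <- paste0(random_dna(10), core, random_dna(10))
  repB <- paste0(random_dna(25), core, random_dna(5))
  rs <- reference_set(data.frame(ref_id = c("repA", "repB"),
                                 category = "repeat",
                                 sequence = c(repA, repB)))
  long_read <- substr(paste0(repA, repA), 1, 31)  # 31 nt, outside window
  lib <- read_library(c(core, substr(repA, 1, 31)), c(5L, 2L))
  res <- classify_library(lib, rs)
  # 31-nt read excluded entirely; core counts once to the category...
  expect_equal(res$category_totals$count[res$category_totals$category == "repeat"], 5)
  expect_equal(res$total_mapped, 5)
  # ...but profiles at both loci it hits
  expect_setequal(unique(res$profiles$ref_id), c("repA", "repB"))
  expect_equal(res$profiles$count[res$profiles$ref_id == "repA"], 5)
  expect_equal(res$profiles$count[res$profiles$ref_id == "repB"], 5)
  expect_equal(res$profiles$pos5[res$profiles$ref_id == "repA"], 10)
  expect_equal(res$profiles$pos5[res$profiles$ref_id == "repB"], 25)
})

test_that("antisense 5' ends are reported at start + length - 1", {
  set.seed(17)
  ref <- random_dna(80)
  rs <- reference_set(data.frame(ref_id = "r", category = "repeat",
                                 sequence = ref))
  read <- revcomp(substr(ref, 21, 42))  # 0-based [20, 42), length 22
  lib <- read_library(read, 3L)
  res <- classify_library(lib, rs)
  p <- res$profiles
  expect_equal(p$strand, "antisense")
  expect_equal(p$pos5, 20L + 22L - 1L)
  expect_equal(p$nt5, substr(read, 1, 1))
})

test_that("rpm is linear with the stated normalisation and guards zero totals", {
  expect_equal(rpm(5, 1000), 5000)
  expect_equal(rpm(0, 1000), 0)
  expect_equal(rpm(1000, 1000), 1e6)
  expect_error(rpm(5, 0), "total_mapped")
})

test_that("category percentages plus unannotated sum to 100% of mapped reads", {
  classes <- small_panel_classes(abundance = 300)
  refs <- generate_references(classes, seed = 31)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP", seed = 32))
  res <- classify_library(sim$libraries$dsGFP, refs$refset)
  expect_equal(sum(res$category_totals$count), res$total_mapped)
  expect_equal(sum(res$category_totals$rpm), 1e6)
})

test_that("removing a hierarchy category only moves reads later, never earlier", {
  classes <- small_panel_classes(abundance = 200)
  refs <- generate_references(classes, seed = 41)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP", seed = 42))
  lib <- sim$libraries$dsGFP
  rs <- refs$refset
  rs_drop <- reference_set(rs$records[rs$records$category != "miRNA", ],
                           hierarchy = setdiff(rs$hierarchy, "miRNA"),
                           background = rs$background)
  rank_full <- c(setNames(seq_along(rs$hierarchy), rs$hierarchy),
                 genome = length(rs$hierarchy) + 1,
                 unmapped = length(rs$hierarchy) + 2)
  set.seed(43)
  for (sq in sample(lib$reads$sequence, 60)) {
    before <- assign_category(sq, rs)
    after <- assign_category(sq, rs_drop)
    expect_gte(rank_full[[after]], rank_full[[before]])
  }
})

test_that("size profiles conserve counts and recover planted bimodal lengths", {
  classes <- small_panel_classes(abundance = 400)
  refs <- generate_references(classes, seed = 51)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP", seed = 52))
  res <- classify_library(sim$libraries$dsGFP, refs$refset)

  sp <- size_profile(res, category = "repeat")
  # conservation: cells scale back to the selector's summed profile count
  expect_equal(sum(sp$rpm) * res$total_mapped / 1e6,
               sum(res$profiles$count[res$profiles$category == "repeat"]))

  # direct counting of generated reads is the oracle for the modes
  lens <- nchar(sim$libraries$dsGFP$reads$sequence)
  cnts <- sim$libraries$dsGFP$reads$count
  hist_all <- vapply(18:30, function(L) sum(cnts[lens == L]), numeric(1))
  names(hist_all) <- 18:30
  whole <- size_profile(res, category = refs$refset$hierarchy)
  by_len <- vapply(18:30, function(L)
    sum(whole$count[whole$length == L]), numeric(1))
  names(by_len) <- 18:30
  expect_equal(by_len, hist_all)
  short_mode <- as.integer(names(which.max(by_len[as.character(18:24)])))
  long_mode <- as.integer(names(which.max(by_len[as.character(25:30)])))
  expect_equal(short_mode, 22L)
  expect_true(long_mode %in% 26:29)

  # concentrated input -> single nonzero cell
  ref <- refs$refset$records$sequence[1]
  id <- refs$refset$records$ref_id[1]
  one <- classify_library(read_library(substr(ref, 1, 22), 4L),
                          refs$refset)
  spo <- size_profile(one, ref_ids = id)
  nz <- spo[spo$count > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$length, 22L)
  expect_equal(nz$strand, "sense")
  expect_error(size_profile(one, ref_ids = "no_such_locus"), "unknown")
})
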