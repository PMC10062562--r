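test_that("reference generation counts loci, keeps 18-mers unique, is seeded", {
  classes <- list(
    sim_class("a", "miRNA", n_loci = 3,
              length_distribution = c(`22` = 1), abundance = 100),
    sim_class("b", "repeat", n_loci = 3,
              length_distribution = c(`22` = 1), abundance = 100))
  refs <- generate_references(classes, seed = 5)
  expect_equal(nrow(refs$refset$records), 6L)
  expect_equal(nrow(refs$truth), 6L)
  expect_null(refs$virus)

  # determinism: same seed, identical sequences
  refs2 <- generate_references(classes, seed = 5)
  expect_identical(refs2$truth$sequence, refs$truth$sequence)
  expect_identical(refs2$refset$background, refs$refset$background)

  # no shared 18-mer (either strand) between any two sequences
  all_seqs <- c(refs$truth$sequence, unname(refs$refset$background))
  kmers <- lapply(all_seqs, function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - 17), 18:n)
    unique(pmin(km, revcomp(km)))
  })
  expect_equal(anyDuplicated(unlist(kmers)), 0L)

  expect_error(generate_references(classes, background_length = 500),
               "background_length")
})

test_that("sim_class validates its probability vectors and ping-pong contract", {
  expect_error(sim_class("x", "repeat", 1,
                         length_distribution = c(`22` = 0.5)), "sum to 1")
  expect_error(sim_class("x", "repeat", 1,
                         length_distribution = c(`40` = 1)), "18-30")
  expect_error(sim_class("x", "repeat", 1, length_distribution = c(`22` = 1),
                         strand_mix = 0, pingpong_fraction = 0.3),
               "strand_mix")
})

test_that("knockdown planting follows the multiplicative reduction arithmetic", {
  cls <- list(sim_class("dep", "repeat", n_loci = 2,
                        length_distribution = c(`22` = 1),
                        dependencies = "RdRP1", abundance = 1000),
              sim_class("indep", "miRNA", n_loci = 1,
                        length_distribution = c(`22` = 1),
                        dependencies = "Ago-78", abundance = 400))
  refs <- generate_references(cls, seed = 8)
  des <- sim_design(conditions = c("dsGFP", "dsRdRP1", "dsAgo-78"),
                    knockdown_efficiency = 0.8, seed = 9)
  sim <- generate_libraries(refs, des)
  expect_equal(unname(sim$expected["dep_locus01", ]), c(1000, 200, 1000))
  expect_equal(unname(sim$expected["indep_locus01", ]), c(400, 400, 80))
  # count conservation: realised per-locus counts sum to the library total
  for (cond in des$conditions)
    expect_equal(sum(sim$realized[, cond]),
                 sim$libraries[[cond]]$total_count)
  # determinism
  sim2 <- generate_libraries(refs, des)
  expect_identical(sim2$libraries$dsGFP$reads, sim$libraries$dsGFP$reads)
})

test_that("strand_mix 0 yields no antisense reads and 5' bias is realised", {
  cls <- list(sim_class("sense_only", "miRNA", n_loci = 1,
                        length_distribution = c(`22` = 1), strand_mix = 0,
                        five_prime_bias = c(A = 0, C = 0, G = 0, T = 1),
                        abundance = 400))
  refs <- generate_references(cls, seed = 12)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP", seed = 13))
  lib <- sim$libraries$dsGFP
  ref <- refs$truth$sequence[1]
  expect_true(all(vapply(lib$reads$sequence, function(s)
    grepl(s, ref, fixed = TRUE), logical(1))))
  expect_true(all(substr(lib$reads$sequence, 1, 1) == "T"))
})

test_that("uncovered planted dependencies are flagged, except in control-only designs", {
  cls <- list(sim_class("dep", "repeat", n_loci = 1,
                        length_distribution = c(`22` = 1),
                        dependencies = "RdRP9", abundance = 100))
  refs <- generate_references(cls, seed = 3)
  expect_warning(generate_libraries(refs, sim_design(seed = 1)), "RdRP9")
  expect_silent(generate_libraries(refs, sim_design(conditions = "dsGFP",
                                                    seed = 1)))
})

test_that("chemical treatment thins counts per planted state, reproducibly", {
  cls <- list(
    sim_class("pi", "repeat", n_loci = 1, length_distribution = c(`27` = 1),
              strand_mix = 0.5, three_prime_state = "two_prime_O_me",
              abundance = 600),
    sim_class("si", "RNAPIII", n_loci = 1, length_distribution = c(`22` = 1),
              strand_mix = 0.5, abundance = 600))
  refs <- generate_references(cls, seed = 21)
  sim <- generate_libraries(refs, sim_design(conditions = "dsGFP", seed = 22))
  lib <- sim$libraries$dsGFP

  ox1 <- apply_chemical_treatment(lib, refs$truth, "oxidized", seed = 23)
  ox2 <- apply_chemical_treatment(lib, refs$truth, "oxidized", seed = 23)
  expect_identical(ox1$reads, ox2$reads)
  expect_equal(ox1$treatment, "oxidized")

  # retention 0 removes every copy of that state
  ret <- default_retention()
  ret$oxidized["two_prime_OH"] <- 0
  ox0 <- apply_chemical_treatment(lib, refs$truth, "oxidized",
                                  retention = ret, seed = 24)
  pi_ref <- refs$truth$sequence[refs$truth$class == "pi"]
  from_pi <- vapply(ox0$reads$sequence, function(s)
    grepl(s, pi_ref, fixed = TRUE) || grepl(revcomp(s), pi_ref, fixed = TRUE),
    logical(1))
  expect_true(all(from_pi))
})

test_that("oxidation enrichment matches the closed-form expectation", {
  # two classes, equal abundance: survivors are Binomial(count, r_state);
  # expected post-treatment fraction of the 2'-O-me class is
  # r_ome / (r_ome + r_oh) for equal class totals.
  cls <- list(
    sim_class("ome", "repeat", n_loci = 1, length_distribution = c(`27` = 1),
              strand_mix = 0.5, three_prime_state = "two_prime_O_me",
              abundance = 500),
    sim_class("oh", "RNAPIII", n_loci = 1, length_distribution = c(`22` = 1),
              strand_mix = 0.5, abundance = 500))
  ret <- default_retention()$oxidized
  want <- ret[["two_prime_O_me"]] / sum(ret)
  fracs <- numeric(30)
  for (s in seq_len(30)) {
    refs <- generate_references(cls, seed = 100 + s)
    sim <- generate_libraries(refs, sim_design(conditions = "dsGFP",
                                               seed = 200 + s))
    ox <- apply_chemical_treatment(sim$libraries$dsGFP, refs$truth,
                                   "oxidized", seed = 300 + s)
    ome_ref <- refs$truth$sequence[refs$truth$class == "ome"]
    is_ome <- vapply(ox$reads$sequence, function(x)
      grepl(x, ome_ref, fixed = TRUE) ||
        grepl(revcomp(x), ome_ref, fixed = TRUE), logical(1))
    fracs[s] <- sum(ox$reads$count[is_ome]) / ox$total_count
  }
  expect_equal(mean(fracs), want, tolerance = 0.03)
})

test_that("library depth rescaling preserves planted fold changes", {
  cls <- list(sim_class("dep", "repeat", n_loci = 2,
                        length_distribution = c(`22` = 1),
                        dependencies = "RdRP1", abundance = 1000))
  refs <- generate_references(cls, seed = 30)
  des <- sim_design(conditions = c("dsGFP", "dsRdRP1"),
                    knockdown_efficiency = 0.8, depth = 500, seed = 31)
  sim <- generate_libraries(refs, des)
  expect_equal(sum(sim$expected[, "dsGFP"]), 500)
  expect_equal(unname(sim$expected[, "dsRdRP1"] / sim$expected[, "dsGFP"]),
               c(0.2, 0.2))
})
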