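test_that("flanking k-mers follow the half-open slice convention", {
  f <- extract_flanks("ACGTACGTAC", p = 5, k = 3)
  expect_equal(f, c(s = "GTA", t = "CGT"))
  expect_equal(extract_flanks("ACGTACGTAC", p = 3, k = 3)[["s"]], "ACG")
  expect_error(extract_flanks("ACGTACGTAC", p = 1, k = 3),
               "too close to contig end")
  expect_error(extract_flanks("ACGNACGTAC", p = 4, k = 3),
               "ambiguous flank")
})

test_that("a planted insertion is genotyped exactly with filtering on", {
  cfg <- sim_config(reference_length = 30000, n_insertions = 1L,
                    length_range = c(300L, 300L), coverage = 30,
                    mean_insert = 1500, sd_insert = 150,
                    min_separation = 4000L, seed = 99L)
  sim <- simulate_insertion_dataset(cfg)
  model <- insert_size_model(cfg$read_length, cfg$mean_insert,
                             cfg$sd_insert)
  params <- run_params(k = 31, min_abundance = 1, coverage = cfg$coverage)
  calls <- genotype_all(sim$sites, sim$reference, unname(sim$reads),
                        alignments = sim$alignments, model = model,
                        params = params)
  expect_equal(calls$status, "filled")
  expect_identical(calls$insertion, sim$insertion_truth$seq)
  expect_equal(insertion_score(calls$insertion,
                               sim$insertion_truth$seq)$score, 0)
})

test_that("filtering off and on give the same sequence when both succeed", {
  cfg <- sim_config(reference_length = 20000, n_insertions = 1L,
                    length_range = c(150L, 150L), coverage = 30,
                    mean_insert = 500, sd_insert = 50,
                    min_separation = 2000L, seed = 7L)
  sim <- simulate_insertion_dataset(cfg)
  model <- insert_size_model(cfg$read_length, cfg$mean_insert,
                             cfg$sd_insert)
  params <- run_params(k = 31, min_abundance = 1, coverage = cfg$coverage)
  with_f <- genotype_all(sim$sites, sim$reference, unname(sim$reads),
                         alignments = sim$alignments, model = model,
                         params = params)
  without_f <- genotype_all(sim$sites, sim$reference, sim$reads,
                            model = model, params = params)
  expect_equal(with_f$status, "filled")
  expect_equal(without_f$status, "filled")
  expect_identical(with_f$insertion, without_f$insertion)
})

test_that("absent local signal yields not_filled, not an error", {
  set.seed(3)
  ref <- make_reference(2000)
  # reads from the reference only: the 100 nt "insertion" is unsupported
  cfg <- sim_config(reference_length = 2000, n_insertions = 0L,
                    mean_insert = 300, sd_insert = 30, coverage = 20)
  rd <- simulate_reads(ref, cfg)
  sites <- insertion_sites("ref", 1000L, 100L)
  calls <- genotype_all(sites, ref, rd$reads,
                        params = run_params(k = 21, min_abundance = 1))
  expect_equal(calls$status, "not_filled")
  expect_true(is.na(calls$insertion))
})

test_that("a zero-length site is filled with the empty insertion", {
  set.seed(13)
  ref <- make_reference(2000)
  cfg <- sim_config(reference_length = 2000, n_insertions = 0L,
                    mean_insert = 300, sd_insert = 30, coverage = 20)
  rd <- simulate_reads(ref, cfg)
  sites <- insertion_sites("ref", 1000L, 0L)
  calls <- genotype_all(sites, ref, rd$reads,
                        params = run_params(k = 21, min_abundance = 1,
                                            slack = 0L))
  expect_equal(calls$status, "filled")
  expect_identical(calls$insertion, "")
})

test_that("duplicate sites produce identical independent calls", {
  cfg <- sim_config(reference_length = 20000, n_insertions = 1L,
                    length_range = c(120L, 120L), coverage = 30,
                    mean_insert = 500, sd_insert = 50,
                    min_separation = 2000L, seed = 23L)
  sim <- simulate_insertion_dataset(cfg)
  sites2 <- rbind(sim$sites, sim$sites)
  params <- run_params(k = 31, min_abundance = 1)
  expect_warning(
    calls <- genotype_all(sites2, sim$reference, sim$reads,
                          params = params),
    "processed independently")
  expect_equal(nrow(calls), 2L)
  expect_identical(calls$insertion[1], calls$insertion[2])
})

test_that("an empty site list yields an empty report", {
  sites <- insertion_sites(character(0), integer(0), integer(0),
                           id = character(0))
  calls <- genotype_all(sites, "ACGT", c("ACGTACGT"),
                        params = run_params(k = 5, min_abundance = 1))
  expect_equal(nrow(calls), 0L)
})

test_that("splicing exact calls back reproduces the simulated donor", {
  cfg <- sim_config(reference_length = 30000, n_insertions = 3L,
                    length_range = c(50L, 400L), coverage = 30,
                    mean_insert = 500, sd_insert = 50,
                    min_separation = 3000L, seed = 77L)
  sim <- simulate_insertion_dataset(cfg)
  calls <- genotype_all(sim$sites, sim$reference, sim$reads,
                        params = run_params(k = 31, min_abundance = 1))
  expect_true(all(calls$status == "filled"))
  expect_identical(splice_insertions(sim$reference, calls), sim$donor)
})
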