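test_that("reference generation is seed-reproducible with near-uniform composition", {
  expect_identical(make_reference(10, seed = 1), make_reference(10, seed = 1))
  expect_equal(nchar(make_reference(1, seed = 2)), 1L)
  r <- make_reference(100000, seed = 3)
  comp <- table(strsplit(r, "")[[1]]) / 100000
  # binomial: 3 sigma around 0.25 at n = 1e5 is ~0.0041
  expect_true(all(abs(comp - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("planting conserves length and records recoverable coordinates", {
  set.seed(11)
  ref <- make_reference(60000)
  cfg <- sim_config(reference_length = 60000, n_insertions = 5L,
                    length_range = c(20L, 500L), min_separation = 5000L)
  pl <- plant_insertions(ref, cfg)
  expect_equal(nchar(pl$donor), 60000 + sum(pl$truth$length))
  for (i in seq_len(5)) {
    q <- pl$truth$donor_start[i]
    d <- pl$truth$length[i]
    expect_identical(substr(pl$donor, q + 1, q + d), pl$truth$seq[i])
  }
  expect_true(all(diff(sort(pl$sites$breakpoint)) >= 5000))
})

test_that("planting zero insertions returns the reference unchanged", {
  ref <- make_reference(500, seed = 4)
  pl <- plant_insertions(ref, sim_config(reference_length = 500,
                                         n_insertions = 0L))
  expect_identical(pl$donor, ref)
  expect_equal(nrow(pl$sites), 0L)
})

test_that("an over-packed reference triggers the capacity error", {
  ref <- make_reference(1000, seed = 5)
  cfg <- sim_config(reference_length = 1000, n_insertions = 50L,
                    min_separation = 100L)
  expect_error(plant_insertions(ref, cfg), "too short")
})

test_that("pair count, substring identity and insert-size moments hold", {
  set.seed(21)
  donor <- make_reference(100000)
  cfg <- sim_config(reference_length = 100000, n_insertions = 0L,
                    coverage = 30, read_length = 100,
                    mean_insert = 1500, sd_insert = 150)
  rd <- simulate_reads(donor, cfg)
  expect_equal(length(rd$reads), 2L * ceiling(30 * 100000 / 200))

  # error-free reads are exact donor substrings (reverse strand reads
  # are reverse complements)
  idx <- sample(length(rd$reads), 200)
  tr <- rd$truth[idx, ]
  raw <- substring(donor, tr$start + 1, tr$end)
  expect_identical(unname(rd$reads[idx]),
                   ifelse(tr$strand == "-", revcomp(raw), raw))

  # CLT bound on the realized mean insert size
  ins <- rd$truth$insert[rd$truth$strand == "+"]
  expect_lt(abs(mean(ins) - 1500), 4 * 150 / sqrt(length(ins)))
})

test_that("substitution errors appear at roughly the requested rate", {
  set.seed(31)
  donor <- make_reference(20000)
  cfg <- sim_config(reference_length = 20000, n_insertions = 0L,
                    coverage = 10, mean_insert = 500, sd_insert = 50,
                    error_rate = 0.01)
  rd <- simulate_reads(donor, cfg)
  tr <- rd$truth
  raw <- substring(donor, tr$start + 1, tr$end)
  raw <- ifelse(tr$strand == "-", revcomp(raw), raw)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    rd$reads, raw))
  total <- sum(nchar(raw))
  expect_gt(mism / total, 0.005)
  expect_lt(mism / total, 0.02)
})

test_that("truth-mode projection maps flank reads and unmaps insertion reads", {
  ins_truth <- data.frame(id = "ins001", breakpoint = 1000L,
                          donor_start = 1000L, length = 200L,
                          seq = NA, stringsAsFactors = FALSE)
  read_truth <- data.frame(
    read_id = c("a/1", "a/2", "b/1", "b/2", "c/1", "c/2"),
    pair_id = c("a", "a", "b", "b", "c", "c"),
    start = c(100L, 1050L, 2000L, 950L, 800L, 1150L),
    end = c(200L, 1150L, 2100L, 1050L, 900L, 1250L),
    strand = rep(c("+", "-"), 3),
    insert = rep(0L, 6), stringsAsFactors = FALSE)
  aln <- truth_alignments(read_truth, ins_truth)
  # a/1: left flank -> mapped at its own coordinates
  expect_true(aln$mapped[1]); expect_equal(aln$start[1], 100L)
  # a/2: inside the insertion -> unmapped, mate mapped at 100
  expect_false(aln$mapped[2])
  expect_true(aln$mate_mapped[2]); expect_equal(aln$mate_start[2], 100L)
  # b/1: right of the insertion -> mapped, shifted left by 200
  expect_true(aln$mapped[3]); expect_equal(aln$start[3], 1800L)
  # b/2: crosses the left breakpoint by >= 1 base -> unmapped
  expect_false(aln$mapped[4])
  # c/2: crosses the right breakpoint (1150 < 1200 < 1250) -> unmapped
  expect_false(aln$mapped[6])
  # c pair: both members flank/cross -> c/1 mapped with unmapped mate
  expect_true(aln$mapped[5]); expect_false(aln$mate_mapped[5])
})

test_that("a full dataset is reproducible from its seed", {
  cfg <- sim_config(reference_length = 20000, n_insertions = 2L,
                    length_range = c(50L, 100L), coverage = 5,
                    mean_insert = 500, sd_insert = 50,
                    min_separation = 2000L, seed = 8L)
  s1 <- simulate_insertion_dataset(cfg)
  s2 <- simulate_insertion_dataset(cfg)
  expect_identical(s1$donor, s2$donor)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$alignments, s2$alignments)
})
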