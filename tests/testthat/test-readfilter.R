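aln_row <- function(read_id, mapped, start = NA, end = NA,
                    mate_mapped = NA, mate_start = NA) {
  data.frame(read_id = read_id, mapped = mapped, start = start, end = end,
             mate_mapped = mate_mapped, mate_start = mate_start,
             stringsAsFactors = FALSE)
}

test_that("insert-size bounds are mu +/- z sigma rounded outward", {
  m <- insert_size_model(100, 1500, 150)
  expect_equal(insert_size_bounds(m), c(min = 1206L, max = 1794L))
  m2 <- insert_size_model(100, 500, 0)
  expect_equal(insert_size_bounds(m2), c(min = 500L, max = 500L))
  m3 <- insert_size_model(100, 150, 15)
  expect_equal(insert_size_bounds(m3), c(min = 120L, max = 180L))
  expect_warning(insert_size_model(100, 10, 50), "clamped")
})

test_that("the two-sided 95% normal multiplier is 1.96", {
  m <- insert_size_model(100, 1500, 150)
  expect_equal(round(m$z, 2), 1.96)
})

test_that("mate regions reproduce the S_left/S_right formulas", {
  m <- insert_size_model(100, 1500, 150)  # min 1206, max 1794
  r <- mate_regions(c(5000, 5100), m)
  expect_equal(r$left, c(lo = 3006L, hi = 3794L))
  expect_equal(r$right, c(lo = 6306L, hi = 6994L))

  m0 <- structure(list(read_length = 0L, mean_insert = 0, sd_insert = 0,
                       confidence = 0.95, z = 1.96, min_insert = 0L,
                       max_insert = 0L), class = "insert_size_model")
  r0 <- mate_regions(c(300, 400), m0)
  expect_equal(r0$left, c(lo = 300L, hi = 400L))
  expect_equal(r0$right, c(lo = 300L, hi = 400L))

  m3 <- insert_size_model(100, 150, 15)  # min 120, max 180
  r3 <- mate_regions(c(100, 200), m3)
  expect_true(r3$left["hi"] < r3$left["lo"])  # raw [-280..-20]: empty
  expect_equal(r3$right, c(lo = 320L, hi = 480L))
})

test_that("mate regions match an independent re-derivation on random draws", {
  for (i in 1:12) {
    set.seed(i)
    l <- sample(50:150, 1)
    mu <- sample(300:3000, 1)
    sigma <- sample(10:300, 1)
    s <- sample(2000:50000, 1)
    e <- s + sample(0:1000, 1)
    m <- suppressWarnings(insert_size_model(l, mu, sigma))
    z <- qnorm(0.975)
    mn <- max(0, floor(mu - z * sigma))  # bounds clamp at zero
    mx <- ceiling(mu + z * sigma)
    r <- mate_regions(c(s, e), m)
    expect_equal(unname(r$left), c(max(0, s - (mx + 2 * l)), e - (mn + l)))
    expect_equal(unname(r$right), c(s + (mn + l), e + (mx + l)))
  }
})

test_that("selection combines direct overlap and mate rescue", {
  m <- insert_size_model(100, 1500, 150)
  gap <- c(5000, 5100)  # S_left = [3006..3794]
  aln <- rbind(
    aln_row("direct/1", TRUE, 4950, 5050, TRUE, 6500),
    aln_row("rescued/2", FALSE, mate_mapped = TRUE, mate_start = 3100),
    aln_row("far/2", FALSE, mate_mapped = TRUE, mate_start = 100),
    aln_row("leftonly/1", TRUE, 1000, 1100, TRUE, 2400),
    aln_row("orphan/2", FALSE, mate_mapped = NA, mate_start = NA))
  f <- filter_reads(aln, gap, m)
  expect_setequal(f$selected_ids, c("direct/1", "rescued/2"))
  expect_equal(f$n_skipped_mate_info, 1L)
  expect_false(f$fallback_fired)
})

test_that("realized coverage is fold coverage over the padded region", {
  m <- insert_size_model(100, 1500, 150)
  aln <- rbind(aln_row("a/1", TRUE, 4950, 5050, FALSE, NA),
               aln_row("b/1", TRUE, 5010, 5110, FALSE, NA))
  f <- filter_reads(aln, c(5000, 5100), m)
  expect_equal(f$realized_coverage, 2 * 100 / (100 + 200))
})

test_that("the unmapped fallback fires only below the coverage threshold", {
  f <- structure(list(selected_ids = c("a"), selected_idx = 1L,
                      realized_coverage = 12, fallback_fired = FALSE),
                 class = "filter_result")
  out <- apply_unmapped_fallback(f, c("u1", "u2"), threshold = 25)
  expect_true(out$fallback_fired)
  expect_setequal(out$selected_ids, c("a", "u1", "u2"))

  f$realized_coverage <- 30
  out2 <- apply_unmapped_fallback(f, c("u1"), threshold = 25)
  expect_false(out2$fallback_fired)
  expect_equal(out2$selected_ids, "a")

  f$realized_coverage <- 0
  out3 <- apply_unmapped_fallback(f, c("u1"), threshold = 0)
  expect_false(out3$fallback_fired)  # zero threshold never fires
})

test_that("precision and recall follow the printed formulas with NA for empty denominators", {
  u <- sprintf("r%d", 1:20)
  expect_equal(precision_recall(u[1:5], u[1:5], u),
               c(precision = 1, recall = 1))
  expect_equal(precision_recall(u[1:10], u[1:8], u),
               c(precision = 0.8, recall = 1))
  pr <- precision_recall(character(0), u[1:3], u)
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
})

test_that("widening the confidence level never shrinks the selected set", {
  set.seed(5)
  aln <- do.call(rbind, lapply(1:200, function(i)
    aln_row(sprintf("u%d/2", i), FALSE, mate_mapped = TRUE,
            mate_start = sample(0:20000, 1))))
  gap <- c(9000, 9300)
  sel <- lapply(c(0.5, 0.8, 0.95, 0.99), function(conf) {
    m <- insert_size_model(100, 1500, 300, confidence = conf)
    filter_reads(aln, gap, m)$selected_ids
  })
  for (i in 2:4) expect_true(all(sel[[i - 1]] %in% sel[[i]]))
})
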