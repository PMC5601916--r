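# Peak-set algebra: rpm, filters, reciprocal overlap, dependency calls,
# correlation, venn counts.

test_that("rpm and RPTM arithmetic", {
  expect_equal(compute_rpm(200, 1e7), 20)
  expect_equal(compute_rpm(0, 1e7), 0)
  expect_equal(rptm(200, 1e7), 200) # RPTM = 10 x rpm
  expect_error(compute_rpm(10, 0), "library_size")
  expect_error(compute_rpm(-1, 1e6), "reads")
})

test_that("peak filter applies the rpm and fold-over-input gates", {
  peaks <- tibble::tibble(
    peak_id = c("keep", "low_over_input", "low_rpm"),
    chrom = "chr1", start = c(0, 1000, 2000), end = c(200, 1200, 2200),
    reads = c(25, 25, 10), input_reads = c(5, 10, 2)
  )
  cis <- cistrome(peaks, "X", "ctl", library_size = 1e7) # rpm 2.5, 2.5, 1.0
  # rpm 2.5 > 2 and 2.5 > 3 x 0.5 -> kept; 2.5 < 3 x 1.0 -> dropped
  kept <- filter_peaks(cis, min_rpm = 2, input_fold = 3)
  expect_equal(kept$peak_id, "keep")
  expect_error(filter_peaks(cis, min_rpm = -1), ">= 0")
})

test_that("random-cistrome filtering matches a brute-force oracle", {
  for (seed in 1:10) {
    cis <- rand_cistrome(80, seed = seed)
    kept <- filter_peaks(cis, min_rpm = 30, input_fold = 3)
    manual <- cis$peak_id[cis$rpm > 30 & cis$rpm > 3 * cis$input_rpm]
    expect_setequal(kept$peak_id, manual)
  }
})

test_that("overlap boundary cases follow the 50% / 1 rpm rule", {
  a <- cistrome(
    tibble::tibble(
      peak_id = c("a1", "a2"), chrom = "chr1",
      start = c(0, 1000), end = c(100, 1100),
      reads = c(30, 30), input_reads = 0
    ),
    "A", "ctl", 1e7
  )
  # b1 overlaps a1 by exactly 50 bp = 50% of a1; rpm 3 >= 1
  b <- cistrome(
    tibble::tibble(
      peak_id = c("b1", "b2"), chrom = "chr1",
      start = c(50, 1090), end = c(150, 1200),
      reads = c(30, 30), input_reads = 0
    ),
    "B", "ctl", 1e7
  )
  part <- overlap_cistromes(a, b, min_frac = 0.5, min_other_rpm = 1)
  expect_equal(part$a$class, c("co_bound", "a_only")) # a2 overlap 10/100 < 0.5
  expect_equal(venn_counts(part)$co_bound, 1)

  # the same geometry fails when the partner signal is below 1 rpm
  b_weak <- cistrome(
    tibble::tibble(
      peak_id = "b1", chrom = "chr1", start = 50, end = 150,
      reads = 5, input_reads = 0
    ),
    "B", "ctl", 1e7
  ) # 0.5 rpm
  part2 <- overlap_cistromes(a, b_weak, min_frac = 0.5, min_other_rpm = 1)
  expect_equal(part2$a$class, c("a_only", "a_only"))
})

test_that("overlap partition equals the O(n^2) all-pairs oracle", {
  for (seed in 1:8) {
    a <- rand_cistrome(120, seed = seed, factor_name = "A", chrom_len = 5e4)
    b <- rand_cistrome(120, seed = seed + 100, factor_name = "B", chrom_len = 5e4)
    part <- overlap_cistromes(a, b)
    oracle <- oracle_partition(as.data.frame(a), as.data.frame(b))
    expect_identical(part$a$class == "co_bound", oracle$co_a)
    expect_identical(part$b$class == "co_bound", oracle$co_b)
  }
})

test_that("overlap is symmetric and venn counts cover both inputs", {
  a <- rand_cistrome(60, seed = 21, factor_name = "A", chrom_len = 3e4)
  b <- rand_cistrome(60, seed = 22, factor_name = "B", chrom_len = 3e4)
  ab <- overlap_cistromes(a, b)
  ba <- overlap_cistromes(b, a)
  expect_identical(ab$a$class == "co_bound", ba$b$class == "co_bound")
  expect_identical(ab$b$class == "co_bound", ba$a$class == "co_bound")
  v <- venn_counts(ab)
  expect_equal(v$co_bound + v$a_only, nrow(a))
  expect_equal(sum(ab$b$class == "co_bound") + v$b_only, nrow(b))

  # disjoint and identical inputs
  far <- cistrome(
    tibble::tibble(
      peak_id = "z", chrom = "chr9", start = 0, end = 100,
      reads = 50, input_reads = 0
    ),
    "B", "ctl", 1e6
  )
  expect_equal(unlist(venn_counts(overlap_cistromes(a, far))), c(co_bound = 0, a_only = nrow(a), b_only = 1))
  self <- overlap_cistromes(a, a, min_other_rpm = 0)
  expect_equal(unlist(venn_counts(self)), c(co_bound = nrow(a), a_only = 0, b_only = 0))
})

test_that("scale invariance: scaling reads and library together changes nothing", {
  a <- rand_cistrome(50, seed = 31, factor_name = "A", chrom_len = 3e4)
  b <- rand_cistrome(50, seed = 32, factor_name = "B", chrom_len = 3e4)
  scale_cis <- function(x, k) {
    cistrome(
      dplyr::mutate(tibble::as_tibble(x)[setdiff(names(x), c("rpm", "input_rpm"))],
        reads = reads * k, input_reads = input_reads * k
      ),
      factor_name = attr(x, "factor_name"), condition = attr(x, "condition"),
      library_size = attr(x, "library_size") * k,
      input_library_size = attr(x, "input_library_size") * k
    )
  }
  a10 <- scale_cis(a, 10)
  b10 <- scale_cis(b, 10)
  expect_equal(a10$rpm, a$rpm)
  expect_identical(
    overlap_cistromes(a, b)$a$class,
    overlap_cistromes(a10, b10)$a$class
  )
  ko <- scale_cis(a, 1)
  ko$reads[1:25] <- ko$reads[1:25] %/% 5
  ko <- scale_cis(ko, 1) # recompute rpm
  expect_identical(
    classify_dependency(a, ko)$status,
    classify_dependency(a10, scale_cis(ko, 10))$status
  )
  expect_identical(
    filter_peaks(a, 30)$peak_id, filter_peaks(a10, 30)$peak_id
  )
})

test_that("dependency calls use the pseudocounted fold decrease", {
  mk <- function(rpm_vals, cond) {
    cistrome(
      tibble::tibble(
        peak_id = sprintf("p%d", seq_along(rpm_vals)), chrom = "chr1",
        start = seq_along(rpm_vals) * 1000, end = seq_along(rpm_vals) * 1000 + 200,
        reads = rpm_vals * 10, input_reads = 0
      ),
      "A", cond, 1e7
    )
  }
  ctl <- mk(c(4.0, 2.0, 2.0), "ctl")
  ko <- mk(c(1.5, 2.0, 0.95), "ko")
  dep <- classify_dependency(ctl, ko, fold = 2, pseudocount = 0.1)
  # (4.0 + 0.1)/(1.5 + 0.1) = 2.5625 -> lost
  expect_equal(dep$fold_decrease[1], 4.1 / 1.6)
  expect_equal(dep$status[1], "lost")
  # identical signal -> fold 1 -> unchanged
  expect_equal(dep$fold_decrease[2], 1)
  expect_equal(dep$status[2], "unchanged")
  # exactly twofold decrease counts as lost (inclusive bound)
  expect_equal(dep$fold_decrease[3], 2)
  expect_equal(dep$status[3], "lost")

  expect_error(classify_dependency(ctl, mk(c(1, 1), "ko")), "only one condition")
})

test_that("cistrome correlation matches the closed-form oracle", {
  a <- rand_cistrome(40, seed = 41, factor_name = "A", chrom_len = 1e5)
  expect_equal(correlate_cistromes(a, a)$r, 1)

  b <- rand_cistrome(40, seed = 42, factor_name = "B", chrom_len = 1e5)
  r <- correlate_cistromes(a, b)
  # recompute from scratch on the union interval signal
  union <- IRanges::reduce(IRanges::IRanges(
    c(a$start, b$start) + 1L, c(a$end, b$end)
  ))
  # (single-chromosome fixture keeps the oracle simple)
  a1 <- rand_cistrome(40, seed = 41, factor_name = "A", chrom_len = 1e5, chroms = "chr1")
  b1 <- rand_cistrome(40, seed = 43, factor_name = "B", chrom_len = 1e5, chroms = "chr1")
  u <- IRanges::reduce(IRanges::IRanges(c(a1$start, b1$start) + 1L, c(a1$end, b1$end)))
  sig <- function(x) {
    vapply(seq_along(u), function(i) {
      ov <- pmin(x$end, IRanges::end(u)[i]) - pmax(x$start, IRanges::start(u)[i] - 1L)
      sum(x$rpm[ov > 0])
    }, numeric(1))
  }
  expect_equal(correlate_cistromes(a1, b1)$r, oracle_pearson_r(sig(a1), sig(b1)),
    tolerance = 1e-12
  )
})

test_that("independent noise cistromes are uncorrelated", {
  # heavy-tailed peak heights, as in real ChIP: with near-constant heights
  # two sparse exclusive peak sets would anticorrelate by geometry alone
  mk <- function(seed, fac) {
    withr::with_seed(seed, {
      n <- 3000
      w <- sample(100:500, n, replace = TRUE)
      s <- sample.int(5e7 - 600, n, replace = TRUE)
      cistrome(
        tibble::tibble(
          peak_id = sprintf("%s%05d", fac, 1:n), chrom = "chr1",
          start = s, end = s + w,
          reads = round(rlnorm(n, log(40), 1.5)) + 1, input_reads = 1
        ),
        fac, "ctl", 1e6
      )
    })
  }
  expect_lt(abs(correlate_cistromes(mk(51, "A"), mk(52, "B"))$r), 0.1)
})

test_that("triple intersection reports class fractions with saturation limits", {
  a <- rand_cistrome(30, seed = 61, factor_name = "A", chrom_len = 1e5)
  b <- a
  attr(b, "factor_name") <- "B"
  part <- overlap_cistromes(a, b, min_other_rpm = 0)
  expect_error(triple_intersection(part, rand_cistrome(5, seed = 1, chroms = "chrZ")),
    NA
  ) # disjoint C is fine: fraction 0
  disjoint <- triple_intersection(part, rand_cistrome(5, seed = 1, chroms = "chrZ"))
  expect_equal(disjoint$fractions$fraction[disjoint$fractions$class == "co_bound"], 0)
  covering <- triple_intersection(part, a)
  expect_equal(covering$fractions$fraction[covering$fractions$class == "co_bound"], 1)
  expect_setequal(covering$triple_bound, a$peak_id)
})

test_that("ko-artifact filter drops knockout-persistent peaks", {
  ctl <- rand_cistrome(20, seed = 71)
  ko <- ctl
  ko$rpm[1:10] <- ctl$rpm[1:10] * 0.9 # persistent
  ko$rpm[11:20] <- ctl$rpm[11:20] * 0.1 # collapsed
  kept <- filter_ko_artifacts(ctl, ko, max_ko_ratio = 0.5)
  expect_setequal(kept$peak_id, ctl$peak_id[11:20])
})

test_that("unknown chromosome names are rejected with their names", {
  peaks <- tibble::tibble(
    peak_id = "p1", chrom = "chrUn", start = 0, end = 100,
    reads = 10, input_reads = 1
  )
  expect_error(
    cistrome(peaks, "A", "ctl", 1e6, genome = c(chr1 = 1e6)),
    "chrUn"
  )
})
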