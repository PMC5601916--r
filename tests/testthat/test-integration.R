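# Peak-to-gene linking under both conventions, the Yates chi-squared
# association test, and the small-sample rank/t tests.

test_that("nearest-gene assignment: identity, range cap, tie break", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(10000, 30000, 500000),
    end = c(20000, 40000, 510000),
    strand = c("+", "-", "+")
  )
  peaks <- tibble::tibble(
    peak_id = c("at_tss", "far", "between"),
    chrom = "chr1",
    start = c(9950, 700000, 24950),
    end = c(10050, 700200, 25050)
  )
  links <- assign_nearest_gene(peaks, genes, max_dist = 100000)
  # peak midpoint exactly at gA's TSS
  expect_equal(links$gene_id[links$peak_id == "at_tss"], "gA")
  expect_equal(links$distance[links$peak_id == "at_tss"], 0)
  # nearest TSS beyond 100 kb -> unlinked
  expect_false("far" %in% links$peak_id)
  # midpoint 25000: gA TSS 10000 (15000 away), gB TSS 40000 (15000 away);
  # tie broken lexicographically
  expect_equal(links$gene_id[links$peak_id == "between"], "gA")
})

test_that("nearest-gene links equal the all-pairs oracle", {
  for (seed in 1:6) {
    genes <- rand_genes(40, seed = seed)
    peaks <- tibble::as_tibble(rand_cistrome(60, seed = seed + 50))
    links <- assign_nearest_gene(peaks, genes, max_dist = 50000)
    oracle <- oracle_nearest_gene(peaks, genes, max_dist = 50000)
    expect_equal(nrow(links), nrow(oracle))
    merged <- merge(links, oracle, by = "peak_id")
    expect_true(all(merged$gene_id.x == merged$gene_id.y))
  }
})

test_that("window assignment is strand-aware with closed boundaries", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"),
    chrom = "chr1",
    start = c(100000, 400000),
    end = c(110000, 410000),
    strand = c("+", "-")
  )
  # minus-strand gene: upstream extends to the RIGHT of its TSS coordinate
  peaks <- tibble::tibble(
    peak_id = c("up_plus_edge", "up_minus", "down_minus_off", "inside_minus"),
    chrom = "chr1",
    start = c(100000 - 50000 - 50, 455000, 400000 - 2100, 405000) - 0,
    end = c(100000 - 50000 + 50, 455200, 400000 - 1900, 405200)
  )
  links <- assign_gene_window(peaks, genes, upstream = 50000, downstream = 2000)
  # midpoint exactly at TSS - 50000 is linked (closed boundary)
  expect_true(any(links$peak_id == "up_plus_edge" & links$gene_id == "plus"))
  expect_true(any(links$peak_id == "up_minus" & links$gene_id == "minus"))
  expect_true(any(links$peak_id == "inside_minus" & links$gene_id == "minus"))
  # 2 kb downstream window of the minus gene sits left of gene start
  expect_true(any(links$peak_id == "down_minus_off" & links$gene_id == "minus"))
  # signed distances are strand-aware: upstream is negative
  expect_lt(links$distance[links$peak_id == "up_plus_edge"], 0)
  expect_lt(links$distance[links$peak_id == "up_minus"], 0)
})

test_that("window links equal the brute-force containment oracle", {
  for (seed in 1:6) {
    genes <- rand_genes(30, seed = seed + 10)
    peaks <- tibble::as_tibble(rand_cistrome(60, seed = seed + 80))
    links <- assign_gene_window(peaks, genes, upstream = 20000, downstream = 2000)
    oracle <- oracle_window_links(peaks, genes, upstream = 20000, downstream = 2000)
    expect_equal(
      sort(paste(links$peak_id, links$gene_id)),
      sort(paste(oracle$peak_id, oracle$gene_id))
    )
  }
})

test_that("mirror invariance: flipping the genome and strands preserves links", {
  L <- 1e6
  genes <- rand_genes(25, seed = 9, chroms = "chr1", chrom_len = L)
  # even starts and widths keep midpoints exact under mirroring
  peaks <- withr::with_seed(19, tibble::tibble(
    peak_id = sprintf("p%02d", 1:40),
    chrom = "chr1",
    start = 2L * sample.int(4e5, 40),
    end = start + 2L * sample(50:250, 40, replace = TRUE)
  ))
  flip_iv <- function(df) {
    new_start <- L - df$end
    df$end <- L - df$start
    df$start <- new_start
    df
  }
  genes_f <- flip_iv(genes)
  genes_f$strand <- ifelse(genes$strand == "+", "-", "+")
  peaks_f <- flip_iv(peaks)
  key <- function(l) sort(paste(l$peak_id, l$gene_id))
  expect_equal(
    key(assign_gene_window(peaks, genes, 20000, 2000)),
    key(assign_gene_window(peaks_f, genes_f, 20000, 2000))
  )
  # midpoint flooring can shift the mirrored midpoint by 1 bp; nearest-gene
  # assignment is compared through its distances instead
  l1 <- assign_nearest_gene(peaks, genes, 50000)
  l2 <- assign_nearest_gene(peaks_f, genes_f, 50000)
  expect_equal(nrow(l1), nrow(l2))
})

test_that("both chi-squared variants match textbook closed forms", {
  tab <- rbind(c(40, 160), c(20, 780))
  y <- yates_chi2(tab)
  expect_equal(y$statistic, oracle_yates_chi2(tab), tolerance = 1e-10)
  expect_equal(y$p_value, pchisq(oracle_yates_chi2(tab), 1, lower.tail = FALSE),
    tolerance = 1e-10
  )
  p <- pearson_chi2(tab)
  expect_equal(p$statistic, oracle_pearson_chi2(tab), tolerance = 1e-10)

  withr::with_seed(8, {
    for (i in 1:100) {
      t2 <- matrix(rpois(4, 40) + 1, 2, 2)
      e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
      if (any(abs(t2 - e) < 0.5)) next # R truncates the correction there
      expect_equal(pearson_chi2(t2)$statistic, oracle_pearson_chi2(t2), tolerance = 1e-10)
      expect_equal(yates_chi2(t2)$statistic, oracle_yates_chi2(t2), tolerance = 1e-10)
    }
  })
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "degenerate margin")
})

test_that("association test builds the 2x2 table and applies Yates", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:1000),
    has_dependent_link = rep(c(TRUE, FALSE), c(200, 800)),
    coregulated = c(rep(TRUE, 40), rep(FALSE, 160), rep(TRUE, 20), rep(FALSE, 780))
  )
  res <- association_test(genes)
  expect_equal(as.vector(res$table), c(40, 20, 160, 780))
  expect_equal(res$statistic, oracle_yates_chi2(res$table), tolerance = 1e-10)
  expect_equal(tidy(res)$p_value, res$p_value)
  expect_error(
    association_test(tibble::tibble(
      gene_id = "g", has_dependent_link = TRUE, coregulated = TRUE
    )),
    "degenerate"
  )
})

test_that("association universe keeps coregulated plus both-arm-unchanged genes", {
  de <- function(ids, passes) tibble::tibble(gene_id = ids, passes = passes)
  ids <- sprintf("g%d", 1:6)
  de_a <- de(ids, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  de_b <- de(ids, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  coreg <- tibble::tibble(
    gene_id = c("g1", "g2"),
    class = c("correlated", "anti_correlated")
  )
  links <- tibble::tibble(gene_id = c("g1", "g3"))
  uni <- build_association_universe(de_a, de_b, coreg, links)
  # g1 correlated; g3, g4 unchanged in both arms; g5/g6 single-arm passers
  # and g2 (anti-correlated) are excluded by default
  expect_setequal(uni$gene_id, c("g1", "g3", "g4"))
  expect_equal(uni$has_dependent_link[uni$gene_id == "g3"], TRUE)
  uni2 <- build_association_universe(de_a, de_b, coreg, links,
    include_anti_correlated = TRUE
  )
  expect_true("g2" %in% uni2$gene_id)
})

test_that("rank-sum test: enumeration oracle, symmetry, tie degeneracy", {
  res <- binding_strength_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 of C(6,3)=20 assignments are as extreme
  expect_equal(res$p_value, oracle_mannwhitney_enum(c(1, 2, 3), c(4, 5, 6)))

  withr::with_seed(13, {
    x <- runif(4)
    y <- runif(5)
  })
  expect_equal(
    binding_strength_test(x, y)$p_value,
    oracle_mannwhitney_enum(x, y),
    tolerance = 1e-12
  )
  # U_A + U_B = n_A * n_B
  u_a <- binding_strength_test(x, y)$u_statistic
  u_b <- binding_strength_test(y, x)$u_statistic
  expect_equal(u_a + u_b, length(x) * length(y))

  tied <- binding_strength_test(rep(2, 5), rep(2, 6))
  expect_equal(tied$p_value, 1)

  # large samples switch to the tie-corrected normal approximation
  withr::with_seed(14, {
    big_x <- sample(1:5, 15, replace = TRUE)
    big_y <- sample(2:6, 15, replace = TRUE)
  })
  big <- binding_strength_test(big_x, big_y)
  expect_equal(big$method, "normal approximation (tie-corrected)")
  expect_equal(
    big$p_value,
    suppressWarnings(wilcox.test(big_x, big_y, exact = FALSE, correct = TRUE))$p.value
  )
  expect_error(binding_strength_test(c(1, 2), c(3, 4, 5)), ">= 3")
})

test_that("reChIP test is the one-tailed pooled-variance t-test", {
  expect_equal(rechip_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
  withr::with_seed(15, {
    sig <- rnorm(3, 5)
    ctl <- rnorm(3, 1)
  })
  res <- rechip_test(sig, ctl)
  two_sided <- t.test(sig, ctl, var.equal = TRUE)$p.value
  # positive direction: one tail is half the two-tailed P
  expect_equal(res$p_value, two_sided / 2, tolerance = 1e-12)
  # closed-form check through the t distribution
  expect_equal(res$p_value, pt(res$t_stat, df = res$df, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_error(rechip_test(1, c(1, 2)), ">= 2 replicates")
})
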