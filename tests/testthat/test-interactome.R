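# Interactome scoring chain: digestion, iBAQ, normalisation, imputation,
# enrichment testing, gates, nuclease classes.

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  # no cleavage after R when followed by P
  expect_equal(
    digest_protein("AAAAAAKRPAAAAAA", min_len = 6, max_len = 30),
    c("AAAAAAK", "RPAAAAAA")
  )
  # a chain without K/R is one peptide if it fits the window
  expect_equal(digest_protein("AAAAAAAA", min_len = 6, max_len = 30), "AAAAAAAA")
  expect_length(digest_protein("AAAA", min_len = 6, max_len = 30), 0)
  # length window is applied after cleavage
  expect_equal(
    digest_protein("AAKCCCCCCCCKDD", min_len = 4, max_len = 12),
    "CCCCCCCCK"
  )
  expect_error(digest_protein("AAAKBB", min_len = 2, max_len = 30), "B")
  expect_error(digest_protein(""), "non-empty")
})

test_that("theoretical peptide counts match per-protein digestion", {
  prots <- c(p1 = "AAAAAAKRPAAAAAA", p2 = "CCCCCCCCCC")
  counts <- theoretical_peptide_counts(prots, min_len = 6, max_len = 30)
  expect_equal(counts$n_theoretical, c(2L, 1L))
})

test_that("iBAQ is summed intensity over theoretical peptide count", {
  pep <- tibble::tibble(
    protein_id = c("p1", "p1", "p2"),
    peptide = c("AAAAAAK", "RPAAAAAA", "CCCCCCK"),
    sample_id = "s1", condition = "bait", nuclease = "none",
    intensity = c(6e8, 4e8, NA)
  )
  digests <- tibble::tibble(protein_id = c("p1", "p2"), n_theoretical = c(10L, 5L))
  q <- compute_ibaq(pep, digests)
  expect_equal(q$values["p1", "s1"], 1e8)
  # no observed peptide -> missing cell
  expect_true(is.na(q$values["p2", "s1"]))
  expect_error(
    compute_ibaq(pep, tibble::tibble(protein_id = c("p1", "p2"), n_theoretical = c(10L, 0L))),
    "digest count of 0"
  )
})

test_that("iBAQ matches a brute-force group-sum oracle on random tables", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n_prot <- sample(3:8, 1)
      n_samp <- sample(2:5, 1)
      grid <- expand.grid(
        protein_id = sprintf("p%d", seq_len(n_prot)),
        sample_id = sprintf("s%d", seq_len(n_samp)),
        pep = 1:3, stringsAsFactors = FALSE
      )
      pep <- tibble::tibble(
        protein_id = grid$protein_id,
        peptide = sprintf("PEP%s%d", grid$protein_id, grid$pep),
        sample_id = grid$sample_id,
        condition = "bait", nuclease = "none",
        intensity = ifelse(runif(nrow(grid)) < 0.3, NA, exp(rnorm(nrow(grid), 12)))
      )
      digests <- tibble::tibble(
        protein_id = sprintf("p%d", seq_len(n_prot)),
        n_theoretical = sample(1:20, n_prot, replace = TRUE)
      )
      q <- compute_ibaq(pep, digests)
      o <- oracle_ibaq(pep, digests)
      expect_equal(q$values[rownames(o), colnames(o)], o, tolerance = 1e-6)
    })
  }
})

test_that("median normalisation centres every sample's observed values at zero", {
  v <- matrix(c(2, 8, 4, NA), 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  q <- tiny_quant(v, conditions = c("bait", "control"), stage = "raw_ibaq")
  norm <- log2_median_normalize(q)
  expect_equal(unname(norm$values[, "s1"]), c(-1, 1))
  # all-equal sample maps to all zeros
  expect_equal(unname(norm$values["p1", "s2"]), 0)
  meds <- apply(norm$values, 2, median, na.rm = TRUE)
  expect_true(all(abs(meds) < 1e-9))

  v2 <- matrix(c(2, 4, NA, NA), 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  q2 <- tiny_quant(v2, conditions = c("bait", "control"), stage = "raw_ibaq")
  expect_error(log2_median_normalize(q2), "zero observed")
})

test_that("downshifted-Gaussian imputation has the stated location and spread", {
  withr::with_seed(1, {
    v <- matrix(rnorm(400, 0, 1), 100, 4,
      dimnames = list(sprintf("p%d", 1:100), sprintf("s%d", 1:4))
    )
    v[sample(length(v), 120)] <- NA
  })
  q <- tiny_quant(v, conditions = c("bait", "bait", "control", "control"),
    stage = "log2_median"
  )
  # width 0: every imputed cell sits exactly at mu - 2 sigma of its sample
  det <- impute_missing(q, width = 0, downshift = 2, seed = 5)
  for (j in 1:4) {
    mu <- mean(v[, j], na.rm = TRUE)
    sigma <- sd(v[, j], na.rm = TRUE)
    imputed <- det$values[is.na(v[, j]), j]
    expect_equal(unname(imputed), rep(mu - 2 * sigma, length(imputed)))
  }
  # seeded determinism
  expect_identical(
    impute_missing(q, seed = 7)$values,
    impute_missing(q, seed = 7)$values
  )
  expect_false(identical(
    impute_missing(q, seed = 7)$values,
    impute_missing(q, seed = 8)$values
  ))
  # observed cells never change
  imp <- impute_missing(q, seed = 7)
  expect_identical(imp$values[!is.na(v)], v[!is.na(v)])
})

test_that("imputed values have mean mu - downshift*sigma at large n", {
  withr::with_seed(2, {
    v <- matrix(rnorm(2.5e5, 10, 2), ncol = 2)
  })
  v[1:1e5, 1] <- NA # many missing cells in sample 1
  dimnames(v) <- list(sprintf("p%d", seq_len(nrow(v))), c("s1", "s2"))
  q <- tiny_quant(v, conditions = c("bait", "control"), stage = "log2_median")
  imp <- impute_missing(q, width = 0.25, downshift = 2, seed = 3)
  mu <- mean(v[, 1], na.rm = TRUE)
  sigma <- sd(v[, 1], na.rm = TRUE)
  drawn <- imp$values[is.na(v[, 1]), 1]
  se <- 0.25 * sigma / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - (mu - 2 * sigma)), 3 * se)
  expect_equal(sd(drawn), 0.25 * sigma, tolerance = 0.02)
})

test_that("imputation refuses samples where sigma is undefined", {
  v <- matrix(c(1, NA, NA, 1, 2, 3), 3, 2,
    dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))
  )
  q <- tiny_quant(v, conditions = c("bait", "control"), stage = "log2_median")
  expect_error(impute_missing(q), "s1")
})

test_that("enrichment t-test equals the pooled-variance t-test oracle", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      nb <- sample(2:6, 1)
      nc <- sample(2:6, 1)
      v <- matrix(rnorm(20 * (nb + nc)), 20,
        dimnames = list(
          sprintf("p%d", 1:20),
          sprintf("s%d", seq_len(nb + nc))
        )
      )
    })
    q <- tiny_quant(v, conditions = rep(c("bait", "control"), c(nb, nc)))
    res <- test_enrichment(q, "none")
    for (i in c(1, 7, 20)) {
      expect_equal(
        res$p_value[i],
        oracle_pooled_t_p(v[i, seq_len(nb)], v[i, nb + seq_len(nc)]),
        tolerance = 1e-10
      )
    }
    expect_equal(res$adj_p, p.adjust(res$p_value, "BH"))
  }
})

test_that("degenerate enrichment inputs give the null identity", {
  v <- matrix(c(3, 3, 3, 3, 3, 3), 1, 6,
    dimnames = list("p1", sprintf("s%d", 1:6))
  )
  q <- tiny_quant(v, conditions = rep(c("bait", "control"), each = 3))
  res <- test_enrichment(q, "none")
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)

  # clear separation: enrichment equals the mean difference
  v2 <- rbind(p1 = c(3, 3, 3, 0, 0, 0) + c(1e-9, -1e-9, 0, 1e-9, -1e-9, 0))
  colnames(v2) <- sprintf("s%d", 1:6)
  q2 <- tiny_quant(v2, conditions = rep(c("bait", "control"), each = 3))
  expect_equal(test_enrichment(q2, "none")$log2_enrichment, 3, tolerance = 1e-8)

  expect_error(
    test_enrichment(tiny_quant(v, conditions = c("bait", rep("control", 5))), "none"),
    ">= 2 samples"
  )
})

test_that("interactor gate behaves exactly at the 10-fold / P 0.01 boundary", {
  res <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    log2_enrichment = c(3.33, 3.33, log2(10), 3.31),
    p_value = c(0.005, 0.02, 0.009, 0.005)
  )
  called <- call_interactors(res, fold_cutoff = 10, p_cutoff = 0.01)
  # 3.33 >= log2(10) ~ 3.3219 with P below the gate
  expect_true(called$is_interactor[1])
  # P gate fails
  expect_false(called$is_interactor[2])
  # exactly log2(10) is an interactor (inclusive fold bound, exclusive P bound)
  expect_true(called$is_interactor[3])
  expect_false(called$is_interactor[4])
  expect_error(call_interactors(res, fold_cutoff = -1), "fold_cutoff")
})

test_that("nuclease classification separates direct from DNA-bridged", {
  untreated <- call_interactors(tibble::tibble(
    protein_id = c("direct1", "bridged1", "lost_in_treated"),
    log2_enrichment = log2(16),
    p_value = 0.001
  ))
  benzo <- tibble::tibble(
    protein_id = c("direct1", "bridged1"),
    log2_enrichment = c(log2(12), log2(2))
  )
  cls <- classify_nuclease_sensitivity(untreated, benzo)
  expect_equal(
    cls$nuclease_class[match(c("direct1", "bridged1", "lost_in_treated"), cls$protein_id)],
    c("direct", "dna_bridged", "indeterminate")
  )
})

test_that("effect monotonicity: stronger spikes never call fewer true interactors", {
  calls <- sapply(c(2, 4, 16), function(eff) {
    cfg <- small_sim_config(seed = 42, interactor_effect = eff)
    sim <- simulate_proteomics(cfg)
    dig <- theoretical_peptide_counts(sim$proteins)
    q <- impute_missing(log2_median_normalize(compute_ibaq(sim$peptides, dig)), seed = 1)
    res <- call_interactors(test_enrichment(q, "none"))
    sum(res$is_interactor & res$protein_id %in% sim$truth$true_interactors)
  })
  expect_true(all(diff(calls) >= 0))
})

test_that("low-detection proteins are flagged, not dropped", {
  v <- matrix(rnorm(24), 4, 6, dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:6)))
  obs <- matrix(TRUE, 4, 6)
  obs[1, ] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE) # < 50% both arms
  samples <- tibble::tibble(
    sample_id = colnames(v),
    condition = rep(c("bait", "control"), each = 3), nuclease = "none"
  )
  q <- protein_quant(v, samples, stage = "imputed", observed = obs)
  res <- test_enrichment(q, "none")
  expect_equal(nrow(res), 4)
  expect_true(res$low_detection[1])
  expect_false(any(res$low_detection[-1]))
})
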