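# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, base-R tests, and closed-form formulas.

oracle_ibaq <- function(peptides, digests) {
  prot <- unique(peptides$protein_id)
  samp <- sort(unique(peptides$sample_id))
  out <- matrix(NA_real_, length(prot), length(samp), dimnames = list(prot, samp))
  for (p in prot) {
    denom <- digests$n_theoretical[digests$protein_id == p]
    for (s in samp) {
      v <- peptides$intensity[peptides$protein_id == p & peptides$sample_id == s]
      v <- v[!is.na(v)]
      if (length(v)) out[p, s] <- sum(v) / denom
    }
  }
  out
}

oracle_pooled_t_p <- function(x, y) {
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

oracle_welch_t_p <- function(x, y) {
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

oracle_pearson_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# textbook Yates formula; only valid against R's variant when |O - E| >= 0.5
oracle_yates_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - e) - 0.5)^2 / e)
}

oracle_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exact two-sided Mann-Whitney P by full enumeration of group assignments
oracle_mannwhitney_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(k))
  all_u <- apply(utils::combn(n, k), 2, u_of)
  mu <- k * (n - k) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# O(n^2) all-pairs overlap partition
oracle_partition <- function(a, b, min_frac = 0.5, min_other_rpm = 1) {
  co_a <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov <= 0) next
      if (ov / (a$end[i] - a$start[i]) >= min_frac && b$rpm[j] >= min_other_rpm) {
        co_a[i] <- TRUE
      }
    }
  }
  co_b <- logical(nrow(b))
  for (j in seq_len(nrow(b))) {
    for (i in seq_len(nrow(a))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov <= 0) next
      if (ov / (b$end[j] - b$start[j]) >= min_frac && a$rpm[i] >= min_other_rpm) {
        co_b[j] <- TRUE
      }
    }
  }
  list(co_a = co_a, co_b = co_b)
}

oracle_nearest_gene <- function(peaks, genes, max_dist = 100000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      tss <- if (genes$strand[j] == "-") genes$end[j] else genes$start[j]
      d <- abs(mid - tss)
      if (d > max_dist) next
      if (is.null(best) || d < best$d ||
        (d == best$d && genes$gene_id[j] < best$gene_id)) {
        best <- list(d = d, gene_id = genes$gene_id[j])
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(
        peak_id = peaks$peak_id[i], gene_id = best$gene_id
      )
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), gene_id = character()))
  }
  do.call(rbind, out)
}

oracle_window_links <- function(peaks, genes, upstream = 50000, downstream = 2000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      if (genes$strand[j] == "-") {
        lo <- genes$start[j] - downstream
        hi <- genes$end[j] + upstream
      } else {
        lo <- genes$start[j] - upstream
        hi <- genes$end[j] + downstream
      }
      if (mid >= lo && mid <= hi) {
        out[[length(out) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j]
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(), gene_id = character()))
  }
  do.call(rbind, out)
}

# brute-force best log-odds PWM score over all offsets and both strands
oracle_scan_best <- function(window, pw) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_one <- function(chars) {
    L <- ncol(pw$logodds)
    best <- -Inf
    if (length(chars) < L) {
      return(best)
    }
    for (off in seq_len(length(chars) - L + 1)) {
      s <- 0
      for (k in seq_len(L)) {
        ch <- chars[off + k - 1]
        s <- s + if (ch %in% c("A", "C", "G", "T")) pw$logodds[ch, k] else -Inf
      }
      best <- max(best, s)
    }
    best
  }
  chars <- strsplit(toupper(window), "")[[1]]
  rc <- rev(unname(comp[chars]))
  max(score_one(chars), score_one(rc))
}
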