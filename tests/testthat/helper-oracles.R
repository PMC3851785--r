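# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exhaustive affine-gap Smith-Waterman (Gotoh), gap of length k costs
# gap_open + k * gap_extend; returns the maximal local score
dp_local_score <- function(q, s, mat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1, n + 1); E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - (gap_open + gap_extend),
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - (gap_open + gap_extend),
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# raw alignment score back-computed from the reported e-value
raw_score_from_evalue <- function(e_value, m, n, scheme) {
  -log(e_value / (scheme$karlin_k * m * n)) / scheme$karlin_lambda
}

# closed-form one-way ANOVA + Tukey-Kramer HSD from sums of squares and the
# studentized range distribution
anova_tukey_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_b <- sum(ni * (mi - grand)^2)
  ss_w <- sum((values - mi[groups])^2)
  df_w <- N - k
  mse <- ss_w / df_w
  f <- (ss_b / (k - 1)) / mse
  p_overall <- stats::pf(f, k - 1, df_w, lower.tail = FALSE)
  combs <- utils::combn(levels(groups), 2)
  p_adj <- apply(combs, 2, function(pair) {
    i <- pair[1]; j <- pair[2]
    qstat <- abs(mi[i] - mi[j]) / sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    stats::ptukey(qstat, k, df_w, lower.tail = FALSE)
  })
  list(p_overall = p_overall,
       pairs = data.frame(group_i = combs[2, ], group_j = combs[1, ],
                          p_adj = p_adj, stringsAsFactors = FALSE))
}

# truth-vs-report ortholog metrics for a simulated pair
pair_recovery_stats <- function(sim, map) {
  ta <- sim$a$truth; tb <- sim$b$truth
  tp <- merge(ta[ta$fate == "intact", c("ancestor_id", "locus_tag")],
              tb[tb$fate == "intact", c("ancestor_id", "locus_tag")],
              by = "ancestor_id")
  key_true <- paste(tp$locus_tag.x, tp$locus_tag.y)
  key_got <- paste(map$pairs$query_id, map$pairs$subject_id)
  list(recovery = mean(key_true %in% key_got),
       false_rate = if (length(key_got)) mean(!key_got %in% key_true) else 0)
}

# pseudogene sensitivity/specificity of a comparative report against truth
pseudogene_truth_stats <- function(sim, rep, min_disruptions = 2) {
  sens_num <- 0L; sens_den <- 0L
  fp <- 0L; tn_den <- 0L
  for (strain in c("a", "b")) {
    other <- if (strain == "a") "b" else "a"
    tt <- sim[[strain]]$truth; to <- sim[[other]]$truth
    calls <- rep[[paste0("pseudogenes_", strain)]]
    centers <- vapply(calls, `[[`, numeric(1), "locus_center")
    ps <- which(tt$fate == "pseudogene" & to$fate == "intact")
    for (i in ps) {
      if (tt$n_disruptions[i] < min_disruptions) next
      sens_den <- sens_den + 1L
      hit <- length(centers) &&
        any(centers >= tt$start[i] - 2000 & centers <= tt$end[i] + 2000)
      sens_num <- sens_num + as.integer(hit)
    }
    # specificity over never-coding regions: intergenic regions of this
    # strain containing no true pseudogene span
    regions <- rep[[paste0("regions_", strain)]]
    all_ps <- tt[tt$fate == "pseudogene", , drop = FALSE]
    never <- vapply(seq_len(nrow(regions)), function(r) {
      !any(all_ps$start < regions$end[r] & all_ps$end > regions$start[r])
    }, logical(1))
    called_regions <- vapply(calls, function(x) x$region$region_id, character(1))
    tn_den <- tn_den + sum(never)
    fp <- fp + sum(regions$region_id[never] %in% called_regions)
  }
  list(sensitivity = if (sens_den) sens_num / sens_den else NA_real_,
       specificity = if (tn_den) 1 - fp / tn_den else NA_real_,
       n_eval = sens_den)
}
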