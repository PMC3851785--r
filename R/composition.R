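# Nucleotide-composition analytics: GC, GC2, GC4 (fourfold-degenerate third
# positions), relative synonymous codon usage (RSCU), the codon adaptation
# index (CAI, Sharp & Li convention with a 0.5 pseudo-count), and the group
# statistics used to classify GC strata and validate composition-based
# contig bins (one-way ANOVA via stats::aov followed by Tukey HSD).

#' GC content of sequences
#'
#' `N` counts as non-GC (denominator includes all bases).
#'
#' @param seq character vector of DNA strings.
#' @return percent G+C per sequence.
#' @export
gc_percent <- function(seq) {
  vapply(seq, function(s) 100 * gc_count(s) / nchar(s), numeric(1),
         USE.NAMES = FALSE)
}

check_inframe <- function(cds) {
  if (any(nchar(cds) %% 3L != 0L))
    stop("CDS length must be divisible by 3 for codon-position statistics")
}

#' GC at second codon positions
#'
#' @param cds in-frame CDS strings (length divisible by 3).
#' @return percent G+C at codon position 2.
#' @export
gc2 <- function(cds) {
  check_inframe(cds)
  vapply(cds, function(s) {
    p2 <- substring(s, seq(2L, nchar(s), 3L), seq(2L, nchar(s), 3L))
    100 * sum(p2 %in% c("G", "C", "g", "c")) / length(p2)
  }, numeric(1), USE.NAMES = FALSE)
}

FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' GC at synonymous third positions
#'
#' By default restricted to third positions of the eight fourfold-degenerate
#' codon families (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN) — the standard
#' GC4 definition. With `fourfold_only = FALSE` all third positions are used
#' (GC3).
#'
#' @param cds in-frame CDS strings.
#' @param fourfold_only restrict to fourfold-degenerate families.
#' @return percent G+C; `NaN` when a gene has no qualifying codon.
#' @export
gc4 <- function(cds, fourfold_only = TRUE) {
  check_inframe(cds)
  vapply(cds, function(s) {
    cods <- toupper(split_codons(s))
    if (fourfold_only) cods <- cods[substring(cods, 1L, 2L) %in% FOURFOLD_PREFIXES]
    if (!length(cods)) return(NaN)
    third <- substring(cods, 3L, 3L)
    100 * sum(third %in% c("G", "C")) / length(third)
  }, numeric(1), USE.NAMES = FALSE)
}

# synonymous families of the standard code, stops excluded
synonymous_families <- function() {
  aa <- codon2aa()
  aa <- aa[aa != "*"]
  split(names(aa), unname(aa))
}

#' Reference codon-usage table: counts, RSCU and relative adaptiveness
#'
#' RSCU of a codon is its count divided by the mean count within its
#' synonymous family; relative adaptiveness `w` is RSCU divided by the
#' family maximum (so the best codon of every family has `w = 1`).
#' Zero-count codons receive a 0.5 pseudo-count before RSCU so that rare
#' codons absent from a small reference set do not zero out downstream CAI
#' values. Stop codons are excluded.
#'
#' @param genes character vector of in-frame reference CDS strings.
#' @param pseudo_count value substituted for zero counts (default 0.5).
#' @return object of class `codon_usage_table`: data.frame
#'   `codon, aa, count, rscu, w`.
#' @export
rscu <- function(genes, pseudo_count = 0.5) {
  if (!length(genes)) stop("empty reference gene set")
  check_inframe(genes)
  cods <- toupper(unlist(lapply(genes, split_codons), use.names = FALSE))
  fam <- synonymous_families()
  all_codons <- unlist(fam, use.names = FALSE)
  counts <- table(factor(cods, levels = all_codons))
  out <- data.frame(codon = all_codons,
                    aa = rep(names(fam), lengths(fam)),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  eff <- ifelse(out$count == 0L, pseudo_count, out$count)
  out$rscu <- NA_real_; out$w <- NA_real_
  for (a in names(fam)) {
    i <- out$aa == a
    out$rscu[i] <- eff[i] / mean(eff[i])
    out$w[i] <- out$rscu[i] / max(out$rscu[i])
  }
  structure(out, class = c("codon_usage_table", "data.frame"))
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the reference relative adaptiveness values (`w`) over
#' the gene's codons, excluding ATG, TGG and stop codons (the Sharp & Li
#' convention: codons with no synonymous alternative carry no information).
#'
#' @param cds in-frame CDS string.
#' @param table a `codon_usage_table` from [rscu()].
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(cds, table) {
  check_inframe(cds)
  cods <- toupper(split_codons(cds))
  cods <- cods[!cods %in% c("ATG", "TGG", "TAA", "TAG", "TGA")]
  w <- table$w[match(cods, table$codon)]
  w <- w[!is.na(w)] # ambiguous codons carry no information
  if (!length(w)) return(NA_real_)
  exp(mean(log(w)))
}

#' Per-ORF composition profile
#'
#' @param cds named character vector of in-frame CDS strings.
#' @param ref_table reference `codon_usage_table` for CAI (optional).
#' @param group group label column value (recycled).
#' @return data.frame `id, group, gc, gc2, gc4, cai`.
#' @export
composition_profile <- function(cds, ref_table = NULL, group = NA_character_) {
  data.frame(id = names(cds) %||% seq_along(cds), group = group,
             gc = gc_percent(cds), gc2 = gc2(cds), gc4 = gc4(cds),
             cai = if (is.null(ref_table)) NA_real_
                   else vapply(cds, cai, numeric(1), table = ref_table,
                               USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Group statistics

#' One-way ANOVA followed by Tukey HSD
#'
#' Fixed-effects one-way ANOVA (`stats::aov`) with Tukey honest significant
#' difference post-hoc comparisons via the studentized range distribution
#' (`stats::TukeyHSD`), exactly the classical R behavior. Degenerate inputs
#' (fewer than two groups, singleton groups, zero pooled variance) are an
#' error, never a silent p of 0.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return list with `p_overall` and `tukey` (data.frame
#'   `group_i, group_j, diff, lwr, upr, p_adj`).
#' @export
group_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  keep <- !is.na(values) & !is.nan(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least two groups")
  n_per <- table(groups)
  if (any(n_per < 2L))
    stop("each group needs at least two values (offending: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), ")")
  gm <- tapply(values, groups, mean)
  ss_w <- sum((values - gm[groups])^2)
  if (!is.finite(ss_w) || ss_w <= max(abs(values), 1)^2 * 1e-18)
    stop("degenerate (zero) pooled within-group variance")
  fit <- stats::aov(values ~ groups)
  p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group_i = vapply(nm, `[`, "", 1),
                      group_j = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(p_overall = p_overall, tukey = tukey)
}

#' Two-stage GC stratification of genome compartments
#'
#' Mirrors the two-stage procedure used for GC strata: per-category, the two
#' strains' groups are compared first and merged when not significantly
#' different (pseudogenes are always merged across strains — each strain
#' alone has too few); ANOVA + Tukey HSD is then rerun on the merged groups.
#'
#' @param gc numeric GC values.
#' @param category compartment label per value (e.g. `coding`, `intergenic`,
#'   `pseudogene`, `RNA`).
#' @param strain strain label per value.
#' @param alpha significance level for the merge decision.
#' @return list `groups` (merged label per value), `p_overall`, `tukey`.
#' @export
classify_gc_strata <- function(gc, category, strain, alpha = 0.05) {
  category <- as.character(category); strain <- as.character(strain)
  stopifnot(length(gc) == length(category), length(gc) == length(strain))
  merged <- character(length(gc))
  for (cat in unique(category)) {
    i <- category == cat
    strains <- unique(strain[i])
    merge_it <- cat == "pseudogene" || length(strains) < 2L
    if (!merge_it) {
      res <- tryCatch(group_anova_tukey(gc[i], strain[i]), error = function(e) NULL)
      merge_it <- is.null(res) || res$p_overall > alpha
    }
    merged[i] <- if (merge_it) cat else paste(cat, strain[i], sep = ".")
  }
  res <- group_anova_tukey(gc, merged)
  list(groups = merged, p_overall = res$p_overall, tukey = res$tukey)
}

#' Composition-based contig screen
#'
#' For each of the four per-ORF metrics (GC, GC2, GC4, CAI), runs ANOVA +
#' Tukey HSD across contigs; a contig is an outlier when it differs from at
#' least one other contig (Tukey-adjusted p below `alpha`) on any metric.
#' Because both members of every significant pair trivially satisfy that
#' reading, the reported outlier set is the minimal (greedy) set of contigs
#' that covers all significant pairs — the contigs whose removal leaves no
#' significant comparison, mirroring how a single composition-shifted
#' contig is singled out against an otherwise homogeneous bin.
#'
#' @param profiles data.frame with columns `contig, gc, gc2, gc4, cai`
#'   (one row per ORF); see [composition_profile()].
#' @param alpha significance level (default 0.05).
#' @return list `outliers` (contig ids), `pairwise` (per-metric Tukey
#'   tables), `p_overall` (per-metric ANOVA p).
#' @export
contig_screen <- function(profiles, alpha = 0.05) {
  contigs <- unique(as.character(profiles$contig))
  metrics <- intersect(c("gc", "gc2", "gc4", "cai"), names(profiles))
  if (length(contigs) < 2L)
    return(list(outliers = character(0), pairwise = list(), p_overall = numeric(0)))
  pairwise <- list(); p_overall <- numeric(0)
  sig_pairs <- data.frame(group_i = character(0), group_j = character(0))
  for (m in metrics) {
    v <- profiles[[m]]
    if (all(is.na(v))) next
    res <- group_anova_tukey(v, profiles$contig)
    pairwise[[m]] <- res$tukey
    p_overall[m] <- res$p_overall
    sig <- res$tukey[res$tukey$p_adj < alpha, c("group_i", "group_j")]
    sig_pairs <- unique(rbind(sig_pairs, sig))
  }
  # greedy vertex cover of the significant-pair graph
  flagged <- character(0)
  while (nrow(sig_pairs)) {
    tallies <- sort(table(c(sig_pairs$group_i, sig_pairs$group_j)),
                    decreasing = TRUE)
    top <- names(tallies)[1]
    flagged <- c(flagged, top)
    sig_pairs <- sig_pairs[sig_pairs$group_i != top & sig_pairs$group_j != top, ,
                           drop = FALSE]
  }
  list(outliers = sort(flagged), pairwise = pairwise, p_overall = p_overall)
}

# ---------------------------------------------------------------------------
# Genome summary arithmetic

#' Coding density of a genome
#'
#' 100 x (union length of the selected features) / genome length;
#' overlapping features are counted once.
#'
#' @param g a [genome_record].
#' @param definition `"cds-only"` (default) or `"all-genes"` (includes RNA
#'   genes and pseudo-typed features).
#' @return percent of the genome covered.
#' @export
coding_density <- function(g, definition = c("cds-only", "all-genes")) {
  definition <- match.arg(definition)
  f <- g$features
  if (definition == "cds-only") f <- f[f$kind == "CDS", , drop = FALSE]
  if (!nrow(f)) return(0)
  len <- length(g)
  s <- f$start; e <- pmin(f$end, len)
  s2 <- rep(0L, sum(f$end > len)); e2 <- f$end[f$end > len] - len
  ir <- IRanges::reduce(IRanges::IRanges(start = c(s, s2) + 1L, end = c(e, e2)))
  100 * sum(IRanges::width(ir)) / len
}

#' Variant rate from assembly validation
#'
#' @param n_variants variant site count.
#' @param genome_length bases.
#' @return percent, `100 * n / length`.
#' @export
variant_rate <- function(n_variants, genome_length) {
  100 * n_variants / genome_length
}
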