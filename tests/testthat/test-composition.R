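# GC metrics, RSCU/CAI, ANOVA + Tukey HSD and the derived screens.

test_that("GC, GC2 and GC4 follow their positional definitions", {
  expect_equal(gc_percent("ATGC"), 50.0)
  expect_equal(gc_percent("ANNN"), 25 * 0)     # N counts as non-GC
  expect_equal(gc2("ATGAAA"), 0.0)             # positions 2: T, A
  expect_equal(gc2("ATTGCA"), 100 * 1 / 2) # positions 2: T, C
  expect_equal(gc4("GCTGCG"), 50.0)            # two GCN codons, thirds T and G
  expect_equal(gc4("ATGAAA"), NaN)             # no fourfold codon
  expect_equal(gc4("ATGAAA", fourfold_only = FALSE), 100 * 1 / 2) # GC3: G, A
  expect_error(gc2("ATGA"), "divisible")
  expect_error(gc4("ATGA"), "divisible")
})

test_that("gc2/gc4 agree between a CDS and its annotated-strand extraction", {
  set.seed(41)
  cds <- random_dna(300)
  g <- genome_record("g", paste0("AAAA", ratchet:::rc_chr(cds), "TTTT"),
                     "linear", data.frame(
    locus_tag = "m1", start = 4L, end = 304L, strand = "-", kind = "CDS",
    product = "", translation = "", wraps = FALSE))
  back <- feature_seq(g, g$features[1, ])
  expect_equal(back, cds)
  expect_equal(gc2(back), gc2(cds))
  expect_equal(gc4(back), gc4(cds))
})

test_that("RSCU and CAI match closed-form hand calculations", {
  # uniform usage within every family -> all RSCU = w = 1, CAI = 1
  fam <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  fam <- fam[names(fam) != "*"]
  uniform_gene <- paste(unlist(fam), collapse = "")
  tab <- rscu(uniform_gene)
  expect_true(all(abs(tab$rscu - 1) < 1e-12))
  expect_true(all(abs(tab$w - 1) < 1e-12))
  expect_equal(cai("GCTGCAGCGGCC", tab), 1.0)

  # two-codon family with counts 30/10 -> RSCU 1.5/0.5, w 1/(1/3)
  ref <- c(strrep("AAA", 30), strrep("AAG", 10))
  tab2 <- rscu(ref)
  expect_equal(tab2$rscu[tab2$codon == "AAA"], 1.5)
  expect_equal(tab2$rscu[tab2$codon == "AAG"], 0.5)
  expect_equal(tab2$w[tab2$codon == "AAA"], 1.0)
  expect_equal(tab2$w[tab2$codon == "AAG"], 1 / 3, tolerance = 1e-12)
  # gene with one codon of each -> CAI = sqrt(1/3)
  expect_equal(cai("AAAAAG", tab2), sqrt(1 / 3), tolerance = 1e-12)
  # gene made of family-maximal codons only -> CAI 1
  expect_equal(cai(strrep("AAA", 7), tab2), 1.0)

  expect_error(rscu(character(0)), "empty")
})

test_that("RSCU family means are 1 and CAI ignores gene-length duplication", {
  set.seed(42)
  genes <- vapply(1:12, function(i) random_dna(300, gc = 0.45), "")
  tab <- rscu(genes)
  for (a in unique(tab$aa))
    expect_equal(mean(tab$rscu[tab$aa == a]), 1, tolerance = 1e-9)
  g <- random_dna(240)
  expect_equal(cai(paste0(g, g), tab), cai(g, tab), tolerance = 1e-12)
  # ATG/TGG singleton families always carry w = 1
  expect_equal(tab$w[tab$codon %in% c("ATG", "TGG")], c(1, 1))
})

test_that("RSCU agrees with an independent implementation on zero-free sets", {
  skip_if_not_installed("seqinr")
  set.seed(43)
  genes <- vapply(1:40, function(i) random_dna(900, gc = 0.5), "")
  tab <- rscu(genes)
  expect_true(all(tab$count > 0)) # no pseudo-count distortion in this set
  uco <- seqinr::uco(unlist(strsplit(tolower(paste(genes, collapse = "")), "")),
                     index = "rscu")
  ref <- uco[tolower(tab$codon)]
  expect_equal(unname(ref), tab$rscu, tolerance = 1e-9)
})

test_that("ANOVA + Tukey equal the closed-form oracle and reject degeneracy", {
  set.seed(44)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(5:15, k, replace = TRUE)
    values <- unlist(lapply(seq_len(k), function(j)
      rnorm(n[j], mean = sample(0:3, 1))))
    groups <- rep(paste0("g", seq_len(k)), n)
    got <- group_anova_tukey(values, groups)
    want <- anova_tukey_oracle(values, groups)
    expect_equal(got$p_overall, want$p_overall, tolerance = 1e-6)
    merged <- merge(got$tukey, want$pairs, by = c("group_i", "group_j"))
    expect_equal(nrow(merged), nrow(got$tukey))
    expect_equal(merged$p_adj.x, merged$p_adj.y, tolerance = 1e-6)
  }
  expect_error(group_anova_tukey(rep(1, 10), rep(c("a", "b"), 5)), "degenerate")
  expect_error(group_anova_tukey(c(1, 2, 3), c("a", "a", "b")), "at least two")
  expect_error(group_anova_tukey(1:5, rep("a", 5)), "two groups")
})

test_that("identically distributed groups rarely reach significance", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    v <- rnorm(60)
    g <- rep(c("a", "b"), each = 30)
    if (group_anova_tukey(v, g)$p_overall > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("well-separated groups give essentially zero Tukey p", {
  set.seed(45)
  v <- c(rnorm(50, 40, 1), rnorm(50, 25, 1))
  g <- rep(c("hi", "lo"), each = 50)
  res <- group_anova_tukey(v, g)
  expect_lt(res$tukey$p_adj[1], 1e-6)
})

test_that("GC strata stratification follows the two-stage merge procedure", {
  set.seed(46)
  mk <- function(mean, n, cat, strain)
    data.frame(gc = rnorm(n, mean, 3), category = cat, strain = strain)
  d <- rbind(mk(41, 25, "coding", "L2"), mk(41, 25, "coding", "L5"),
             mk(33, 20, "pseudogene", "L2"), mk(33, 20, "pseudogene", "L5"),
             mk(25, 25, "intergenic", "L2"), mk(25, 25, "intergenic", "L5"))
  res <- classify_gc_strata(d$gc, d$category, d$strain)
  expect_setequal(unique(res$groups), c("coding", "pseudogene", "intergenic"))
  expect_true(all(res$tukey$p_adj < 0.05))
  means <- tapply(d$gc, res$groups, mean)
  expect_true(means["coding"] > means["pseudogene"])
  expect_true(means["pseudogene"] > means["intergenic"])

  # all strata from a single distribution: merge proceeds, nothing significant
  set.seed(47)
  d0 <- rbind(mk(30, 25, "coding", "L2"), mk(30, 25, "coding", "L5"),
              mk(30, 20, "pseudogene", "L2"), mk(30, 20, "pseudogene", "L5"),
              mk(30, 25, "intergenic", "L2"), mk(30, 25, "intergenic", "L5"))
  res0 <- classify_gc_strata(d0$gc, d0$category, d0$strain)
  expect_true(all(res0$tukey$p_adj > 0.05))

  # a singleton merged group propagates the ANOVA precondition error
  d1 <- rbind(mk(41, 10, "coding", "L2"), mk(25, 1, "pseudogene", "L2"))
  expect_error(classify_gc_strata(d1$gc, d1$category, d1$strain),
               "at least two")
})

test_that("contig screen flags exactly a composition-shifted contig", {
  set.seed(48)
  mk_contig_orfs <- function(contig, n, gc) {
    cds <- vapply(seq_len(n), function(i) random_dna(450, gc = gc), "")
    names(cds) <- sprintf("%s_orf%02d", contig, seq_len(n))
    cds
  }
  all_cds <- c()
  contigs <- c()
  for (i in 1:10) {
    gc <- if (i == 7) 0.43 else 0.35
    cds <- mk_contig_orfs(paste0("Contig", i), 25, gc)
    all_cds <- c(all_cds, cds)
    contigs <- c(contigs, rep(paste0("Contig", i), length(cds)))
  }
  ref <- rscu(all_cds[contigs == "Contig1"])
  prof <- composition_profile(all_cds, ref_table = ref)
  prof$contig <- contigs
  res <- run_contig_screen(prof)
  expect_equal(res$outliers, "Contig7")

  # null: all contigs from one model, none flagged in >= 9/10 seeds
  ok <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    cds0 <- c(); ct0 <- c()
    for (i in 1:6) {
      cds <- mk_contig_orfs(paste0("C", i), 15, 0.35)
      cds0 <- c(cds0, cds); ct0 <- c(ct0, rep(paste0("C", i), length(cds)))
    }
    prof0 <- composition_profile(cds0)
    prof0$contig <- ct0
    if (length(contig_screen(prof0[, c("contig", "gc", "gc2", "gc4")])$outliers) == 0)
      ok <- ok + 1
  }
  expect_gte(ok, 9)

  expect_length(contig_screen(data.frame(contig = "only", gc = 1))$outliers, 0)
  expect_error(run_contig_screen(NULL), "empty")
})

test_that("coding density is a union length, not a sum", {
  g1 <- genome_record("g", strrep("A", 1000), "circular", data.frame(
    locus_tag = "x", start = 0L, end = 570L, strand = "+", kind = "CDS",
    product = "", translation = "", wraps = FALSE))
  expect_equal(coding_density(g1), 57.0)

  g2 <- genome_record("g", strrep("A", 1000), "circular", data.frame(
    locus_tag = c("x", "y"), start = c(0L, 50L), end = c(100L, 150L),
    strand = "+", kind = "CDS", product = "", translation = "",
    wraps = FALSE))
  expect_equal(coding_density(g2), 15.0)

  # all-genes definition includes RNA features
  g3 <- genome_record("g", strrep("A", 1000), "circular", data.frame(
    locus_tag = c("x", "r"), start = c(0L, 500L), end = c(100L, 600L),
    strand = "+", kind = c("CDS", "rRNA"), product = "", translation = "",
    wraps = FALSE))
  expect_equal(coding_density(g3, "cds-only"), 10.0)
  expect_equal(coding_density(g3, "all-genes"), 20.0)
})

test_that("variant-rate arithmetic reproduces the printed error rates", {
  expect_equal(round(variant_rate(34, 1.478e6), 4), 0.0023)
  expect_equal(variant_rate(0, 12345), 0)
  expect_equal(variant_rate(1, 100), 1.0)
})
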