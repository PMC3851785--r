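# One-to-one pairing, synteny fitting, truncation screen, outgroup check.

mk_hits <- function(q, s, e, bit = 100) {
  data.frame(query_id = q, subject_id = s, pct_identity = 90,
             aln_length = 100L, mismatches = 10L, gap_opens = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             e_value = e, bit_score = bit, stringsAsFactors = FALSE)
}

# genome whose features exist only for their coordinates
coord_genome <- function(id, starts, len, tags = names(starts)) {
  genome_record(id, strrep("A", len), "circular", data.frame(
    locus_tag = tags, start = as.integer(starts),
    end = as.integer(starts) + 30L, strand = "+", kind = "CDS", product = "",
    translation = "", wraps = FALSE))
}

test_that("greedy pairing follows best-hit, e-value order, duplicate-subject rules", {
  h <- mk_hits(c("q1", "q2", "q3"), c("s1", "s2", "s3"), c(1e-50, 1e-40, 1e-5))
  m <- pair_homologs(h, c("q1", "q2", "q3"), c("s1", "s2", "s3"))
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$orphans_a, 0)
  expect_length(m$orphans_b, 0)

  h2 <- mk_hits(c("q1", "q2"), c("s1", "s1"), c(1e-50, 1e-20))
  m2 <- pair_homologs(h2, c("q1", "q2"), c("s1", "s2"))
  expect_equal(m2$pairs$query_id, "q1")
  expect_equal(m2$orphans_a, "q2")
  expect_equal(m2$orphans_b, "s2")

  m3 <- pair_homologs(hit_table(), c("q1", "q2"), c("s1"))
  expect_equal(nrow(m3$pairs), 0L)
  expect_setequal(m3$orphans_a, c("q1", "q2"))
  expect_equal(m3$orphans_b, "s1")
})

test_that("unknown gene ids in the hit table are an error", {
  expect_error(pair_homologs(mk_hits("qX", "s1", 1e-5), "q1", "s1"), "qX")
})

test_that("pairing is one-to-one on random hit tables and deterministic on ties", {
  set.seed(21)
  for (i in 1:20) {
    nq <- sample(3:12, 1); ns <- sample(3:12, 1); nh <- sample(5:40, 1)
    h <- mk_hits(paste0("q", sample(nq, nh, TRUE)),
                 paste0("s", sample(ns, nh, TRUE)),
                 signif(10^-sample(1:30, nh, TRUE), 3))
    genes_a <- paste0("q", 1:nq); genes_b <- paste0("s", 1:ns)
    m <- pair_homologs(h, genes_a, genes_b)
    expect_false(any(duplicated(m$pairs$query_id)))
    expect_false(any(duplicated(m$pairs$subject_id)))
    expect_equal(nrow(m$pairs) + length(m$orphans_a), nq)
    expect_equal(nrow(m$pairs) + length(m$orphans_b), ns)
    expect_length(intersect(m$pairs$query_id, m$orphans_a), 0)
  }
  # all e-values tied: ties break by bit score then lexicographic ids
  ht <- mk_hits(c("q2", "q1", "q1"), c("s2", "s1", "s2"), 1e-10,
                bit = c(50, 50, 60))
  m1 <- pair_homologs(ht, c("q1", "q2"), c("s1", "s2"))
  m2 <- pair_homologs(ht[c(3, 1, 2), ], c("q1", "q2"), c("s1", "s2"))
  expect_equal(m1$pairs, m2$pairs)
  expect_equal(m1$pairs$subject_id[m1$pairs$query_id == "q1"], "s2")
})

test_that("perfect synteny gives zero discrepancies", {
  starts <- seq(0, 90000, by = 2000)
  names(starts) <- paste0("g", seq_along(starts))
  ga <- coord_genome("A", starts, 100000)
  gb <- coord_genome("B", starts, 100000, tags = paste0("h", seq_along(starts)))
  h <- mk_hits(paste0("g", seq_along(starts)), paste0("h", seq_along(starts)),
               10^-(40 + seq_along(starts)))
  m <- synteny_discrepancy(pair_homologs(h, ga, gb), ga, gb)
  expect_true(all(m$pairs$discrepancy == 0))
  expect_equal(sum(m$pairs$flag_review), ceiling(0.1 * length(starts)))
})

test_that("a transposed gene carries the maximal discrepancy and is flagged", {
  starts_a <- seq(0, 98000, by = 2000) # 50 genes
  names(starts_a) <- paste0("g", seq_along(starts_a))
  starts_b <- starts_a
  starts_b["g10"] <- (starts_a["g10"] + 200000) %% 500000
  ga <- coord_genome("A", starts_a, 500000)
  gb <- coord_genome("B", starts_b[order(starts_b)], 500000)
  h <- mk_hits(names(starts_a), names(starts_a), 10^-(40 + seq_along(starts_a)))
  m <- synteny_discrepancy(pair_homologs(h, ga, gb), ga, gb)
  worst <- m$pairs$query_id[which.max(m$pairs$discrepancy)]
  expect_equal(worst, "g10")
  expect_true(m$pairs$flag_review[m$pairs$query_id == "g10"])
  expect_gt(max(m$pairs$discrepancy), 150000)
})

test_that("inversion members have discrepancies bounded by the inversion span", {
  starts_a <- seq(0, 198000, by = 2000) # 100 genes over 200 kb
  names(starts_a) <- paste0("g", seq_along(starts_a))
  starts_b <- starts_a
  inv <- 20:35 # a ~30 kb inversion
  span <- max(starts_a[inv]) - min(starts_a[inv])
  starts_b[inv] <- rev(starts_a[inv])
  ga <- coord_genome("A", starts_a, 200000)
  gb <- coord_genome("B", starts_b[order(starts_b)], 200000)
  h <- mk_hits(names(starts_a), names(starts_a), 10^-(40 + seq_along(starts_a)))
  m <- synteny_discrepancy(pair_homologs(h, ga, gb), ga, gb)
  expect_lte(max(m$pairs$discrepancy), span)
  segs <- reversed_segments(m, ga, gb)
  expect_equal(nrow(segs), 1L)
  expect_gte(segs$n_pairs, length(inv) - 1L)
})

test_that("fewer than three pairs flags everything with no fit", {
  ga <- coord_genome("A", c(g1 = 0, g2 = 500), 10000)
  gb <- coord_genome("B", c(g1 = 0, g2 = 500), 10000)
  h <- mk_hits(c("g1", "g2"), c("g1", "g2"), c(1e-30, 1e-20))
  m <- synteny_discrepancy(pair_homologs(h, ga, gb), ga, gb)
  expect_true(all(m$pairs$flag_review))
  expect_true(all(is.na(m$pairs$discrepancy)))
  expect_null(m$synteny_model)
})

test_that("hit-list similarity is the top-k Jaccard index", {
  expect_equal(hitlist_similarity(letters[1:10], letters[1:10]), 1.0)
  expect_equal(hitlist_similarity(letters[1:10], LETTERS[1:10]), 0.0)
  expect_equal(hitlist_similarity(letters[1:10], c(letters[1:5], LETTERS[1:5])),
               5 / 15)
  expect_error(hitlist_similarity(letters, letters, k = 0), "positive")
})

test_that("length screen uses a strict 20% rule with signed differences", {
  r <- length_screen(c(100, 100), c(79, 80))
  expect_equal(r$pct_diff, c(-21, -20))
  expect_equal(r$flagged, c(TRUE, FALSE))
  expect_error(length_screen(0, 10), "positive")
})

test_that("start extension moves the start back over in-frame upstream homology", {
  set.seed(23)
  aa2cod <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  prot_ext <- paste(sample(setdiff(AA20, c("M", "W")), 30, TRUE), collapse = "")
  prot_core <- random_protein(80)
  cod_of <- function(p) paste(vapply(strsplit(p, "")[[1]],
                                     function(a) aa2cod[[a]][1], ""),
                              collapse = "")
  ext_dna <- paste0("ATG", cod_of(prot_ext))      # earlier ATG + 30 codons
  core_dna <- paste0("ATG", cod_of(prot_core), "TAA")
  spacer <- strrep("C", 150) # stop-free in every frame
  genome <- genome_record("S", paste0(spacer, ext_dna, core_dna, spacer),
                          "circular", data.frame(
    locus_tag = "short1", start = 150L + nchar(ext_dna),
    end = 150L + nchar(ext_dna) + nchar(core_dna), strand = "+", kind = "CDS",
    product = "", translation = "", wraps = FALSE))
  long_prot <- paste0("M", prot_ext, "M", prot_core)
  res <- extend_start(genome$features[1, ], genome, long_prot)
  expect_true(res$extended)
  expect_equal(res$shift_bases, nchar(ext_dna))
  expect_equal(res$feature$start, 150L)

  # an intervening stop before the earlier ATG blocks the move
  blocked <- genome
  blocked$sequence <- paste0(spacer, "TAA", substring(ext_dna, 4), core_dna,
                             spacer)
  res2 <- extend_start(blocked$features[1, ], blocked, long_prot)
  expect_false(res2$extended)

  # equal-length pair: nothing upstream to find, feature unchanged
  res3 <- extend_start(genome$features[1, ], genome,
                       paste0("M", prot_core))
  expect_false(res3$extended)
  expect_equal(res3$feature$start, genome$features$start[1])
})

test_that("three-way outgroup check fires only on conflicting evidence", {
  m <- pair_homologs(mk_hits(c("q1", "q2", "q3"), c("s1", "s2", "s3"),
                             c(1e-30, 1e-20, 1e-10)),
                     c("q1", "q2", "q3"), c("s1", "s2", "s3"))
  ha <- mk_hits(c("q1", "q2"), c("og1", "og2"), c(1e-30, 1e-10))
  hb <- mk_hits(c("s1", "s2"), c("og1", "og9"), c(1e-25, 1e-12))
  tw <- three_way_check(m, ha, hb)
  expect_true(tw$consistent[tw$query_id == "q1"])  # same outgroup id
  expect_false(tw$consistent[tw$query_id == "q2"]) # different ids
  expect_true(tw$consistent[tw$query_id == "q3"])  # no evidence either side
})

test_that("inventory matrix reflects annotation and deletion truth", {
  g1 <- genome_record("G1", strrep("ACGT", 100), "circular", data.frame(
    locus_tag = c("x1", "x2"), start = c(0L, 60L), end = c(30L, 90L),
    strand = "+", kind = "CDS", product = c("cell division protein FtsZ",
                                            "replication initiator DnaA"),
    translation = "", wraps = FALSE))
  g2 <- genome_record("G2", strrep("ACGT", 100), "circular", data.frame(
    locus_tag = "y1", start = 0L, end = 30L, strand = "+", kind = "CDS",
    product = "cell division protein FtsZ", translation = "", wraps = FALSE))
  inv <- inventory_matrix(list(G1 = g1, G2 = g2), c("ftsZ", "dnaA"))
  expect_true(inv["ftsZ", "G1"] && inv["ftsZ", "G2"])
  expect_true(inv["dnaA", "G1"])
  expect_false(inv["dnaA", "G2"]) # deleted from G2
  expect_equal(dim(inventory_matrix(list(G1 = g1), character(0))), c(0L, 1L))
})
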