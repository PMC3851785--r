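# Pseudogene calling rules, weighted-identity aggregation, intergenic
# synteny modes and stop-codon/GC maps.

mk_region <- function(id, start, seq, genome_id = "B") {
  data.frame(region_id = id, genome_id = genome_id, start = start,
             end = start + nchar(seq), length = nchar(seq),
             midpoint = start + nchar(seq) / 2, wraps = FALSE, sequence = seq,
             stringsAsFactors = FALSE)
}

mk_thit <- function(subject, s_start, s_end, frame_s, bit = 80, e = 1e-20,
                    query = "orf1", pct = 60, frame_q = 0L) {
  data.frame(query_id = query, subject_id = subject, pct_identity = pct,
             aln_length = as.integer(abs(s_end - s_start) %/% 3 + 1),
             mismatches = 5L, gap_opens = 0L, q_start = 1L, q_end = 100L,
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             e_value = e, bit_score = bit, frame_q = frame_q,
             frame_s = as.integer(frame_s), stringsAsFactors = FALSE)
}

ident_model <- list(scale = 1, offset = 0, L_a = 1e6, L_b = 1e6)
orphan_feat <- data.frame(locus_tag = "orf1", start = 10000L, end = 11000L,
                          strand = "+", kind = "CDS", product = "",
                          translation = "", wraps = FALSE)

test_that("orphan hits grouping into a compact syntenic locus yield a call", {
  set.seed(31)
  reg <- mk_region("B_ig001", 9950L, random_dna(1200))
  hits <- rbind(mk_thit("B_ig001", 10, 300, 1),
                mk_thit("B_ig001", 310, 600, 2),
                mk_thit("B_ig001", 620, 910, 1))
  call <- call_pseudogene_from_orphan(orphan_feat, hits, reg, ident_model)
  expect_s3_class(call, "pseudogene_call")
  expect_equal(call$frameshift_count, 1L) # frames {+1, +2} -> one shift
  expect_equal(call$evidence, "orphan-tblastn")
  expect_equal(call$nearest_homolog, "orf1")
  expect_gte(call$inframe_stop_count, 0L)

  # three distinct frames -> two frameshifts
  hits3 <- rbind(mk_thit("B_ig001", 10, 300, 1),
                 mk_thit("B_ig001", 310, 600, 2),
                 mk_thit("B_ig001", 620, 910, 3))
  call3 <- call_pseudogene_from_orphan(orphan_feat, hits3, reg, ident_model)
  expect_equal(call3$frameshift_count, 2L)
})

test_that("the locus span rule rejects hits spread wider than the query", {
  set.seed(32)
  reg <- mk_region("B_ig001", 9000L, random_dna(3000))
  # the same three-HSP evidence, but chained over 2.5 kb for a 1 kb orphan
  hits <- rbind(mk_thit("B_ig001", 10, 300, 1),
                mk_thit("B_ig001", 1110, 1400, 2),
                mk_thit("B_ig001", 2210, 2500, 1))
  expect_null(call_pseudogene_from_orphan(orphan_feat, hits, reg, ident_model))
  # an isolated stray HSP far away cannot veto a compact qualifying locus
  compact <- rbind(mk_thit("B_ig001", 910, 1200, 1, bit = 120),
                   mk_thit("B_ig001", 1210, 1500, 2, bit = 120),
                   mk_thit("B_ig001", 2900, 2960, 3, bit = 40))
  call <- call_pseudogene_from_orphan(orphan_feat, compact, reg, ident_model)
  expect_s3_class(call, "pseudogene_call")
  expect_equal(call$frameshift_count, 1L) # stray frame not in the cluster
})

test_that("the synteny rule rejects an off-model locus", {
  set.seed(33)
  reg <- mk_region("B_ig050", 510000L, random_dna(1200))
  hits <- rbind(mk_thit("B_ig050", 10, 300, 1),
                mk_thit("B_ig050", 320, 900, 2))
  expect_null(call_pseudogene_from_orphan(orphan_feat, hits, reg, ident_model,
                                          window = 20000))
})

test_that("intergenic protein-database calls follow the e-value and title rules", {
  set.seed(34)
  reg <- mk_region("A_ig007", 50000L, random_dna(600), genome_id = "A")
  good <- mk_thit("UTP-glucose-1-phosphate uridylyltransferase", 1, 300, 1,
                  e = 1e-5, frame_q = 1L)
  good$q_start <- 10L; good$q_end <- 310L
  call <- call_pseudogene_from_intergenic(reg, good)
  expect_s3_class(call, "pseudogene_call")
  expect_equal(call$nearest_homolog,
               "UTP-glucose-1-phosphate uridylyltransferase")

  weak <- good; weak$e_value <- 0.01
  expect_null(call_pseudogene_from_intergenic(reg, weak))

  hypo <- good; hypo$subject_id <- "hypothetical protein XYZ_123"
  hypo$e_value <- 1e-20
  expect_null(call_pseudogene_from_intergenic(reg, hypo))
})

test_that("weighted identity follows the forced formula and is order-invariant", {
  h <- rbind(mk_thit("r1", 1, 300, 1, pct = 80), mk_thit("r1", 1, 150, 2, pct = 90))
  h$aln_length <- c(100L, 50L)
  agg <- aggregate_translated_hits(h)
  expect_equal(agg$weighted_identity, (80 * 100 + 90 * 50) / 150)

  single <- aggregate_translated_hits(h[1, ])
  expect_equal(single$weighted_identity, 80)

  shuf <- aggregate_translated_hits(h[c(2, 1), ])
  expect_equal(shuf$weighted_identity, agg$weighted_identity)

  # bounded by member identities
  expect_gte(agg$weighted_identity, 80)
  expect_lte(agg$weighted_identity, 90)
})

test_that("identical intergenic sets give a 100% diagonal; disjoint sets give none", {
  set.seed(35)
  seqs <- vapply(1:6, function(i) random_dna(400), "")
  regs <- do.call(rbind, lapply(1:6, function(i)
    mk_region(sprintf("ig%02d", i), 1000L * i, seqs[i])))
  pts <- intergenic_synteny(regs, regs, mode = "nucleotide")
  expect_equal(nrow(pts), 6L)
  expect_true(all(pts$weighted_identity == 100))
  expect_true(all(pts$midpoint_a == pts$midpoint_b))

  other <- do.call(rbind, lapply(1:6, function(i)
    mk_region(sprintf("og%02d", i), 1000L * i, random_dna(400))))
  none <- intergenic_synteny(regs, other, mode = "nucleotide")
  expect_equal(nrow(none), 0L)
})

test_that("translated mode retains far more decayed syntenic pairs than nucleotide mode", {
  # two branches of AT-biased neutral drift (0.25/site each, ~40% pairwise
  # divergence): nucleotide-level similarity is mostly gone while the
  # translated scan still recovers most syntenic region pairs. Note the
  # nucleotide mode here is an exhaustive local-alignment scan, which is
  # more sensitive than a word-seeded search would be, so the contrast
  # ratio is conservative.
  set.seed(36)
  drift <- ratchet:::neutral_drift
  n <- 25
  anc <- vapply(seq_len(n), function(i) random_dna(600, gc = 0.30), "")
  ra <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_region(sprintf("a%02d", i), 2000L * i, drift(anc[i], 0.25, 0.8), "A")))
  rb <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_region(sprintf("b%02d", i), 2000L * i, drift(anc[i], 0.25, 0.8), "B")))
  nt <- intergenic_synteny(ra, rb, mode = "nucleotide")
  tx <- intergenic_synteny(ra, rb, mode = "translated")
  expect_lte(nrow(nt), n / 3)          # nucleotide signal largely erased
  expect_gte(nrow(tx), 2 * nrow(nt))   # translated mode retains far more
  expect_gte(nrow(tx), n / 2)
  # and the translated points are overwhelmingly syntenic (diagonal)
  expect_gte(mean(sub("a", "", tx$query_id) == sub("b", "", tx$subject_id)),
             0.8)
  # intergenic synteny mirrors coordinate order (no inversions simulated)
  expect_gt(cor(tx$midpoint_a, tx$midpoint_b, method = "spearman"), 0.9)
})

test_that("stop-frame map locates stops per frame and windows GC", {
  m <- stop_frame_map("TAATAGTGA")
  expect_equal(m$stops$frame0, c(0L, 3L, 6L))
  expect_length(m$stops$frame1, 0)
  expect_length(m$stops$frame2, 0)

  gcseq <- strrep("GC", 200)
  m2 <- stop_frame_map(gcseq, window = 100)
  expect_true(all(lengths(m2$stops) == 0))
  expect_true(all(m2$gc$gc_pct == 100))

  # random sequence: stop density within 3 sigma of 3/64 per codon per frame
  set.seed(37)
  r <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  m3 <- stop_frame_map(r)
  n_cod <- 1000
  expected <- n_cod * 3 / 64
  sigma <- sqrt(n_cod * (3 / 64) * (61 / 64))
  for (f in 1:3)
    expect_lt(abs(length(m3$stops[[f]]) - expected), 3 * sigma)
})
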