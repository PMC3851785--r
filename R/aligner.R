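# Local similarity search used in place of external search binaries. The
# dynamic programming itself is delegated to Biostrings::pairwiseAlignment
# (Smith-Waterman with affine gaps); this module adds greedy multi-HSP
# enumeration by subject masking, Karlin-Altschul e-value/bit-score
# statistics, six-frame translated modes with DNA coordinate mapping, and
# exact k-mer seeded batch searches. Externally produced 12-column hit
# tables can be substituted anywhere a hit table is consumed.

#' Scoring scheme for local similarity search
#'
#' Protein mode uses BLOSUM62 with affine gaps (default open 11, extend 1)
#' and fixed Karlin-Altschul calibration constants; e-values are used only
#' for ordering and loose cutoffs, not for parity with any external tool.
#' Stop characters (`*`) and masked/ambiguous letters (`X`, and `N` in
#' nucleotide mode) are strongly penalized so local alignments do not cross
#' stops or masked regions, and never count as identities.
#'
#' @param mode `"protein"` or `"nucleotide"`.
#' @param gap_open,gap_extend positive gap penalties.
#' @param match,mismatch nucleotide scores (defaults +2/-3).
#' @param karlin_k,karlin_lambda calibration constants for e-values.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("protein", "nucleotide"),
                           gap_open = NULL, gap_extend = NULL,
                           match = 2, mismatch = -3,
                           karlin_k = NULL, karlin_lambda = NULL) {
  mode <- match.arg(mode)
  if (mode == "protein") {
    mat <- get_blosum62()
    mat["X", ] <- -6; mat[, "X"] <- -6
    mat["*", ] <- -20; mat[, "*"] <- -20
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    karlin_k <- karlin_k %||% 0.134
    karlin_lambda <- karlin_lambda %||% 0.317
  } else {
    letters <- c("A", "C", "G", "T", "N")
    mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(mat) <- match
    mat["N", ] <- -6; mat[, "N"] <- -6
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    karlin_k <- karlin_k %||% 0.41
    karlin_lambda <- karlin_lambda %||% 0.625
  }
  stopifnot(gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_k > 0)
  structure(list(mode = mode, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_k = karlin_k,
                 karlin_lambda = karlin_lambda),
            class = "scoring_scheme")
}

.BLOSUM62_CACHE <- NULL
get_blosum62 <- function() {
  if (is.null(.BLOSUM62_CACHE)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    utils::assignInMyNamespace(".BLOSUM62_CACHE", e$BLOSUM62)
  }
  .BLOSUM62_CACHE
}

evalue_of <- function(score, m, n, s) s$karlin_k * m * n * exp(-s$karlin_lambda * score)
bits_of <- function(score, s) (s$karlin_lambda * score - log(s$karlin_k)) / log(2)

check_alphabet <- function(seq, mode) {
  pat <- if (mode == "nucleotide") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWYXBZU*]"
  if (grepl(pat, seq))
    stop("sequence contains letters outside the ", mode, " alphabet")
}

# letters that never count as identities (ambiguity/mask/stop/gap);
# "N" is only ambiguous in DNA - in protein it is asparagine
nonmatch_letters <- function(mode) {
  if (mode == "nucleotide") c("N", "-") else c("X", "*", "-")
}

#' Local alignment with greedy HSP enumeration
#'
#' Smith-Waterman with affine gaps. The best local alignment is reported,
#' the matched subject interval is masked, and the search repeats until the
#' raw score drops below `min_score` (greedy multi-HSP enumeration).
#' Identity is `matches / alignment columns * 100`; `N`/`X`/`*` never count
#' as matches.
#'
#' @param query,subject sequences (character strings) in the scheme's
#'   alphabet.
#' @param scheme a [scoring_scheme].
#' @param min_score minimum raw HSP score reported.
#' @param max_hsps cap on HSPs per pair.
#' @param query_id,subject_id identifiers placed in the hit table.
#' @return hit table (see [hit_table()]) ordered by decreasing score.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme("protein"),
                        min_score = 30, max_hsps = 25,
                        query_id = "query", subject_id = "subject") {
  query <- toupper(query); subject <- toupper(subject)
  if (!nchar(query) || !nchar(subject)) stop("sequences must be non-empty")
  check_alphabet(query, scheme$mode); check_alphabet(subject, scheme$mode)
  mk <- if (scheme$mode == "nucleotide") Biostrings::DNAString else Biostrings::AAString
  mask_char <- if (scheme$mode == "nucleotide") "N" else "X"
  q <- mk(query)
  subj_chr <- subject
  out <- hit_table()
  m <- nchar(query); n <- nchar(subject)
  for (i in seq_len(max_hsps)) {
    aln <- Biostrings::pairwiseAlignment(
      q, mk(subj_chr), type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    sc <- Biostrings::score(aln)
    if (sc < min_score) break
    ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    nonmatch <- nonmatch_letters(scheme$mode)
    matches <- sum(ap == as_ & !(ap %in% nonmatch))
    cols <- length(ap)
    gaps_p <- rle(ap == "-"); gaps_s <- rle(as_ == "-")
    gap_opens <- sum(gaps_p$values) + sum(gaps_s$values)
    mism <- sum(ap != "-" & as_ != "-" & (ap != as_ | ap %in% nonmatch))
    s1 <- IRanges::start(Biostrings::subject(aln))
    s2 <- IRanges::end(Biostrings::subject(aln))
    out <- rbind(out, data.frame(
      query_id = query_id, subject_id = subject_id,
      pct_identity = 100 * matches / cols, aln_length = cols,
      mismatches = mism, gap_opens = gap_opens,
      q_start = IRanges::start(Biostrings::pattern(aln)),
      q_end = IRanges::end(Biostrings::pattern(aln)),
      s_start = s1, s_end = s2,
      e_value = evalue_of(sc, m, n, scheme), bit_score = bits_of(sc, scheme),
      stringsAsFactors = FALSE))
    # mask the matched subject interval and look for the next HSP
    substr(subj_chr, s1, s2) <- strrep(mask_char, s2 - s1 + 1L)
  }
  out
}

# full-frame translations of a DNA string; stops retained as "*" (the
# scoring matrix penalizes them so alignments are confined to stop-free
# segments). Returns list of list(frame, aa, dna_len).
frame_translations <- function(seq) {
  seq <- toupper(seq)
  ft <- six_frames(seq)
  lapply(seq_len(nrow(ft)), function(i)
    list(frame = ft$frame[i], aa = ft$aa[i], dna_len = nchar(seq)))
}

# map 1-based aa positions in a frame translation back to forward-strand DNA
# coordinates (1-based inclusive; start > end for minus frames)
aa_to_dna <- function(aa_start, aa_end, frame, dna_len) {
  f <- abs(frame)
  d1 <- (f - 1L) + 3L * (aa_start - 1L) + 1L
  d2 <- (f - 1L) + 3L * aa_end
  if (frame > 0) c(d1, d2) else c(dna_len - d1 + 1L, dna_len - d2 + 1L)
}

#' Translated similarity search
#'
#' `"tblastn"` mode searches a protein query against all six reading frames
#' of a DNA subject; `"tblastx"` mode translates both sides. Frames are
#' translated in full with stop codons retained; the protein scoring matrix
#' penalizes `*` heavily, so HSPs are confined to stop-free segments.
#' Subject (and query, in `tblastx` mode) coordinates are reported on the
#' DNA, with start > end for minus-frame hits, and each hit carries
#' `frame_q`/`frame_s` (0 for an untranslated protein query).
#'
#' @param query protein (tblastn) or DNA (tblastx) sequence.
#' @param subject DNA sequence.
#' @param scheme protein [scoring_scheme].
#' @param mode `"tblastn"` or `"tblastx"`.
#' @inheritParams local_align
#' @return hit table with `frame_q` and `frame_s` columns.
#' @export
translated_search <- function(query, subject, scheme = scoring_scheme("protein"),
                              mode = c("tblastn", "tblastx"), min_score = 30,
                              max_hsps = 25, query_id = "query",
                              subject_id = "subject") {
  mode <- match.arg(mode)
  stopifnot(scheme$mode == "protein")
  sub_frames <- frame_translations(subject)
  q_frames <- if (mode == "tblastn") {
    list(list(frame = 0L, aa = toupper(query), dna_len = NA_integer_))
  } else frame_translations(query)
  out <- hit_table(); out$frame_q <- integer(0); out$frame_s <- integer(0)
  for (qf in q_frames) {
    if (nchar(qf$aa) == 0L) next
    for (sf in sub_frames) {
      if (nchar(sf$aa) == 0L) next
      hits <- local_align(qf$aa, sf$aa, scheme, min_score = min_score,
                          max_hsps = max_hsps, query_id = query_id,
                          subject_id = subject_id)
      if (!nrow(hits)) next
      for (i in seq_len(nrow(hits))) {
        sd <- aa_to_dna(hits$s_start[i], hits$s_end[i], sf$frame, sf$dna_len)
        hits$s_start[i] <- sd[1]; hits$s_end[i] <- sd[2]
        if (qf$frame != 0L) {
          qd <- aa_to_dna(hits$q_start[i], hits$q_end[i], qf$frame, qf$dna_len)
          hits$q_start[i] <- qd[1]; hits$q_end[i] <- qd[2]
        }
      }
      hits$frame_q <- qf$frame; hits$frame_s <- sf$frame
      out <- rbind(out, hits)
    }
  }
  if (nrow(out)) out <- out[order(out$e_value, -out$bit_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Seeded batch searches (k-mer candidate prescreen, then full alignment).

#' All-vs-all protein search with k-mer seeding
#'
#' Candidate query/subject pairs must share at least one exact amino-acid
#' `k`-mer before full local alignment is attempted (the same seeding idea
#' word-based search tools use, reduced to an exact prescreen).
#'
#' @param queries,subjects named character vectors of protein sequences.
#' @param scheme protein [scoring_scheme].
#' @param k seed word size (amino acids).
#' @inheritParams local_align
#' @return combined hit table.
#' @details The default reporting threshold (raw 60, about 30 bits) suits
#'   whole-protein ortholog searches, where genuine homologs score orders
#'   of magnitude above the sporadic sub-30-bit matches that exhaustive
#'   alignment of seeded pairs produces between unrelated proteins.
#' @export
search_proteins <- function(queries, subjects, scheme = scoring_scheme("protein"),
                            k = 5, min_score = 60, max_hsps = 5) {
  cand <- kmer_candidates(queries, subjects, k)
  out <- batch_pair_hits(unname(queries[cand$query_id]),
                         unname(subjects[cand$subject_id]),
                         cand$query_id, cand$subject_id, scheme,
                         min_score = min_score, max_hsps = max_hsps)
  out <- out[order(out$query_id, out$e_value, -out$bit_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized elementwise alignment engine for candidate pair lists.
# pairwiseAlignment aligns pattern[i] with subject[i] when given two
# equal-length sets, so every candidate pair of a whole search fits in a
# handful of C-level calls: one score-only prescreen, then detailed
# alignment plus greedy masking rounds for the survivors only.
batch_pair_hits <- function(q_chr, s_chr, query_ids, subject_ids, scheme,
                            min_score = 30, max_hsps = 25) {
  if (!length(q_chr)) return(hit_table())
  mk <- if (scheme$mode == "nucleotide") Biostrings::DNAStringSet
        else Biostrings::AAStringSet
  mask_char <- if (scheme$mode == "nucleotide") "N" else "X"
  nonmatch <- nonmatch_letters(scheme$mode)
  args <- list(type = "local", substitutionMatrix = scheme$matrix,
               gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc0 <- do.call(Biostrings::pairwiseAlignment,
                 c(list(mk(s_chr), mk(q_chr), scoreOnly = TRUE), args))
  alive <- which(sc0 >= min_score)
  rows <- list()
  q_act <- q_chr[alive]; s_act <- s_chr[alive]; idx_act <- alive
  for (round in seq_len(max_hsps)) {
    if (!length(idx_act)) break
    aln <- do.call(Biostrings::pairwiseAlignment,
                   c(list(mk(s_act), mk(q_act)), args))
    sc <- Biostrings::score(aln)
    keep <- which(sc >= min_score)
    if (!length(keep)) break
    # role swap: "pattern" is our subject, "subject" our query. Counts come
    # from the vectorized accessors: mask/stop letters are penalized hard
    # enough that optimal HSPs never include them, so letter-match counting
    # agrees with the nonmatch policy used by local_align().
    ss <- IRanges::start(Biostrings::pattern(aln))[keep]
    se <- IRanges::end(Biostrings::pattern(aln))[keep]
    qs <- IRanges::start(Biostrings::subject(aln))[keep]
    qe <- IRanges::end(Biostrings::subject(aln))[keep]
    n_match <- Biostrings::nmatch(aln)[keep]
    n_mism <- Biostrings::nmismatch(aln)[keep]
    n_cols <- Biostrings::nchar(aln)[keep]
    ind <- Biostrings::nindel(aln)
    n_go <- (Biostrings::insertion(ind)[, "Length"] +
             Biostrings::deletion(ind)[, "Length"])[keep]
    gi <- idx_act[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = query_ids[gi], subject_id = subject_ids[gi],
      pct_identity = 100 * n_match / n_cols, aln_length = n_cols,
      mismatches = n_mism, gap_opens = n_go,
      q_start = qs, q_end = qe, s_start = ss, s_end = se,
      e_value = evalue_of(sc[keep], nchar(q_chr[gi]), nchar(s_chr[gi]), scheme),
      bit_score = bits_of(sc[keep], scheme), stringsAsFactors = FALSE)
    # mask the matched subject intervals; only those pairs stay active
    s_next <- s_act[keep]
    for (j in seq_along(keep)) {
      substr(s_next[j], ss[j], se[j]) <- strrep(mask_char, se[j] - ss[j] + 1L)
    }
    q_act <- q_act[keep]; s_act <- s_next; idx_act <- idx_act[keep]
  }
  out <- do.call(rbind, c(list(hit_table()), rows))
  rownames(out) <- NULL
  out
}

# frame-level translated sets: named vector of frame translations with
# composite names "<id>|<frame>"
frame_set <- function(seqs) {
  out <- character(0)
  for (id in names(seqs)) {
    ft <- six_frames(seqs[[id]])
    v <- stats::setNames(ft$aa, sprintf("%s|%d", id, ft$frame))
    out <- c(out, v)
  }
  out
}

split_frame_id <- function(x) {
  pos <- regexpr("\\|[-0-9]+$", x)
  list(id = substr(x, 1L, pos - 1L),
       frame = as.integer(substring(x, pos + 1L)))
}

#' Translated search between two DNA sequence sets with frame-level seeding
#'
#' Six-frame translations of both sets are indexed by exact amino-acid
#' `k`-mers; only frame pairs sharing a seed are aligned. Used for the
#' intergenic tblastx-style synteny scan where all-vs-all alignment of every
#' frame combination would be wasteful.
#'
#' @param queries,subjects named character vectors of DNA sequences.
#' @param scheme protein [scoring_scheme].
#' @param k amino-acid seed size.
#' @inheritParams local_align
#' @return hit table with `frame_q`/`frame_s`; DNA coordinates.
#' @export
search_tblastx <- function(queries, subjects, scheme = scoring_scheme("protein"),
                           k = 5, min_score = 35, max_hsps = 5) {
  qf <- frame_set(queries); sf <- frame_set(subjects)
  cand <- kmer_candidates(qf, sf, k)
  hits <- batch_pair_hits(unname(qf[cand$query_id]), unname(sf[cand$subject_id]),
                          cand$query_id, cand$subject_id, scheme,
                          min_score = min_score, max_hsps = max_hsps)
  empty <- hit_table(); empty$frame_q <- integer(0); empty$frame_s <- integer(0)
  if (!nrow(hits)) return(empty)
  qi <- split_frame_id(hits$query_id); si <- split_frame_id(hits$subject_id)
  qlen <- nchar(queries[qi$id]); slen <- nchar(subjects[si$id])
  for (j in seq_len(nrow(hits))) {
    qd <- aa_to_dna(hits$q_start[j], hits$q_end[j], qi$frame[j], qlen[j])
    sd <- aa_to_dna(hits$s_start[j], hits$s_end[j], si$frame[j], slen[j])
    hits$q_start[j] <- qd[1]; hits$q_end[j] <- qd[2]
    hits$s_start[j] <- sd[1]; hits$s_end[j] <- sd[2]
  }
  hits$query_id <- qi$id; hits$subject_id <- si$id
  hits$frame_q <- qi$frame; hits$frame_s <- si$frame
  hits <- hits[order(hits$query_id, hits$e_value, -hits$bit_score), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Nucleotide search between two DNA sets with k-mer seeding
#'
#' Forward and reverse-complement orientations are both screened; minus
#' orientation hits report subject start > end.
#'
#' @inheritParams search_tblastx
#' @param scheme nucleotide [scoring_scheme].
#' @param k nucleotide seed size.
#' @export
search_blastn <- function(queries, subjects, scheme = scoring_scheme("nucleotide"),
                          k = 12, min_score = 50, max_hsps = 5) {
  do_one <- function(subjects_or, minus) {
    cand <- kmer_candidates(queries, subjects_or, k)
    hits <- batch_pair_hits(unname(queries[cand$query_id]),
                            unname(subjects_or[cand$subject_id]),
                            cand$query_id, cand$subject_id, scheme,
                            min_score = min_score, max_hsps = max_hsps)
    if (nrow(hits) && minus) {
      slen <- nchar(subjects_or[hits$subject_id])
      s1 <- slen - hits$s_start + 1L; s2 <- slen - hits$s_end + 1L
      hits$s_start <- s1; hits$s_end <- s2
    }
    hits
  }
  fwd <- do_one(subjects, minus = FALSE)
  rev <- do_one(stats::setNames(rc_chr(unname(subjects)), names(subjects)),
                minus = TRUE)
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}
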