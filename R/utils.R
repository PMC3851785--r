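# Internal helpers shared across modules: circular-coordinate arithmetic,
# string-level codon machinery (the simulator and composition code work on
# plain character vectors; Biostrings objects are built only at alignment
# boundaries), and exact k-mer candidate prescreens for the seeded searches.

`%||%` <- function(x, y) if (is.null(x)) y else x

.datatable.aware <- TRUE

#' Minimal distance between positions on a circular replicon
#'
#' @param a,b numeric positions (same units).
#' @param len replicon length; both positions are taken modulo `len`.
#' @return numeric vector of distances in `[0, len/2]`.
#' @export
circ_dist <- function(a, b, len) {
  d <- abs((a - b) %% len)
  pmin(d, len - d)
}

# signed circular step from a to b, in (-len/2, len/2]
circ_step <- function(a, b, len) {
  ((b - a + len / 2) %% len) - len / 2
}

DNA_BASES <- c("A", "C", "G", "T")

rc_chr <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# codon -> amino acid lookup (standard code; identical codon assignments to
# the bacterial table for translation purposes). Ambiguous codons -> "X".
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.CODON2AA <- NULL # filled lazily (Biostrings data not available at build time)
codon2aa <- function() {
  if (is.null(.CODON2AA)) {
    utils::assignInMyNamespace(".CODON2AA", codon_table())
  }
  .CODON2AA
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# translate a DNA character string; trailing partial codon dropped; stops "*"
translate_chr <- function(seq) {
  cods <- split_codons(toupper(seq))
  if (length(cods) == 0L) return("")
  aa <- codon2aa()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# All six reading-frame translations of a DNA string.
# Returns data.frame(frame, aa) where frame is +1..+3, -1..-3; translations of
# minus frames are taken on the reverse complement (BLAST convention).
six_frames <- function(seq) {
  seq <- toupper(seq)
  rc <- rc_chr(seq)
  frames <- integer(0); aa <- character(0)
  for (f in 1:3) {
    if (nchar(seq) - f + 1L >= 3L) {
      frames <- c(frames, f); aa <- c(aa, translate_chr(substring(seq, f)))
    }
    if (nchar(rc) - f + 1L >= 3L) {
      frames <- c(frames, -f); aa <- c(aa, translate_chr(substring(rc, f)))
    }
  }
  data.frame(frame = frames, aa = aa, stringsAsFactors = FALSE)
}

# exact k-mer candidate pairs between two named sets of sequences;
# returns data.frame(query_id, subject_id, n_shared)
kmer_candidates <- function(seqs_a, seqs_b, k) {
  kmers_of <- function(seqs) {
    km_list <- lapply(seqs, function(s) {
      n <- nchar(s) - k + 1L
      if (n < 1L) return(character(0))
      unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
    })
    data.frame(id = rep(names(seqs), lengths(km_list)),
               kmer = unlist(km_list, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  ka <- kmers_of(seqs_a); kb <- kmers_of(seqs_b)
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      n_shared = integer(0), stringsAsFactors = FALSE)
  if (nrow(ka) == 0L || nrow(kb) == 0L) return(empty)
  # the shared-kmer join can reach tens of millions of rows at genome scale;
  # data.table keeps it tractable
  da <- data.table::data.table(kmer = ka$kmer, query_id = ka$id)
  db <- data.table::data.table(kmer = kb$kmer, subject_id = kb$id)
  m <- merge(da, db, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L) return(empty)
  agg <- m[, list(n_shared = .N), by = c("query_id", "subject_id")]
  agg <- as.data.frame(agg, stringsAsFactors = FALSE)
  agg[order(agg$query_id, agg$subject_id), , drop = FALSE]
}

gc_count <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  sum(s %in% c("G", "C"))
}
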