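# Per-gene and genome-wide divergence metrics: protein alignments with
# codon-wise induced nucleotide alignments, identity distributions, MSA
# trimming and identity matrices, and amplicon classification against a
# reference gene at a fixed identity threshold.

#' Protein and codon-level nucleotide identity of a CDS pair
#'
#' A global (Needleman-Wunsch) protein alignment is built first; the
#' nucleotide alignment is then induced codon-wise from it (each aligned
#' residue pair contributes its three source bases, each protein gap a
#' codon gap), so the nucleotide alignment length is exactly three times
#' the protein alignment length. Identity denominators exclude columns with
#' a gap in either sequence by default (`denominator = "pairwise"`);
#' `"all"` divides by all alignment columns instead.
#'
#' @param cds_a,cds_b in-frame CDS strings (terminal stop codons allowed
#'   and trimmed).
#' @param gene optional gene name used in messages.
#' @param scheme protein [scoring_scheme].
#' @param denominator identity denominator convention.
#' @return data.frame row: `gene, aln_length_bp, protein_identity,
#'   nucleotide_identity`.
#' @export
pair_identity <- function(cds_a, cds_b, gene = NA_character_,
                          scheme = scoring_scheme("protein"),
                          denominator = c("pairwise", "all")) {
  denominator <- match.arg(denominator)
  prep <- function(cds, which) {
    check_inframe(cds)
    aa <- translate_chr(cds)
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE))
      stop(sprintf("internal stop codon in translation of %s (%s)",
                   if (is.na(gene)) which else gene, which))
    list(aa = aa, cod = split_codons(cds)[seq_len(nchar(aa))])
  }
  a <- prep(cds_a, "a"); b <- prep(cds_b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa), type = "global",
    substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aa <- length(pa)
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  cod_a <- ifelse(pa == "-", "---", a$cod[ia])
  cod_b <- ifelse(pb == "-", "---", b$cod[ib])
  both <- pa != "-" & pb != "-"
  prot_den <- if (denominator == "pairwise") sum(both) else ncol_aa
  prot_matches <- sum(pa == pb & both & !(pa %in% nonmatch_letters("protein")))
  na <- unlist(strsplit(cod_a, ""), use.names = FALSE)
  nb <- unlist(strsplit(cod_b, ""), use.names = FALSE)
  nt_both <- na != "-" & nb != "-"
  nt_den <- if (denominator == "pairwise") sum(nt_both) else 3L * ncol_aa
  nt_matches <- sum(na == nb & nt_both & !(na %in% nonmatch_letters("nucleotide")))
  data.frame(gene = gene, aln_length_bp = 3L * ncol_aa,
             protein_identity = 100 * prot_matches / prot_den,
             nucleotide_identity = 100 * nt_matches / nt_den,
             stringsAsFactors = FALSE)
}

#' Identity distribution summary
#'
#' @param identities numeric vector of percent identities (e.g. one per
#'   homolog pair).
#' @return list `median`, `identities`, `density` (a [stats::density]
#'   object, `NULL` for fewer than 2 values).
#' @export
identity_distribution <- function(identities) {
  identities <- identities[!is.na(identities)]
  list(median = stats::median(identities), identities = identities,
       density = if (length(identities) >= 2L) stats::density(identities)
                 else NULL)
}

as_aligned_chr <- function(msa) {
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  widths <- unique(nchar(msa))
  if (length(widths) != 1L) stop("aligned sequences must all have equal length")
  msa
}

#' Trim ragged alignment ends
#'
#' Removes leading columns up to the first column where every sequence is
#' non-gap, and trailing columns likewise; interior columns are untouched.
#' Idempotent.
#'
#' @param msa named character vector of equal-length aligned sequences (or
#'   an `XStringSet`).
#' @return character vector of trimmed aligned sequences.
#' @export
trim_alignment <- function(msa) {
  msa <- as_aligned_chr(msa)
  m <- do.call(rbind, strsplit(msa, ""))
  full <- which(colSums(m == "-") == 0L)
  if (!length(full)) return(substring(msa, 1L, 0L))
  out <- substring(msa, min(full), max(full))
  names(out) <- names(msa)
  out
}

#' Pairwise identity matrix of an alignment
#'
#' For each sequence pair: matches / columns where both are non-gap x 100
#' (pairwise deletion, the default) or over all columns
#' (`denominator = "all"`). Symmetric with a 100 diagonal.
#'
#' @inheritParams trim_alignment
#' @param denominator identity denominator convention.
#' @param alphabet `"DNA"` (N never matches) or `"AA"` (X/* never match).
#' @return numeric matrix of percent identities.
#' @export
identity_matrix <- function(msa, denominator = c("pairwise", "all"),
                            alphabet = c("DNA", "AA")) {
  denominator <- match.arg(denominator)
  alphabet <- match.arg(alphabet)
  nonmatch <- nonmatch_letters(if (alphabet == "DNA") "nucleotide" else "protein")
  msa <- as_aligned_chr(msa)
  n <- length(msa)
  m <- do.call(rbind, strsplit(msa, ""))
  ids <- names(msa) %||% as.character(seq_len(n))
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    den <- if (denominator == "pairwise") sum(both) else ncol(m)
    matches <- sum(m[i, ] == m[j, ] & both & !(m[i, ] %in% nonmatch))
    out[i, j] <- out[j, i] <- 100 * matches / den
  }
  out
}

#' Classify amplicon reads against a reference gene
#'
#' A read is counted as belonging to the reference organism when its best
#' local alignment to the reference (either orientation) reaches at least
#' `threshold` percent identity.
#'
#' @param reads named character vector of read sequences (use
#'   [read_fasta()] for files).
#' @param ref reference gene sequence (e.g. a 16S rRNA gene).
#' @param threshold percent identity (default 98).
#' @param scheme nucleotide [scoring_scheme].
#' @param min_score minimum raw alignment score for a read to be evaluated.
#' @return list `count`, `fraction`, `matched` (logical per read).
#' @export
classify_amplicons <- function(reads, ref, threshold = 98,
                               scheme = scoring_scheme("nucleotide"),
                               min_score = 50) {
  matched <- vapply(reads, function(r) {
    for (s in c(r, rc_chr(r))) {
      h <- local_align(s, ref, scheme, min_score = min_score, max_hsps = 1)
      if (nrow(h) && h$pct_identity[1] >= threshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(count = sum(matched), fraction = mean(matched), matched = matched)
}

#' Divergence-time arithmetic
#'
#' Elementary rate x time helper: age (Myr) implied by a percent divergence
#' under a constant percent-per-Myr rate.
#'
#' @param divergence_pct observed percent divergence.
#' @param rate_pct_per_myr divergence rate, percent per million years.
#' @export
divergence_age <- function(divergence_pct, rate_pct_per_myr) {
  divergence_pct / rate_pct_per_myr
}
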