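# Synteny-aware one-to-one homolog pairing between two strains, orphan
# calling, truncation screens and three-way outgroup consistency checks.
# The pairing procedure is a fixed greedy algorithm: per-query best hit,
# global ascending e-value order, later duplicate subjects discarded.
# E-value ties are broken by higher bit score, then lexicographic query id,
# then subject id, so the result is deterministic.

order_hits <- function(hits) {
  hits[order(hits$e_value, -hits$bit_score, hits$query_id, hits$subject_id), ,
       drop = FALSE]
}

#' One-to-one homolog pairing from a hit table
#'
#' Greedy pairing: for each query keep only its best (lowest e-value) hit;
#' order the retained hits by ascending e-value; walking down that list,
#' discard any pair whose subject has already been used. Genes left unpaired
#' on either side become orphans.
#'
#' @param hits hit table from an A-proteins vs B-proteins search.
#' @param genes_a,genes_b character vectors of gene ids (or [genome_record]s,
#'   whose CDS locus tags are used).
#' @return an object of class `ortholog_map`: list with `pairs` (data.frame
#'   `query_id, subject_id, pct_identity, e_value, bit_score`), `orphans_a`,
#'   `orphans_b`.
#' @export
pair_homologs <- function(hits, genes_a, genes_b) {
  ids_of <- function(x) {
    if (inherits(x, "genome_record")) x$features$locus_tag[x$features$kind == "CDS"]
    else as.character(x)
  }
  genes_a <- ids_of(genes_a); genes_b <- ids_of(genes_b)
  unknown <- c(setdiff(hits$query_id, genes_a), setdiff(hits$subject_id, genes_b))
  if (length(unknown))
    stop("hit table references unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (nrow(hits)) {
    hits <- order_hits(hits)
    best <- hits[!duplicated(hits$query_id), , drop = FALSE]   # per-query best
    best <- best[!duplicated(best$subject_id), , drop = FALSE] # drop reused subjects
    pairs <- best[, c("query_id", "subject_id", "pct_identity", "e_value",
                      "bit_score")]
  } else {
    pairs <- data.frame(query_id = character(0), subject_id = character(0),
                        pct_identity = numeric(0), e_value = numeric(0),
                        bit_score = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 orphans_a = setdiff(genes_a, pairs$query_id),
                 orphans_b = setdiff(genes_b, pairs$subject_id)),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d pairs, %d orphans (A), %d orphans (B)\n",
              nrow(x$pairs), length(x$orphans_a), length(x$orphans_b)))
  if (!is.null(x$pairs$discrepancy))
    cat(sprintf("  synteny fit: median discrepancy %.0f bp, %d flagged for review\n",
                stats::median(x$pairs$discrepancy),
                sum(x$pairs$flag_review)))
  invisible(x)
}

feature_start <- function(g, ids) {
  idx <- match(ids, g$features$locus_tag)
  if (anyNA(idx)) stop("locus tag(s) not found in ", g$id, ": ",
                       paste(ids[is.na(idx)], collapse = ", "))
  g$features$start[idx]
}

#' Fill synteny discrepancies in an ortholog map
#'
#' Fits a global scaled circular offset model for the expected partner
#' coordinate: `expected_b = (scale * coord_a + offset) mod L_b` with
#' `scale = L_b / L_a` and `offset` chosen to minimize the median absolute
#' circular discrepancy over all pairs (robust to a small number of
#' inversions/transpositions). Coordinates are feature starts of the
#' plus-strand representation. The top `review_fraction` of pairs by
#' discrepancy is flagged `manual-review` rather than dropped.
#'
#' @param map an `ortholog_map`.
#' @param g_a,g_b the two [genome_record]s.
#' @param review_fraction fraction of pairs flagged for review (default 0.10).
#' @return the map with `expected_b_coord`, `discrepancy` and `flag_review`
#'   columns added to `pairs`, plus `$synteny_model` (`scale`, `offset`,
#'   `L_a`, `L_b`).
#' @export
synteny_discrepancy <- function(map, g_a, g_b, review_fraction = 0.10) {
  p <- map$pairs
  L_a <- length(g_a); L_b <- length(g_b)
  if (nrow(p) < 3L) {
    p$expected_b_coord <- NA_real_; p$discrepancy <- NA_real_
    p$flag_review <- rep(TRUE, nrow(p))
    map$pairs <- p
    map$synteny_model <- NULL
    return(map)
  }
  ca <- feature_start(g_a, p$query_id)
  cb <- feature_start(g_b, p$subject_id)
  scale <- L_b / L_a
  resid <- (cb - scale * ca) %% L_b
  med_abs <- vapply(resid, function(off) stats::median(circ_dist(resid, off, L_b)),
                    numeric(1))
  offset <- resid[which.min(med_abs)]
  expected <- (scale * ca + offset) %% L_b
  p$expected_b_coord <- expected
  p$discrepancy <- circ_dist(cb, expected, L_b)
  n_flag <- ceiling(review_fraction * nrow(p))
  thr <- sort(p$discrepancy, decreasing = TRUE)[n_flag]
  p$flag_review <- rank(-p$discrepancy, ties.method = "first") <= n_flag
  map$pairs <- p
  map$synteny_model <- list(scale = scale, offset = offset, L_a = L_a, L_b = L_b)
  map
}

#' Expected partner coordinate under a fitted synteny model
#'
#' @param model `$synteny_model` from [synteny_discrepancy()].
#' @param coord_a coordinate(s) in genome A.
#' @export
expected_coord <- function(model, coord_a) {
  (model$scale * coord_a + model$offset) %% model$L_b
}

#' Reversed (inverted) segments in an ortholog map
#'
#' Orders the pairs along genome A and finds maximal runs where the partner
#' coordinate steps backwards in genome B (signed circular step < 0). Runs of
#' at least `min_run` consecutive reversed steps are reported; on a syntenic
#' pair of genomes these correspond to in-place inversions.
#'
#' @param map an `ortholog_map` (after [synteny_discrepancy()] or not).
#' @param g_a,g_b the two [genome_record]s.
#' @param min_run minimum number of reversed steps in a reported segment.
#' @return data.frame `start_a, end_a, n_pairs` (genome-A coordinates).
#' @export
reversed_segments <- function(map, g_a, g_b, min_run = 2L) {
  p <- map$pairs
  if (nrow(p) < 3L)
    return(data.frame(start_a = numeric(0), end_a = numeric(0),
                      n_pairs = integer(0)))
  ca <- feature_start(g_a, p$query_id)
  cb <- feature_start(g_b, p$subject_id)
  ord <- order(ca)
  ca <- ca[ord]; cb <- cb[ord]
  L_b <- length(g_b)
  steps <- circ_step(cb[-length(cb)], cb[-1], L_b)
  rev_run <- rle(steps < 0)
  out <- data.frame(start_a = numeric(0), end_a = numeric(0), n_pairs = integer(0))
  pos <- cumsum(c(1L, rev_run$lengths))
  for (i in seq_along(rev_run$values)) {
    if (rev_run$values[i] && rev_run$lengths[i] >= min_run) {
      i1 <- pos[i]; i2 <- pos[i] + rev_run$lengths[i]
      out <- rbind(out, data.frame(start_a = ca[i1], end_a = ca[i2],
                                   n_pairs = i2 - i1 + 1L))
    }
  }
  out
}

#' Similarity of two ranked hit-id lists
#'
#' Jaccard index of the top-`k` id sets; used to mechanize the manual
#' "dissimilar hit lists" screen as a flag-only check.
#'
#' @param query_hits,subject_hits ranked character vectors of database ids.
#' @param k number of top hits compared.
#' @return similarity in `[0, 1]`.
#' @export
hitlist_similarity <- function(query_hits, subject_hits, k = 10) {
  if (k <= 0) stop("k must be positive")
  a <- unique(utils::head(query_hits, k)); b <- unique(utils::head(subject_hits, k))
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Extend an annotated start site when homology reaches an earlier start codon
#'
#' For a homolog pair with a length difference, checks whether the shorter
#' gene's genome shows in-frame homology to the longer protein upstream of
#' the annotated start, reaching an earlier ATG with no intervening stop
#' codon. If so the start is moved back and the feature is flagged
#' `start-extended`.
#'
#' @param feature_short one feature row (the shorter gene).
#' @param g_short its [genome_record].
#' @param protein_long translation of the longer homolog.
#' @param scheme protein [scoring_scheme].
#' @param max_extension_codons search window upstream of the annotated start.
#' @param min_cover fraction of the candidate extension the alignment must
#'   reach into for the move to be accepted.
#' @return list `feature` (possibly modified), `extended` (logical),
#'   `shift_bases`.
#' @export
extend_start <- function(feature_short, g_short, protein_long,
                         scheme = scoring_scheme("protein"),
                         max_extension_codons = 200, min_cover = 0.8) {
  len <- length(g_short)
  circular <- g_short$topology == "circular"
  # upstream in-frame codons, nearest-first, on the coding strand
  up <- character(0)
  for (i in seq_len(max_extension_codons)) {
    if (feature_short$strand == "+") {
      s <- feature_short$start - 3L * i
      if (s < 0) { if (!circular) break; s <- s %% len }
      cod <- span_seq(g_short, s, s + 3L)
    } else {
      s <- feature_short$end + 3L * (i - 1L)
      if (s + 3L > 2L * len) break
      if (s + 3L > len && !circular) break
      cod <- rc_chr(span_seq(g_short, s %% len, s %% len + 3L))
    }
    up <- c(cod, up) # build 5'->3', furthest first
  }
  if (!length(up)) return(list(feature = feature_short, extended = FALSE,
                               shift_bases = 0L))
  aa_up <- vapply(up, function(cd) codon2aa()[[cd]] %||% "X", character(1))
  n_up <- length(aa_up)
  # candidate = earliest ATG with no stop between it and the annotated start
  stops <- which(aa_up == "*")
  first_ok <- if (length(stops)) max(stops) + 1L else 1L
  atg <- which(up == "ATG")
  atg <- atg[atg >= first_ok]
  if (!length(atg)) return(list(feature = feature_short, extended = FALSE,
                                shift_bases = 0L))
  cand <- min(atg)
  added <- n_up - cand + 1L
  gene_aa <- translate_chr(feature_seq(g_short, feature_short))
  gene_aa <- sub("\\*$", "", gene_aa)
  ext_aa <- paste0(paste(aa_up[cand:n_up], collapse = ""), gene_aa)
  hit <- local_align(protein_long, ext_aa, scheme, min_score = 30, max_hsps = 1)
  if (!nrow(hit)) return(list(feature = feature_short, extended = FALSE,
                              shift_bases = 0L))
  # alignment must reach into the extension
  reach <- added - hit$s_start[1] + 1L
  if (hit$s_start[1] > added || reach < min_cover * added)
    return(list(feature = feature_short, extended = FALSE, shift_bases = 0L))
  shift <- 3L * added
  f <- feature_short
  if (f$strand == "+") f$start <- (f$start - shift) %% len else f$end <- f$end + shift
  if (f$end > len && f$start < len) f$wraps <- TRUE
  list(feature = f, extended = TRUE, shift_bases = shift)
}

#' Flag homolog pairs with a large length difference
#'
#' Pairs whose lengths differ by strictly more than `threshold` (relative to
#' the longer member) are flagged; the signed percent difference is reported
#' relative to the longer gene, so a shorter partner is negative. This is the
#' classic truncation screen used to spot candidate pseudogenes.
#'
#' @param len_a,len_b positive lengths (same units).
#' @param ids optional identifiers carried through.
#' @param threshold flag when `|len_a - len_b| / max(len_a, len_b) >
#'   threshold` (strict; default 0.20).
#' @return data.frame `id, len_a, len_b, pct_diff, flagged`.
#' @export
length_screen <- function(len_a, len_b, ids = NULL, threshold = 0.20) {
  if (any(len_a <= 0) || any(len_b <= 0)) stop("lengths must be positive")
  longer <- pmax(len_a, len_b)
  rel <- abs(len_a - len_b) / longer
  data.frame(id = ids %||% seq_along(len_a), len_a = len_a, len_b = len_b,
             pct_diff = -100 * rel, flagged = rel > threshold,
             stringsAsFactors = FALSE)
}

#' Three-way outgroup consistency of homolog pairs
#'
#' A pair is inconsistent iff both members have a best outgroup hit and
#' those hits differ; a member with no outgroup hit never renders a pair
#' inconsistent (the rule only fires on conflicting evidence).
#'
#' @param map an `ortholog_map`.
#' @param hits_a_out,hits_b_out hit tables of each strain's proteins vs the
#'   outgroup proteins.
#' @return `map$pairs` with columns `outgroup_a, outgroup_b, consistent`.
#' @export
three_way_check <- function(map, hits_a_out, hits_b_out) {
  best_of <- function(hits) {
    if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
    hits <- order_hits(hits)
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
    stats::setNames(hits$subject_id, hits$query_id)
  }
  ba <- best_of(hits_a_out); bb <- best_of(hits_b_out)
  p <- map$pairs
  p$outgroup_a <- unname(ba[p$query_id])
  p$outgroup_b <- unname(bb[p$subject_id])
  p$consistent <- is.na(p$outgroup_a) | is.na(p$outgroup_b) |
    p$outgroup_a == p$outgroup_b
  p
}

#' Presence/absence inventory of marker genes across genomes
#'
#' A marker is present in a genome when an annotated product or locus name
#' matches it (case-insensitive word match), or, if a marker protein
#' sequence is supplied, when some annotated protein aligns to it above the
#' identity threshold.
#'
#' @param genomes named list of [genome_record]s.
#' @param marker_genes character vector of gene names (e.g. `"ftsZ"`).
#' @param marker_seqs optional named character vector of marker protein
#'   sequences (names in `marker_genes`).
#' @param scheme protein [scoring_scheme].
#' @param min_identity percent identity for sequence-based presence.
#' @return logical matrix markers x genomes.
#' @export
inventory_matrix <- function(genomes, marker_genes, marker_seqs = NULL,
                             scheme = scoring_scheme("protein"),
                             min_identity = 40) {
  out <- matrix(FALSE, nrow = length(marker_genes), ncol = length(genomes),
                dimnames = list(marker_genes, names(genomes)))
  if (!length(marker_genes)) return(out)
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    txt <- paste(g$features$product, g$features$locus_tag)
    prots <- g$features$translation[g$features$kind == "CDS"]
    prots <- prots[nzchar(prots)]
    for (mi in seq_along(marker_genes)) {
      name <- marker_genes[mi]
      hit <- any(grepl(paste0("\\b", name, "\\b"), txt, ignore.case = TRUE))
      if (!hit && !is.null(marker_seqs) && name %in% names(marker_seqs) &&
          length(prots)) {
        for (pr in prots) {
          h <- local_align(marker_seqs[[name]], pr, scheme, min_score = 45,
                           max_hsps = 1)
          if (nrow(h) && h$pct_identity[1] >= min_identity) { hit <- TRUE; break }
        }
      }
      out[mi, gi] <- hit
    }
  }
  out
}
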