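# Pseudogene detection and intergenic-decay analysis. Orphan genes from one
# strain are searched (translated) against the partner strain's intergenic
# DNA; a call requires the hits to group into a compact locus no larger than
# the query and to sit where the genome-wide synteny model predicts.
# Residual intergenic regions are additionally screened against a protein
# database for decayed genes missing from both annotations.

# circular span of a set of [lo, hi] intervals (genome coordinates, mod L):
# the shortest arc covering all of them, plus its center point
circular_span <- function(lo, hi, L) {
  lo <- lo %% L; hi <- hi %% L
  pts <- sort(unique(c(lo, hi)))
  if (length(pts) == 1L) return(list(span = max(hi - lo), center = pts[1]))
  gaps <- diff(c(pts, pts[1] + L))
  gi <- which.max(gaps)
  span <- L - gaps[gi]
  center <- (pts[(gi %% length(pts)) + 1L] + span / 2) %% L
  list(span = span, center = center)
}

# map region-local hit subject coordinates to genome coordinates
hit_genome_coords <- function(hits, regions) {
  idx <- match(hits$subject_id, regions$region_id)
  if (anyNA(idx)) stop("hit subject(s) not found among regions")
  lo_local <- pmin(hits$s_start, hits$s_end)
  hi_local <- pmax(hits$s_start, hits$s_end)
  data.frame(lo = regions$start[idx] + lo_local - 1L,
             hi = regions$start[idx] + hi_local - 1L)
}

#' Call a pseudogene from an orphan gene's translated hits
#'
#' Hits are grouped per subject region and chained into locus clusters
#' (consecutive hits joining a cluster while the gap between them is at
#' most the orphan's length, so a decayed copy scattered across a wide
#' area still registers as one wide locus, while isolated stray HSPs far
#' away form their own clusters and cannot veto a compact one). A call is
#' made iff some cluster (i) has at least one hit, (ii) spans a subject
#' locus no larger than `span_tolerance` times the orphan's nucleotide
#' length, and (iii) lies within `window` (circular distance) of the
#' coordinate the synteny model — or an explicitly supplied `expected`
#' coordinate — predicts for the orphan. Among qualifying clusters the one
#' with the highest summed bit score is reported. Frameshifts are counted
#' as the number of distinct subject frames in that cluster minus one;
#' in-frame stops are counted in the best frame (highest summed bit
#' score).
#'
#' @param orphan one feature row of the orphan gene (strain A annotation).
#' @param hits translated-search hits of the orphan protein against the
#'   partner strain's intergenic regions (needs `frame_s`).
#' @param regions intergenic region table of the partner strain
#'   (from [extract_intergenic()]).
#' @param synteny_model `$synteny_model` from [synteny_discrepancy()].
#' @param span_tolerance locus span allowance relative to the query length
#'   (default 1.0, the literal "not larger than the query").
#' @param window synteny window in bases (default 20 kb).
#' @param expected optional expected subject coordinate overriding the
#'   global model's prediction (e.g. a locally interpolated one).
#' @return a `pseudogene_call` (list) or `NULL` when the criteria fail.
#' @export
call_pseudogene_from_orphan <- function(orphan, hits, regions, synteny_model,
                                        span_tolerance = 1.0, window = 20000,
                                        expected = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  L <- synteny_model$L_b
  orphan_len <- orphan$end - orphan$start
  exp_b <- expected %||% expected_coord(synteny_model, orphan$start)
  best <- NULL; best_score <- -Inf
  for (rid in unique(hits$subject_id)) {
    grp <- hits[hits$subject_id == rid, , drop = FALSE]
    gc_ <- hit_genome_coords(grp, regions)
    ord <- order(gc_$lo)
    grp <- grp[ord, , drop = FALSE]
    lo <- gc_$lo[ord]; hi <- gc_$hi[ord]
    # chain hits into locus clusters (gap <= orphan length joins)
    cluster <- cumsum(c(1L, as.integer(lo[-1] > cummax(hi)[-length(hi)] +
                                         orphan_len)))
    for (cl in unique(cluster)) {
      sel <- cluster == cl
      cs <- circular_span(lo[sel], hi[sel], L)
      if (cs$span > orphan_len * span_tolerance) next
      disc <- circ_dist(cs$center, exp_b, L)
      if (disc > window) next
      sc <- sum(grp$bit_score[sel])
      if (sc > best_score) { best <- grp[sel, , drop = FALSE]
                             best_score <- sc; best_cs <- cs
                             best_disc <- disc }
    }
  }
  if (is.null(best)) return(NULL)
  hits <- best; cs <- best_cs; disc <- best_disc

  frames <- unique(hits$frame_s)
  best_frame <- frames[which.max(vapply(frames, function(f)
    sum(hits$bit_score[hits$frame_s == f]), numeric(1)))]
  # in-frame stops over the hit span in the best frame
  bh <- hits[hits$frame_s == best_frame, , drop = FALSE]
  reg <- regions[match(bh$subject_id[1], regions$region_id), ]
  lo <- min(pmin(bh$s_start, bh$s_end)); hi <- max(pmax(bh$s_start, bh$s_end))
  seg <- substring(reg$sequence, lo, hi)
  if (best_frame < 0) seg <- rc_chr(seg)
  aa <- translate_chr(seg)
  stops <- sum(strsplit(aa, "")[[1]] == "*")
  # GC over the full hit locus within the best region (the decayed gene
  # itself, not the flanking spacer DNA of the merged intergenic region)
  in_reg <- hits$subject_id == reg$region_id
  lo_all <- min(pmin(hits$s_start, hits$s_end)[in_reg])
  hi_all <- max(pmax(hits$s_start, hits$s_end)[in_reg])
  locus_seq <- substring(reg$sequence, lo_all, hi_all)

  structure(list(
    region = reg, evidence = "orphan-tblastn", supporting_hits = hits,
    nearest_homolog = orphan$locus_tag, locus_center = cs$center,
    locus_span = cs$span, discrepancy = disc,
    frameshift_count = length(frames) - 1L, inframe_stop_count = stops,
    strand = if (best_frame > 0) "+" else "-",
    gc_pct = 100 * gc_count(locus_seq) / nchar(locus_seq)),
    class = "pseudogene_call")
}

#' Call a pseudogene from an intergenic region's protein-database hits
#'
#' A region is called a pseudogene iff its best qualifying translated hit
#' has `e_value < e_cutoff` (default 1e-3) against a subject whose title
#' does not contain "hypothetical" (case-insensitive). Taxonomic filtering
#' of imported hit tables is the caller's responsibility.
#'
#' @param region one intergenic region row.
#' @param hits translated hits of the region against a protein database
#'   (subject ids are titles).
#' @param e_cutoff e-value threshold.
#' @return a `pseudogene_call` or `NULL`.
#' @export
call_pseudogene_from_intergenic <- function(region, hits, e_cutoff = 1e-3) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ok <- hits[!grepl("hypothetical", hits$subject_id, ignore.case = TRUE), ,
             drop = FALSE]
  if (!nrow(ok)) return(NULL)
  ok <- order_hits(ok)
  if (ok$e_value[1] >= e_cutoff) return(NULL)
  grp <- ok[ok$subject_id == ok$subject_id[1], , drop = FALSE]
  frames <- if ("frame_q" %in% names(grp)) unique(grp$frame_q) else 0L
  best_frame <- if ("frame_q" %in% names(grp)) {
    frames[which.max(vapply(frames, function(f)
      sum(grp$bit_score[grp$frame_q == f]), numeric(1)))]
  } else 1L
  lo <- min(pmin(grp$q_start, grp$q_end)); hi <- max(pmax(grp$q_start, grp$q_end))
  seg <- substring(region$sequence, lo, hi)
  if (best_frame < 0) seg <- rc_chr(seg)
  stops <- sum(strsplit(translate_chr(seg), "")[[1]] == "*")
  structure(list(
    region = region, evidence = "intergenic-blastx", supporting_hits = grp,
    nearest_homolog = ok$subject_id[1], locus_center = region$midpoint,
    locus_span = hi - lo + 1L, discrepancy = NA_real_,
    frameshift_count = length(frames) - 1L, inframe_stop_count = stops,
    strand = if (best_frame > 0) "+" else "-",
    gc_pct = 100 * gc_count(region$sequence) / nchar(region$sequence)),
    class = "pseudogene_call")
}

#' @export
print.pseudogene_call <- function(x, ...) {
  cat(sprintf(
    "<pseudogene_call> %s [%s]: nearest homolog %s, %d frameshift(s), %d in-frame stop(s), GC %.1f%%\n",
    x$region$region_id, x$evidence, x$nearest_homolog, x$frameshift_count,
    x$inframe_stop_count, x$gc_pct))
  invisible(x)
}

#' Length-weighted mean identity of grouped translated hits
#'
#' Translated searches yield several HSPs between the same query/subject
#' pair (different reading frames); this groups them and computes the mean
#' percent identity weighted by alignment length,
#' `sum(identity * length) / sum(length)`.
#'
#' @param hits hit table.
#' @return data.frame `query_id, subject_id, weighted_identity,
#'   total_aln_length, n_hsps`.
#' @export
aggregate_translated_hits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      weighted_identity = numeric(0), total_aln_length = integer(0),
                      n_hsps = integer(0), stringsAsFactors = FALSE))
  key <- interaction(hits$query_id, hits$subject_id, drop = TRUE, sep = "\r")
  w <- tapply(hits$pct_identity * hits$aln_length, key, sum)
  l <- tapply(hits$aln_length, key, sum)
  n <- tapply(hits$aln_length, key, length)
  ks <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(query_id = vapply(ks, `[`, "", 1),
                    subject_id = vapply(ks, `[`, "", 2),
                    weighted_identity = as.numeric(w / l),
                    total_aln_length = as.integer(l), n_hsps = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Intergenic synteny scan between two strains
#'
#' Nucleotide mode reports the top hit per query region; translated mode
#' aggregates frame-wise HSPs into a length-weighted identity per region
#' pair. Each point carries the two region midpoints for dot plots. On
#' heavily decayed intergenic DNA the translated mode retains syntenic
#' signal long after nucleotide-level similarity has disappeared.
#'
#' In nucleotide mode each query region contributes its top hit. In
#' translated mode frame-wise HSPs are aggregated per region pair and, by
#' default, reduced to a greedy one-to-one matching in descending order of
#' summed bit score (each region keeps at most its strongest partner):
#' decayed gene relics pair one-to-one, and the reduction suppresses the
#' isolated weak frame matches that an exhaustive translated all-vs-all
#' scan inevitably produces between unrelated AT-rich regions.
#'
#' @param regions_a,regions_b intergenic region tables
#'   (from [extract_intergenic()]).
#' @param mode `"nucleotide"` or `"translated"`.
#' @param e_cutoff hit e-value ceiling (default 10).
#' @param min_score minimum raw HSP score (passed to the search).
#' @param k seed size (nucleotide or amino-acid, per mode).
#' @param reduce pair reduction for translated mode: `"reciprocal"`
#'   (default), `"query-best"` or `"none"`.
#' @return data.frame `query_id, subject_id, midpoint_a, midpoint_b,
#'   weighted_identity, total_aln_length`.
#' @export
intergenic_synteny <- function(regions_a, regions_b,
                               mode = c("nucleotide", "translated"),
                               e_cutoff = 10, min_score = NULL, k = NULL,
                               reduce = c("reciprocal", "query-best", "none")) {
  mode <- match.arg(mode)
  reduce <- match.arg(reduce)
  seqs_a <- stats::setNames(regions_a$sequence, regions_a$region_id)
  seqs_b <- stats::setNames(regions_b$sequence, regions_b$region_id)
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      midpoint_a = numeric(0), midpoint_b = numeric(0),
                      weighted_identity = numeric(0),
                      total_aln_length = integer(0), stringsAsFactors = FALSE)
  if (!length(seqs_a) || !length(seqs_b)) return(empty)
  if (mode == "nucleotide") {
    hits <- search_blastn(seqs_a, seqs_b, k = k %||% 12,
                          min_score = min_score %||% 50)
    hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
    if (!nrow(hits)) return(empty)
    hits <- order_hits(hits)
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE] # top hit per query
    agg <- data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
                      weighted_identity = hits$pct_identity,
                      total_aln_length = hits$aln_length, stringsAsFactors = FALSE)
  } else {
    hits <- search_tblastx(seqs_a, seqs_b, k = k %||% 5,
                           min_score = min_score %||% 35)
    hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
    if (!nrow(hits)) return(empty)
    agg <- aggregate_translated_hits(hits)
    key <- paste(hits$query_id, hits$subject_id)
    bit_sum <- tapply(hits$bit_score, key, sum)
    agg$bit_sum <- as.numeric(bit_sum[paste(agg$query_id, agg$subject_id)])
    if (reduce != "none") {
      ord <- order(-agg$bit_sum, agg$query_id, agg$subject_id)
      agg <- agg[ord, , drop = FALSE]
      agg <- agg[!duplicated(agg$query_id), , drop = FALSE]
      if (reduce == "reciprocal")
        agg <- agg[!duplicated(agg$subject_id), , drop = FALSE]
    }
    agg$bit_sum <- NULL
  }
  agg$midpoint_a <- regions_a$midpoint[match(agg$query_id, regions_a$region_id)]
  agg$midpoint_b <- regions_b$midpoint[match(agg$subject_id, regions_b$region_id)]
  rownames(agg) <- NULL
  agg[, c("query_id", "subject_id", "midpoint_a", "midpoint_b",
          "weighted_identity", "total_aln_length")]
}

#' Stop-codon positions per frame and windowed GC content
#'
#' Reports the 0-based start positions of TAA/TAG/TGA codons in the three
#' forward frames of the given orientation, plus GC percent in consecutive
#' windows — the machinery behind stop-codon/GC genome maps of decayed
#' regions.
#'
#' @param seq DNA string.
#' @param window window width in bases (default 100).
#' @return object of class `stop_frame_map`: list with `stops` (list of
#'   three integer vectors, frames 0..2), `gc` (data.frame `start, end,
#'   gc_pct`; 0-based half-open), `length`.
#' @export
stop_frame_map <- function(seq, window = 100) {
  seq <- toupper(seq)
  n <- nchar(seq)
  cods <- substring(seq, seq_len(max(n - 2L, 0L)),
                    seq_len(max(n - 2L, 0L)) + 2L)
  is_stop <- cods %in% c("TAA", "TAG", "TGA")
  pos0 <- which(is_stop) - 1L
  stops <- lapply(0:2, function(f) pos0[pos0 %% 3L == f])
  names(stops) <- paste0("frame", 0:2)
  starts <- seq(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  gc <- vapply(seq_along(starts), function(i)
    100 * gc_count(substring(seq, starts[i] + 1L, ends[i])) /
      (ends[i] - starts[i]), numeric(1))
  structure(list(stops = stops,
                 gc = data.frame(start = starts, end = ends, gc_pct = gc),
                 length = n),
            class = "stop_frame_map")
}

#' @export
print.stop_frame_map <- function(x, ...) {
  cat(sprintf("<stop_frame_map> %d bp; stops per frame: %s; mean GC %.1f%%\n",
              x$length, paste(lengths(x$stops), collapse = "/"),
              mean(x$gc$gc_pct)))
  invisible(x)
}
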