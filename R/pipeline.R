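# Orchestration: ties homolog pairing, synteny, orphan and pseudogene
# calling, intergenic decay, composition strata and divergence statistics
# into one comparative report. Every numeric threshold lives in
# analysis_config() and the full configuration is attached to the report;
# nothing is filtered silently - dropped genes/hits/regions are counted in
# the report log.

#' Analysis configuration
#'
#' Central home of every threshold the comparative analysis uses.
#'
#' @param min_intergenic_len intergenic regions below this are dropped (bp).
#' @param length_screen_threshold truncation-screen fraction (strict >).
#' @param pseudogene_evalue e-value cutoff for intergenic-vs-protein
#'   pseudogene calls.
#' @param amplicon_identity percent identity for amplicon classification.
#' @param orphan_min_len orphans below this length (bp) with no similarity
#'   support can be dropped from gene inventories.
#' @param hit_evalue_ceiling e-value ceiling applied to search hits.
#' @param read_recruitment_evalue e-value used when importing external
#'   read-recruitment hit tables (import-only; no internal use).
#' @param review_fraction top fraction of synteny discrepancies flagged.
#' @param synteny_window pseudogene synteny window (bp).
#' @param span_tolerance pseudogene locus span allowance vs query length.
#' @param seed optional integer seed funneled to any randomized step.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(min_intergenic_len = 100,
                            length_screen_threshold = 0.20,
                            pseudogene_evalue = 1e-3,
                            amplicon_identity = 98,
                            orphan_min_len = 300,
                            hit_evalue_ceiling = 10,
                            read_recruitment_evalue = 1e-30,
                            review_fraction = 0.10,
                            synteny_window = 20000,
                            span_tolerance = 1.0,
                            seed = NULL) {
  cfg <- list(min_intergenic_len = min_intergenic_len,
              length_screen_threshold = length_screen_threshold,
              pseudogene_evalue = pseudogene_evalue,
              amplicon_identity = amplicon_identity,
              orphan_min_len = orphan_min_len,
              hit_evalue_ceiling = hit_evalue_ceiling,
              read_recruitment_evalue = read_recruitment_evalue,
              review_fraction = review_fraction,
              synteny_window = synteny_window,
              span_tolerance = span_tolerance,
              seed = seed)
  num <- vapply(cfg[setdiff(names(cfg), "seed")], is.numeric, logical(1))
  if (!all(num) || any(unlist(cfg[setdiff(names(cfg), "seed")]) <= 0))
    stop("all thresholds must be positive numbers")
  structure(cfg, class = "analysis_config")
}

cds_proteins <- function(g) {
  f <- g$features[g$features$kind == "CDS", , drop = FALSE]
  prot <- f$translation
  fix <- which(!nzchar(prot))
  for (i in fix)
    prot[i] <- sub("\\*$", "", translate_chr(feature_seq(g, f[i, ])))
  stats::setNames(prot, f$locus_tag)
}

cds_sequences <- function(g) {
  f <- g$features[g$features$kind == "CDS", , drop = FALSE]
  stats::setNames(vapply(seq_len(nrow(f)), function(i)
    feature_seq(g, f[i, ]), character(1)), f$locus_tag)
}

invert_synteny_model <- function(model) {
  list(scale = 1 / model$scale,
       offset = (-model$offset / model$scale) %% model$L_a,
       L_a = model$L_b, L_b = model$L_a)
}

# translated search of one strain's orphans against the partner's intergenic
# regions, restricted to a candidate neighbourhood. The expected locus is
# interpolated from the nearest *paired* gene's partner coordinate rather
# than the global offset model: neighbours move with inversions, so a
# decayed copy inside an inverted segment is still looked for (and found)
# at its true syntenic position.
orphan_pseudogene_calls <- function(orphans, g_from, g_to, regions_to, map,
                                    model, cfg, scheme, from_is_query) {
  calls <- list()
  if (is.null(model) || !length(orphans)) return(calls)
  f <- g_from$features
  p <- map$pairs
  if (from_is_query) {
    anchor_from <- feature_start(g_from, p$query_id)
    anchor_to <- feature_start(g_to, p$subject_id)
  } else {
    anchor_from <- feature_start(g_from, p$subject_id)
    anchor_to <- feature_start(g_to, p$query_id)
  }
  L_from <- length(g_from)
  for (tag in orphans) {
    feat <- f[f$locus_tag == tag, , drop = FALSE]
    if (!nrow(feat) || feat$kind[1] != "CDS") next
    feat <- feat[1, ]
    prot <- if (nzchar(feat$translation)) feat$translation
            else sub("\\*$", "", translate_chr(feature_seq(g_from, feat)))
    exp_b <- if (nrow(p)) {
      nn <- which.min(circ_dist(anchor_from, feat$start, L_from))
      anchor_to[nn]
    } else expected_coord(model, feat$start)
    near <- circ_dist(regions_to$midpoint, exp_b, model$L_b) <=
      cfg$synteny_window + regions_to$length / 2 + (feat$end - feat$start)
    cand <- regions_to[near, , drop = FALSE]
    if (!nrow(cand)) next
    hits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      translated_search(prot, cand$sequence[i], scheme, mode = "tblastn",
                        min_score = 60, query_id = tag,
                        subject_id = cand$region_id[i])))
    hits <- hits[hits$e_value <= cfg$hit_evalue_ceiling, , drop = FALSE]
    call <- call_pseudogene_from_orphan(feat, hits, cand, model,
                                        span_tolerance = cfg$span_tolerance,
                                        window = cfg$synteny_window,
                                        expected = exp_b)
    if (!is.null(call)) calls[[tag]] <- call
  }
  calls
}

#' Run the full two-strain comparative analysis
#'
#' Executes homolog pairing, synteny fitting, orphan calling, synteny-aware
#' pseudogene detection from orphans, intergenic synteny in both nucleotide
#' and translated modes, GC stratification of genome compartments
#' (pseudogene-bearing intergenic regions are removed from the intergenic
#' stratum first) and per-pair divergence statistics.
#'
#' @param g_a,g_b annotated [genome_record]s of the two strains.
#' @param outgroup optional outgroup [genome_record] for the three-way
#'   consistency check (skipped with a logged notice when absent).
#' @param cfg an [analysis_config].
#' @param intergenic_modes which intergenic synteny scans to run.
#' @param drop_short_orphans drop orphans shorter than
#'   `cfg$orphan_min_len` that gathered no similarity support from the
#'   orphan/pseudogene search (never silent: the count is logged).
#' @return object of class `comparative_report`.
#' @export
run_comparative <- function(g_a, g_b, outgroup = NULL, cfg = analysis_config(),
                            intergenic_modes = c("nucleotide", "translated"),
                            drop_short_orphans = FALSE) {
  scheme_p <- scoring_scheme("protein")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  prot_a <- cds_proteins(g_a); prot_b <- cds_proteins(g_b)
  note("proteins: %d (%s), %d (%s)", length(prot_a), g_a$id, length(prot_b), g_b$id)

  hits <- search_proteins(prot_a, prot_b, scheme_p)
  n0 <- nrow(hits)
  hits <- hits[hits$e_value <= cfg$hit_evalue_ceiling, , drop = FALSE]
  note("protein search: %d HSPs (%d above e-value ceiling dropped)",
       nrow(hits), n0 - nrow(hits))

  map <- pair_homologs(hits, names(prot_a), names(prot_b))
  map <- synteny_discrepancy(map, g_a, g_b, cfg$review_fraction)
  note("pairs: %d; orphans: %d (%s), %d (%s)", nrow(map$pairs),
       length(map$orphans_a), g_a$id, length(map$orphans_b), g_b$id)

  inversions <- reversed_segments(map, g_a, g_b)
  note("reversed segments: %d", nrow(inversions))

  cds_a <- cds_sequences(g_a); cds_b <- cds_sequences(g_b)
  lens_a <- nchar(cds_a[map$pairs$query_id])
  lens_b <- nchar(cds_b[map$pairs$subject_id])
  lscreen <- if (nrow(map$pairs))
    length_screen(lens_a, lens_b, ids = map$pairs$query_id,
                  threshold = cfg$length_screen_threshold)
  else NULL

  identities <- if (nrow(map$pairs)) {
    do.call(rbind, lapply(seq_len(nrow(map$pairs)), function(i)
      pair_identity(cds_a[[map$pairs$query_id[i]]],
                    cds_b[[map$pairs$subject_id[i]]],
                    gene = map$pairs$query_id[i], scheme = scheme_p)))
  } else NULL
  idist <- identity_distribution(identities$protein_identity %||% numeric(0))

  regions_a <- extract_intergenic(g_a, cfg$min_intergenic_len)
  regions_b <- extract_intergenic(g_b, cfg$min_intergenic_len)
  note("intergenic regions >= %d bp: %d (%s), %d (%s)", cfg$min_intergenic_len,
       nrow(regions_a), g_a$id, nrow(regions_b), g_b$id)

  model_ab <- map$synteny_model
  model_ba <- if (!is.null(model_ab)) invert_synteny_model(model_ab) else NULL
  pseudo_b <- orphan_pseudogene_calls(map$orphans_a, g_a, g_b, regions_b, map,
                                      model_ab, cfg, scheme_p,
                                      from_is_query = TRUE)
  pseudo_a <- orphan_pseudogene_calls(map$orphans_b, g_b, g_a, regions_a, map,
                                      model_ba, cfg, scheme_p,
                                      from_is_query = FALSE)
  note("pseudogene calls: %d in %s, %d in %s", length(pseudo_a), g_a$id,
       length(pseudo_b), g_b$id)

  if (drop_short_orphans) {
    shorten <- function(orphans, g, supported) {
      f <- g$features[match(orphans, g$features$locus_tag), ]
      drop <- (f$end - f$start) < cfg$orphan_min_len & !orphans %in% supported
      note("short unsupported orphans dropped from %s: %d", g$id, sum(drop))
      orphans[!drop]
    }
    map$orphans_a <- shorten(map$orphans_a, g_a, names(pseudo_b))
    map$orphans_b <- shorten(map$orphans_b, g_b, names(pseudo_a))
  }

  pseudo_regions_a <- vapply(pseudo_a, function(x) x$region$region_id, character(1))
  pseudo_regions_b <- vapply(pseudo_b, function(x) x$region$region_id, character(1))
  clean_a <- regions_a[!regions_a$region_id %in% pseudo_regions_a, , drop = FALSE]
  clean_b <- regions_b[!regions_b$region_id %in% pseudo_regions_b, , drop = FALSE]
  note("intergenic regions with pseudogenes removed before composition: %d + %d",
       length(pseudo_regions_a), length(pseudo_regions_b))

  intergenic <- list()
  for (m in intergenic_modes)
    intergenic[[m]] <- intergenic_synteny(regions_a, regions_b, mode = m,
                                          e_cutoff = cfg$hit_evalue_ceiling)

  # GC strata (coding / pseudogene / intergenic / RNA, per strain)
  strata <- rbind(
    data.frame(gc = gc_percent(cds_a), category = "coding", strain = g_a$id),
    data.frame(gc = gc_percent(cds_b), category = "coding", strain = g_b$id),
    if (nrow(clean_a)) data.frame(gc = gc_percent(clean_a$sequence),
                                  category = "intergenic", strain = g_a$id),
    if (nrow(clean_b)) data.frame(gc = gc_percent(clean_b$sequence),
                                  category = "intergenic", strain = g_b$id),
    if (length(pseudo_a)) data.frame(
      gc = vapply(pseudo_a, `[[`, numeric(1), "gc_pct"),
      category = "pseudogene", strain = g_a$id),
    if (length(pseudo_b)) data.frame(
      gc = vapply(pseudo_b, `[[`, numeric(1), "gc_pct"),
      category = "pseudogene", strain = g_b$id))
  rna_gc <- function(g) {
    f <- g$features[g$features$kind %in% c("rRNA", "tRNA", "other-RNA"), ,
                    drop = FALSE]
    if (!nrow(f)) return(NULL)
    data.frame(gc = gc_percent(vapply(seq_len(nrow(f)), function(i)
      feature_seq(g, f[i, ]), character(1))), category = "RNA", strain = g$id)
  }
  strata <- rbind(strata, rna_gc(g_a), rna_gc(g_b))
  strata_test <- tryCatch(
    classify_gc_strata(strata$gc, strata$category, strata$strain),
    error = function(e) { note("GC strata test skipped: %s", conditionMessage(e)); NULL })

  three_way <- NULL
  if (!is.null(outgroup)) {
    prot_o <- cds_proteins(outgroup)
    three_way <- three_way_check(
      map,
      search_proteins(prot_a, prot_o, scheme_p),
      search_proteins(prot_b, prot_o, scheme_p))
    note("three-way outgroup check: %d inconsistent pair(s)",
         sum(!three_way$consistent))
  } else note("no outgroup supplied; three-way check skipped")

  structure(list(
    config = cfg, genome_a = g_a$id, genome_b = g_b$id,
    ortholog_map = map, inversions = inversions, length_screen = lscreen,
    identities = identities, identity_distribution = idist,
    regions_a = regions_a, regions_b = regions_b,
    pseudogenes_a = pseudo_a, pseudogenes_b = pseudo_b,
    intergenic = intergenic, strata = strata, strata_test = strata_test,
    three_way = three_way, log = log),
    class = "comparative_report")
}

#' @export
print.comparative_report <- function(x, ...) {
  cat(sprintf("<comparative_report> %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  homolog pairs: %d (median protein identity %.1f%%)\n",
              nrow(x$ortholog_map$pairs), x$identity_distribution$median))
  cat(sprintf("  orphans: %d / %d; pseudogene calls: %d / %d\n",
              length(x$ortholog_map$orphans_a), length(x$ortholog_map$orphans_b),
              length(x$pseudogenes_a), length(x$pseudogenes_b)))
  cat(sprintf("  reversed segments: %d\n", nrow(x$inversions)))
  for (m in names(x$intergenic))
    cat(sprintf("  intergenic synteny points (%s): %d\n", m,
                nrow(x$intergenic[[m]])))
  if (!is.null(x$strata_test))
    cat(sprintf("  GC strata ANOVA p = %.3g over groups: %s\n",
                x$strata_test$p_overall,
                paste(unique(x$strata_test$groups), collapse = ", ")))
  invisible(x)
}

#' Write the report's tables as TSV files
#'
#' Emits the flat-file surface of a comparative run: homolog pairs with
#' dot-plot coordinates and review flags, orphan lists, pseudogene calls
#' (coordinates, strand, nearest homolog, disruption counts, GC),
#' intergenic synteny points per mode, per-pair identities, and the GC
#' strata table.
#'
#' @param report a `comparative_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files[[name]] <<- path
  }
  emit(report$ortholog_map$pairs, "pairs")
  emit(data.frame(locus_tag = report$ortholog_map$orphans_a), "orphans_a")
  emit(data.frame(locus_tag = report$ortholog_map$orphans_b), "orphans_b")
  ps_table <- function(calls) {
    if (!length(calls))
      return(data.frame(region_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        nearest_homolog = character(0), evidence = character(0),
                        frameshifts = integer(0), inframe_stops = integer(0),
                        gc_pct = numeric(0)))
    do.call(rbind, lapply(calls, function(x) data.frame(
      region_id = x$region$region_id, start = x$region$start,
      end = x$region$end, strand = x$strand,
      nearest_homolog = x$nearest_homolog, evidence = x$evidence,
      frameshifts = x$frameshift_count, inframe_stops = x$inframe_stop_count,
      gc_pct = x$gc_pct, stringsAsFactors = FALSE)))
  }
  emit(ps_table(report$pseudogenes_a), "pseudogenes_a")
  emit(ps_table(report$pseudogenes_b), "pseudogenes_b")
  for (m in names(report$intergenic))
    emit(report$intergenic[[m]], paste0("intergenic_", m))
  if (!is.null(report$identities)) emit(report$identities, "identities")
  emit(report$strata, "gc_strata")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(files)
}

#' Composition-based contig screen with report
#'
#' @param profiles per-ORF composition table (`contig, gc, gc2, gc4, cai`);
#'   see [composition_profile()].
#' @param cfg an [analysis_config].
#' @return list from [contig_screen()] plus the config used.
#' @export
run_contig_screen <- function(profiles, cfg = analysis_config()) {
  if (is.null(profiles) || !nrow(profiles)) stop("empty contig profile set")
  res <- contig_screen(profiles, alpha = 0.05)
  res$config <- cfg
  res
}
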