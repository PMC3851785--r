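#' Annotated genome records
#'
#' `genome_record()` builds the package's central container: one (typically
#' circular) replicon with an ordered table of gene features. All internal
#' coordinates are 0-based half-open; file dialects (GenBank 1-based
#' inclusive, BLAST-style tabular hits) are converted at the read/write
#' boundary so that synteny arithmetic uses a single convention.
#'
#' A feature that wraps the circular origin is stored with `end > length(g)`
#' (i.e. `end = wrapped_end + length`) and `wraps = TRUE`, so
#' `end - start` is always the feature length.
#'
#' @param id replicon identifier.
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param topology `"circular"` or `"linear"`.
#' @param features `data.frame` with columns `locus_tag, start, end, strand,
#'   kind, product, translation, wraps`; `kind` is one of
#'   `CDS, rRNA, tRNA, other-RNA, pseudo`.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          features = empty_features()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("sequence letters must be in {A,C,G,T,N}")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  miss <- setdiff(names(empty_features()), names(features))
  if (length(miss)) stop("features missing columns: ", paste(miss, collapse = ", "))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  bad <- features$start < 0 | features$start >= len | features$end <= features$start |
    (features$end > len & !features$wraps) | features$end > 2L * len
  if (any(bad))
    stop("feature(s) outside sequence: ", paste(features$locus_tag[bad], collapse = ", "))
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "genome_record")
}

#' @export
length.genome_record <- function(x) nchar(x$sequence)

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d features\n",
              x$id, format(length(x), big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features))
    print(table(kind = x$features$kind))
  invisible(x)
}

#' @rdname genome_record
#' @export
empty_features <- function() {
  data.frame(locus_tag = character(0), start = integer(0), end = integer(0),
             strand = character(0), kind = character(0), product = character(0),
             translation = character(0), wraps = logical(0),
             stringsAsFactors = FALSE)
}

# sequence of a feature/region on the forward strand, honouring origin wrap
span_seq <- function(g, start, end) {
  len <- length(g)
  if (end <= len) return(substring(g$sequence, start + 1L, end))
  paste0(substring(g$sequence, start + 1L, len), substring(g$sequence, 1L, end - len))
}

#' Extract the DNA of a feature in its coding orientation
#'
#' @param g a [genome_record].
#' @param feature one row of `g$features`.
#' @return DNA string (reverse-complemented for `-` strand features).
#' @export
feature_seq <- function(g, feature) {
  s <- span_seq(g, feature$start, feature$end)
  if (feature$strand == "-") rc_chr(s) else s
}

# ---------------------------------------------------------------------------
# GenBank flat file

#' Read a GenBank flat file
#'
#' Parses the minimal GenBank dialect this pipeline consumes and emits: LOCUS
#' (length and topology), FEATURES with `CDS`, `rRNA`, `tRNA` and other RNA
#' keys (locations as `a..b`, `complement(...)` and origin-wrapping
#' `join(a..b,c..d)`), and the ORIGIN sequence block. Features carrying a
#' `/pseudo` qualifier are typed `pseudo`. GenBank 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @return a [genome_record].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence block: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank record has an empty ORIGIN block: ", path)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart) && fstart[1] + 1L < ori[1]) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    key_idx <- grep("^ {5}\\S", block)
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1])
      kind <- switch(key, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                     ncRNA = "other-RNA", misc_RNA = "other-RNA", tmRNA = "other-RNA",
                     NA_character_)
      if (is.na(kind)) next
      body <- paste(trimws(chunk), collapse = "\n")
      loc_txt <- sub("^\\S+\\s+", "", trimws(chunk[1]))
      j <- 2L
      while (j <= length(chunk) && !grepl("^\\s*/", chunk[j])) {
        loc_txt <- paste0(loc_txt, trimws(chunk[j])); j <- j + 1L
      }
      loc <- parse_gb_location(loc_txt, nchar(sequence))
      qual <- function(name) {
        m <- regmatches(body, regexpr(sprintf('/%s="[^"]*"', name), body))
        if (!length(m)) return("")
        gsub("\\s+", " ", sub(sprintf('/%s="', name), "", sub('"$', "", m)))
      }
      translation <- gsub(" ", "", qual("translation"))
      pseudo <- grepl("/pseudo(\\b|$)", body)
      feats <- rbind(feats, data.frame(
        locus_tag = qual("locus_tag"), start = loc$start, end = loc$end,
        strand = loc$strand, kind = if (pseudo) "pseudo" else kind,
        product = qual("product"), translation = translation,
        wraps = loc$wraps, stringsAsFactors = FALSE))
    }
  }
  genome_record(id, sequence, topology, feats)
}

parse_gb_location <- function(txt, genome_len) {
  txt <- gsub("\\s", "", txt)
  strand <- "+"
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  wraps <- FALSE
  if (grepl("^join\\(", txt)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", txt)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, parse_gb_range)
    if (length(rng) == 2L && rng[[1]]$to == genome_len && rng[[2]]$from == 1L) {
      # origin-wrapping join
      start <- rng[[1]]$from - 1L
      end <- genome_len + rng[[2]]$to
      wraps <- TRUE
    } else {
      # multi-exon join: take the overall span
      start <- min(vapply(rng, `[[`, numeric(1), "from")) - 1L
      end <- max(vapply(rng, `[[`, numeric(1), "to"))
    }
  } else {
    r <- parse_gb_range(txt)
    start <- r$from - 1L
    end <- r$to
  }
  list(start = as.integer(start), end = as.integer(end), strand = strand,
       wraps = wraps)
}

parse_gb_range <- function(txt) {
  txt <- gsub("[<>]", "", txt)
  m <- regmatches(txt, regexec("^([0-9]+)\\.\\.([0-9]+)$", txt))[[1]]
  if (length(m) != 3L) stop("cannot parse GenBank location: ", txt)
  list(from = as.integer(m[2]), to = as.integer(m[3]))
}

#' Write a genome record as a GenBank flat file
#'
#' Inverse of [read_genbank()] for the dialect this package uses; a read →
#' write → read round trip is feature-stable (locus tags, coordinates,
#' strands).
#'
#' @param g a [genome_record].
#' @param path output file.
#' @export
write_genbank <- function(g, path) {
  len <- length(g)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s BCT %s",
                     g$id, len, g$topology, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$kind[i], CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                  pseudo = "CDS", "misc_RNA")
    loc <- if (f$wraps[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, len, f$end[i] - len)
    } else sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    if (nzchar(f$locus_tag[i]))
      writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag[i]), con)
    if (nzchar(f$product[i]))
      writeLines(sprintf('                     /product="%s"', f$product[i]), con)
    if (f$kind[i] == "pseudo") writeLines("                     /pseudo", con)
    if (nzchar(f$translation[i]))
      writeLines(sprintf('                     /translation="%s"', f$translation[i]), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substring(g$sequence, p, min(p + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read/write FASTA as named character vectors
#'
#' Thin wrappers over Biostrings I/O so the rest of the package can work with
#' plain named character vectors.
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Intergenic regions

#' Extract intergenic regions
#'
#' Returns the complement of the union of all annotated feature intervals
#' (RNA genes count as features, so intergenic means "not covered by any
#' annotated gene"). On a circular replicon the origin-spanning gap is
#' emitted once, with `end > length(g)` and `wraps = TRUE`. Regions shorter
#' than `min_len` are dropped. The midpoint is reported on the genome
#' coordinate (modulo length for wrap regions).
#'
#' @param g a [genome_record].
#' @param min_len minimum region length kept (default 100 bp).
#' @return data.frame with columns `region_id, genome_id, start, end, length,
#'   midpoint, wraps, sequence`.
#' @export
extract_intergenic <- function(g, min_len = 100) {
  len <- length(g)
  f <- g$features
  mk <- function(start, end, wraps) {
    keep <- (end - start) >= min_len
    start <- start[keep]; end <- end[keep]; wraps <- wraps[keep]
    n <- length(start)
    if (n == 0L)
      return(data.frame(region_id = character(0), genome_id = character(0),
                        start = integer(0), end = integer(0), length = integer(0),
                        midpoint = numeric(0), wraps = logical(0),
                        sequence = character(0), stringsAsFactors = FALSE))
    ord <- order(start)
    start <- start[ord]; end <- end[ord]; wraps <- wraps[ord]
    data.frame(
      region_id = sprintf("%s_ig%03d", g$id, seq_len(n)),
      genome_id = g$id, start = start, end = end, length = end - start,
      midpoint = ((start + end) / 2) %% len, wraps = wraps,
      sequence = vapply(seq_len(n), function(i) span_seq(g, start[i], end[i]),
                        character(1)),
      stringsAsFactors = FALSE)
  }
  if (nrow(f) == 0L) return(mk(0L, len, FALSE))

  # linearize (wrap features split in two) and take the covered union
  s <- f$start; e <- pmin(f$end, len)
  s2 <- rep(0L, sum(f$end > len)); e2 <- f$end[f$end > len] - len
  ir <- IRanges::reduce(IRanges::IRanges(start = c(s, s2) + 1L, end = c(e, e2)))
  gp <- IRanges::gaps(ir, start = 1L, end = len)
  gs <- IRanges::start(gp) - 1L; ge <- IRanges::end(gp)
  wraps <- rep(FALSE, length(gs))
  if (g$topology == "circular" && length(gs) >= 2L &&
      gs[1] == 0L && ge[length(ge)] == len) {
    # merge terminal gaps across the origin
    gs_first_end <- ge[1]
    gs <- gs[-1]; ge <- ge[-1]
    ge[length(ge)] <- len + gs_first_end
    wraps <- rep(FALSE, length(gs)); wraps[length(gs)] <- TRUE
  } else if (g$topology == "circular" && length(gs) == 1L &&
             gs[1] == 0L && ge[1] == len) {
    # fully uncovered circle: single non-wrapping region
  }
  mk(gs, ge, wraps)
}

# ---------------------------------------------------------------------------
# Tabular hits (12-column BLAST outfmt-6 dialect)

HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start",
              "s_end", "e_value", "bit_score")

#' Construct an empty hit table
#'
#' In-memory hit tables use the 12 tabular-search columns (coordinates kept
#' in the file dialect: 1-based inclusive, subject start > end for
#' minus-strand hits) plus optional `frame_q`/`frame_s` columns attached by
#' translated searches.
#' @export
hit_table <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    pct_identity = numeric(0), aln_length = integer(0),
                    mismatches = integer(0), gap_opens = integer(0),
                    q_start = integer(0), q_end = integer(0),
                    s_start = integer(0), s_end = integer(0),
                    e_value = numeric(0), bit_score = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

#' Read a 12-column tabular hit file
#'
#' @param path file path.
#' @return data.frame with the standard hit columns.
#' @export
read_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop(sprintf("malformed hit row (expected 12 tab-separated columns) at line %d",
                 bad[1]))
  m <- do.call(rbind, parts)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2L, as.numeric)
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1L, any))[1]
    stop(sprintf("malformed numeric field in hit file at line %d", bad))
  }
  out$pct_identity <- num[, 1]; out$aln_length <- as.integer(num[, 2])
  out$mismatches <- as.integer(num[, 3]); out$gap_opens <- as.integer(num[, 4])
  out$q_start <- as.integer(num[, 5]); out$q_end <- as.integer(num[, 6])
  out$s_start <- as.integer(num[, 7]); out$s_end <- as.integer(num[, 8])
  out$e_value <- num[, 9]; out$bit_score <- num[, 10]
  out
}

#' @rdname read_hits
#' @param hits a hit table.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(hits))) {
    writeLines(paste(c(hits$query_id[i], hits$subject_id[i],
                       vapply(hits[i, HIT_COLS[3:12]], function(x)
                         format(x, digits = 15, scientific = NA, trim = TRUE),
                         character(1))),
                     collapse = "\t"), con)
  }
  invisible(path)
}
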