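# Seeded generator of ancestor -> two-descendant genome pairs with ground
# truth, emulating the statistical regime of a decaying, vertically
# transmitted endosymbiont pair: functional genes diverge under purifying
# selection (synonymous changes always accepted, nonsynonymous rarely,
# nonsense never), a small fraction of genes pseudogenize (frameshifts and
# in-frame stops, then AT-biased neutral decay), never-coding spacers drift
# neutrally with a strong AT bias, and a controllable number of large
# in-place inversions is applied. Pseudogenes are deliberately left
# unannotated in the emitted records: the analysis pipeline has to
# rediscover them.

#' Parameters for the genome-pair simulator
#'
#' Defaults describe the package's reference scenario: 300 genes, two large
#' inversions (applied on the second branch), 5% pseudogenization and 2%
#' deletion per branch, per-branch protein divergence of 7.5% so that
#' cross-strain homologs sit near 85% protein identity, coding GC 41%,
#' ancestral spacer GC 30% decaying under an 0.8 AT bias, spacer drift of
#' 0.25 substitutions/site per branch (about 40% pairwise nucleotide
#' divergence of intergenic DNA) and a post-disruption pseudogene drift of
#' 0.25 — together reproducing the compositional strata (coding >
#' pseudogene > intergenic GC) and the nucleotide-vs-translated intergenic
#' synteny contrast that the analyses in this package are built to detect.
#'
#' @param n_genes number of protein-coding genes on the ancestor.
#' @param gene_len_mean,gene_len_sd gene length distribution (codons,
#'   excluding start/stop).
#' @param spacer_len_mean,spacer_len_sd intergenic spacer length
#'   distribution (bases).
#' @param coding_gc,spacer_gc ancestral GC fractions.
#' @param protein_divergence per-branch target amino-acid divergence of
#'   functional genes.
#' @param nonsyn_acceptance acceptance probability of a nonsynonymous point
#'   mutation (synonymous: 1; nonsense: 0).
#' @param at_bias probability that a neutral substitution lands on A or T.
#' @param spacer_divergence neutral substitutions/site per branch in
#'   never-coding spacers.
#' @param pseudogene_drift neutral substitutions/site applied to a
#'   pseudogene after disruption.
#' @param pseudogenization,deletion per-gene per-branch probabilities.
#' @param n_inversions inversions applied on the second branch.
#' @param inversion_span approximate inversion length (bases).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return object of class `evolution_params`.
#' @export
evolution_params <- function(n_genes = 300, gene_len_mean = 300,
                             gene_len_sd = 80, spacer_len_mean = 600,
                             spacer_len_sd = 200, coding_gc = 0.41,
                             spacer_gc = 0.30, protein_divergence = 0.075,
                             nonsyn_acceptance = 0.15, at_bias = 0.8,
                             spacer_divergence = 0.25, pseudogene_drift = 0.25,
                             pseudogenization = 0.05, deletion = 0.02,
                             n_inversions = 2, inversion_span = 50000,
                             seed = 1L) {
  p <- list(n_genes = n_genes, gene_len_mean = gene_len_mean,
            gene_len_sd = gene_len_sd, spacer_len_mean = spacer_len_mean,
            spacer_len_sd = spacer_len_sd, coding_gc = coding_gc,
            spacer_gc = spacer_gc, protein_divergence = protein_divergence,
            nonsyn_acceptance = nonsyn_acceptance, at_bias = at_bias,
            spacer_divergence = spacer_divergence,
            pseudogene_drift = pseudogene_drift,
            pseudogenization = pseudogenization, deletion = deletion,
            n_inversions = n_inversions, inversion_span = inversion_span,
            seed = seed)
  fracs <- c("protein_divergence", "nonsyn_acceptance", "at_bias",
             "pseudogenization", "deletion")
  for (f in fracs) stopifnot(p[[f]] >= 0, p[[f]] <= 1)
  structure(p, class = "evolution_params")
}

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

random_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(DNA_BASES, n, replace = TRUE, prob = base_probs(gc))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# stop-free random ORF: ATG + n_codons sense codons + one stop
random_gene <- function(n_codons, gc) {
  b <- random_bases(3L * n_codons, gc)
  cods <- paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
                 b[c(FALSE, FALSE, TRUE)])
  bad <- which(cods %in% STOP_CODONS)
  while (length(bad)) {
    for (i in bad) cods[i] <- paste(random_bases(3L, gc), collapse = "")
    bad <- which(cods %in% STOP_CODONS)
  }
  paste0("ATG", paste(cods, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Simulate a circular ancestor genome
#'
#' Genes are stop-free ORFs (ATG-started, stop-terminated) at the coding GC
#' target, placed on random strands and separated by spacers at an
#' independent GC target; the replicon is circular.
#'
#' @param p an [evolution_params].
#' @return object of class `ancestor_sim`: list with `genome`
#'   (a [genome_record]) and `blocks` (the internal gene/spacer layout the
#'   descendants are evolved from).
#' @export
simulate_ancestor <- function(p) {
  n <- p$n_genes
  blocks <- list()
  add <- function(blocks, blk) { blocks[[length(blocks) + 1L]] <- blk; blocks }
  for (i in seq_len(max(n, 1L))) {
    sp_len <- max(50L, round(stats::rnorm(1, p$spacer_len_mean, p$spacer_len_sd)))
    blocks <- add(blocks, list(type = "spacer", id = sprintf("anc_s%04d", i),
                               seq = paste(random_bases(sp_len, p$spacer_gc),
                                           collapse = ""), strand = "+"))
    if (i <= n) {
      len <- max(60L, round(stats::rnorm(1, p$gene_len_mean, p$gene_len_sd)))
      blocks <- add(blocks, list(type = "gene", id = sprintf("anc_g%04d", i),
                                 seq = random_gene(len, p$coding_gc),
                                 strand = sample(c("+", "-"), 1L)))
    }
  }
  asm <- assemble_blocks(blocks, "ancestor", annotate_ids = TRUE)
  structure(list(genome = asm$genome, blocks = blocks), class = "ancestor_sim")
}

# concatenate blocks into a genome_record; annotates intact genes only
assemble_blocks <- function(blocks, genome_id, annotate_ids = FALSE,
                            locus_prefix = genome_id) {
  seqs <- vapply(blocks, function(b)
    if (b$type == "gene" && b$strand == "-") rc_chr(b$seq) else b$seq,
    character(1))
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens))[seq_along(lens)]
  feats <- empty_features()
  coords <- data.frame(id = vapply(blocks, `[[`, "", "id"),
                       type = vapply(blocks, `[[`, "", "type"),
                       start = offs, end = offs + lens,
                       strand = vapply(blocks, `[[`, "", "strand"),
                       stringsAsFactors = FALSE)
  gi <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (b$type != "gene" || isTRUE(b$pseudo)) next
    gi <- gi + 1L
    tag <- if (annotate_ids) b$id else sprintf("%s_%04d", locus_prefix, gi)
    feats <- rbind(feats, data.frame(
      locus_tag = tag, start = offs[i], end = offs[i] + lens[i],
      strand = b$strand, kind = "CDS",
      product = sprintf("protein %s", b$id),
      translation = sub("\\*$", "", translate_chr(b$seq)),
      wraps = FALSE, stringsAsFactors = FALSE))
  }
  list(genome = genome_record(genome_id, paste(seqs, collapse = ""),
                              topology = "circular", features = feats),
       coords = coords)
}

# point mutations under a purifying-selection proxy until the target
# amino-acid divergence from the ancestor is reached
mutate_coding <- function(seq, target, q) {
  cods <- split_codons(seq)
  n <- length(cods)
  if (n <= 2L) return(list(seq = seq, aa_divergence = 0))
  aa0 <- unname(codon2aa()[cods])
  aa_cur <- aa0
  diffd <- rep(FALSE, n)
  n_target <- round(target * (n - 2L))
  body <- 2L:(n - 1L) # start and stop codons are immutable
  iter <- 0L; max_iter <- 400L * max(n_target, 1L) + 1000L
  while (sum(diffd) < n_target && iter < max_iter) {
    iter <- iter + 1L
    i <- sample(body, 1L)
    pos <- sample.int(3L, 1L)
    old <- substr(cods[i], pos, pos)
    new <- sample(setdiff(DNA_BASES, old), 1L)
    cand <- cods[i]; substr(cand, pos, pos) <- new
    aa_new <- codon2aa()[[cand]]
    if (aa_new == "*") next
    if (aa_new != aa_cur[i] && stats::runif(1) > q) next
    cods[i] <- cand; aa_cur[i] <- aa_new
    diffd[i] <- aa_new != aa0[i]
  }
  list(seq = paste(cods, collapse = ""),
       aa_divergence = sum(diffd) / (n - 2L))
}

# neutral substitutions with AT bias; at most one substitution per site
neutral_drift <- function(seq, rate, at_bias) {
  n <- nchar(seq)
  n_sub <- stats::rbinom(1L, n, rate)
  if (n_sub == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  orig <- s
  pos <- sample.int(n, n_sub)
  w_full <- c(A = at_bias / 2, C = (1 - at_bias) / 2, G = (1 - at_bias) / 2,
              T = at_bias / 2)
  for (old in DNA_BASES) {
    sel <- pos[orig[pos] == old]
    if (!length(sel)) next
    w <- w_full[setdiff(DNA_BASES, old)]
    s[sel] <- sample(names(w), length(sel), replace = TRUE, prob = w)
  }
  paste(s, collapse = "")
}

# disruption events: 1-base frameshifts and in-frame premature stops
disrupt_gene <- function(seq, n_events) {
  events <- sample(c("frameshift", "stop"), n_events, replace = TRUE)
  for (ev in events) {
    n <- nchar(seq)
    if (ev == "frameshift") {
      pos <- sample(seq(10L, n - 10L), 1L)
      if (stats::runif(1) < 0.5) {
        seq <- paste0(substring(seq, 1L, pos), sample(DNA_BASES, 1L),
                      substring(seq, pos + 1L)) # insertion
      } else {
        seq <- paste0(substring(seq, 1L, pos - 1L), substring(seq, pos + 1L))
      }
    } else {
      n_cod <- nchar(seq) %/% 3L
      i <- sample(seq(3L, n_cod - 2L), 1L)
      substr(seq, 3L * i - 2L, 3L * i) <- sample(STOP_CODONS, 1L)
    }
  }
  list(seq = seq, events = events)
}

#' Evolve one descendant from a simulated ancestor
#'
#' Functional genes accumulate point mutations under the acceptance rule
#' (synonymous 1, nonsynonymous `nonsyn_acceptance`, nonsense 0) until the
#' branch protein-divergence target is met. Pseudogenized genes first
#' diverge like functional genes, then receive 1-3 disruption events
#' (frameshifts/in-frame stops) and drift neutrally with AT bias; spacers
#' drift neutrally with AT bias. Configured inversions are applied with
#' block-boundary breakpoints (genes are never split) and whole-gene
#' deletions are applied last. Pseudogenes are not annotated in the
#' resulting record.
#'
#' @param ancestor an `ancestor_sim` from [simulate_ancestor()].
#' @param p an [evolution_params].
#' @param strain_id genome/locus-tag prefix for the descendant.
#' @param n_inversions override of `p$n_inversions` for this branch.
#' @return list with `genome` (a [genome_record]), `truth` (data.frame
#'   `ancestor_id, fate, locus_tag, start, end, strand, n_disruptions,
#'   aa_divergence`) and `inversions` (data.frame `start, end`).
#' @export
evolve_descendant <- function(ancestor, p, strain_id,
                              n_inversions = p$n_inversions) {
  blocks <- ancestor$blocks
  gene_idx <- which(vapply(blocks, `[[`, "", "type") == "gene")
  fate <- rep("intact", length(gene_idx))
  r <- stats::runif(length(gene_idx))
  fate[r < p$pseudogenization] <- "pseudogene"
  fate[r >= p$pseudogenization &
       r < p$pseudogenization + p$deletion] <- "deleted"
  n_disrupt <- integer(length(gene_idx))
  aa_div <- numeric(length(gene_idx))

  for (j in seq_along(gene_idx)) {
    i <- gene_idx[j]
    mut <- mutate_coding(blocks[[i]]$seq, p$protein_divergence,
                         p$nonsyn_acceptance)
    blocks[[i]]$seq <- mut$seq
    aa_div[j] <- mut$aa_divergence
    if (fate[j] == "pseudogene") {
      n_disrupt[j] <- sample.int(3L, 1L)
      d <- disrupt_gene(blocks[[i]]$seq, n_disrupt[j])
      blocks[[i]]$seq <- neutral_drift(d$seq, p$pseudogene_drift, p$at_bias)
      blocks[[i]]$pseudo <- TRUE
    }
  }
  for (i in seq_along(blocks)) {
    if (blocks[[i]]$type == "spacer")
      blocks[[i]]$seq <- neutral_drift(blocks[[i]]$seq, p$spacer_divergence,
                                       p$at_bias)
  }

  # resolve deletions by id before inversions reorder the block list
  del_ids <- vapply(ancestor$blocks[gene_idx[fate == "deleted"]], `[[`, "", "id")

  # inversions: contiguous block runs of roughly inversion_span bases,
  # breakpoints at block boundaries, non-overlapping
  inv_ranges <- list()
  if (n_inversions > 0L) {
    lens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
    used <- rep(FALSE, length(blocks))
    tries <- 0L
    while (length(inv_ranges) < n_inversions && tries < 200L) {
      tries <- tries + 1L
      from <- sample.int(length(blocks) - 1L, 1L)
      to <- from
      while (to < length(blocks) && sum(lens[from:to]) < p$inversion_span)
        to <- to + 1L
      if (any(used[from:to])) next
      used[from:to] <- TRUE
      inv_ranges[[length(inv_ranges) + 1L]] <- c(from, to)
    }
    for (k in seq_along(inv_ranges)) {
      rg <- inv_ranges[[k]]
      seg <- blocks[rg[1]:rg[2]]
      inv_ranges[[k]] <- vapply(seg, `[[`, "", "id") # remember by block id
      seg <- rev(lapply(seg, function(b) {
        if (b$type == "gene") b$strand <- if (b$strand == "+") "-" else "+"
        else b$seq <- rc_chr(b$seq)
        b
      }))
      blocks[rg[1]:rg[2]] <- seg
    }
  }

  # deletions last
  blocks <- blocks[!vapply(blocks, function(b)
    b$type == "gene" && b$id %in% del_ids, logical(1))]

  asm <- assemble_blocks(blocks, strain_id, annotate_ids = FALSE,
                         locus_prefix = strain_id)
  co <- asm$coords
  anc_ids <- vapply(ancestor$blocks[gene_idx], `[[`, "", "id")
  truth <- data.frame(ancestor_id = anc_ids, fate = fate,
                      locus_tag = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      n_disruptions = n_disrupt, aa_divergence = aa_div,
                      stringsAsFactors = FALSE)
  m <- match(truth$ancestor_id, co$id)
  truth$start <- co$start[m]; truth$end <- co$end[m]; truth$strand <- co$strand[m]
  feats <- asm$genome$features
  block_of <- match(feats$start, co$start)
  truth$locus_tag[match(co$id[block_of], truth$ancestor_id)] <- feats$locus_tag
  inv_df <- if (length(inv_ranges)) {
    do.call(rbind, lapply(inv_ranges, function(seg_ids) {
      sel <- co$id %in% seg_ids
      data.frame(start = min(co$start[sel]), end = max(co$end[sel]))
    }))
  } else data.frame(start = integer(0), end = integer(0))
  list(genome = asm$genome, truth = truth, inversions = inv_df)
}

#' Simulate a pair of diverged descendant strains with ground truth
#'
#' Seeds the generator, simulates the circular ancestor and evolves two
#' descendants (`A` and `B`); inversions are applied on the `B` branch so
#' that the A-vs-B comparison shows exactly `n_inversions` reversed
#' segments.
#'
#' @param p an [evolution_params].
#' @return object of class `strain_pair_sim`: list `params, ancestor, a, b`.
#' @export
simulate_strain_pair <- function(p = evolution_params()) {
  if (!is.null(p$seed)) set.seed(p$seed)
  anc <- simulate_ancestor(p)
  a <- evolve_descendant(anc, p, "A", n_inversions = 0L)
  b <- evolve_descendant(anc, p, "B", n_inversions = p$n_inversions)
  structure(list(params = p, ancestor = anc, a = a, b = b),
            class = "strain_pair_sim")
}

#' @export
print.strain_pair_sim <- function(x, ...) {
  cat(sprintf("<strain_pair_sim> %d ancestral genes; A: %s bp, B: %s bp\n",
              x$params$n_genes, format(length(x$a$genome), big.mark = ","),
              format(length(x$b$genome), big.mark = ",")))
  for (s in c("a", "b"))
    cat(sprintf("  %s: %d intact, %d pseudogenes, %d deleted, %d inversions\n",
                toupper(s), sum(x[[s]]$truth$fate == "intact"),
                sum(x[[s]]$truth$fate == "pseudogene"),
                sum(x[[s]]$truth$fate == "deleted"), nrow(x[[s]]$inversions)))
  invisible(x)
}

#' Write a simulated strain pair to disk
#'
#' Emits GenBank (intact genes annotated; pseudogenes deliberately absent so
#' the pipeline must rediscover them), FASTA, and tab-separated truth tables.
#'
#' @param sim a `strain_pair_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
emit_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(a_gbk = file.path(dir, "strainA.gbk"),
             b_gbk = file.path(dir, "strainB.gbk"),
             fasta = file.path(dir, "genomes.fasta"),
             truth_a = file.path(dir, "truth_A.tsv"),
             truth_b = file.path(dir, "truth_B.tsv"),
             inversions = file.path(dir, "inversions_B.tsv"))
  write_genbank(sim$a$genome, files["a_gbk"])
  write_genbank(sim$b$genome, files["b_gbk"])
  write_fasta(c(A = sim$a$genome$sequence, B = sim$b$genome$sequence),
              files["fasta"])
  utils::write.table(sim$a$truth, files["truth_a"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$b$truth, files["truth_b"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$b$inversions, files["inversions"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(files)
}
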