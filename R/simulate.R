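#' Default planted differential-expression effects
#'
#' Multiplicative per-library fold effects (CW = 1) for the designated
#' responsive miRNAs, mirroring the four-pair screening design at desk
#' scale: eight "both-responsive" miRNAs (five consistently down-regulated
#' in all four comparison pairs; two with the characteristic sign flip -
#' down in CS/CW, HW/CW and HS/CW but up in HS/HW; one with the inverse
#' flip), four heat-responsive and three spermidine-responsive miRNAs.
#' Every planted pairwise ratio is at least 4-fold so the screening stage
#' must separate the classes cleanly.
#'
#' @return named list: per miRNA id, a named numeric vector of effects over
#'   CW/CS/HW/HS, with attributes `set` (both/heat/spd per id) and
#'   `baseline` (expected CW reads per 100,000)
#' @export
default_de_effects <- function() {
  eff <- list(
    # both-responsive, all-down in the four pairs
    miR1001a = c(CW = 1, CS = 0.25, HW = 0.25,   HS = 0.05),
    miR1002a = c(CW = 1, CS = 0.20, HW = 0.25,   HS = 0.0625),
    miR1003a = c(CW = 1, CS = 0.25, HW = 0.20,   HS = 0.05),
    miR1004a = c(CW = 1, CS = 0.20, HW = 0.20,   HS = 0.05),
    miR1005a = c(CW = 1, CS = 0.25, HW = 0.25,   HS = 0.0625),
    # both-responsive, sign flip: down/down/down then up in HS/HW
    miR1006a = c(CW = 1, CS = 0.25, HW = 0.05,   HS = 0.25),
    miR1007a = c(CW = 1, CS = 0.25, HW = 0.04,   HS = 0.20),
    # both-responsive, inverse flip: up/up/up then down in HS/HW
    miR1008a = c(CW = 1, CS = 4,    HW = 16,     HS = 4),
    # heat-responsive only (HW/CW and HS/CW; HS/HW ratio 1)
    miR1009a = c(CW = 1, CS = 1, HW = 0.20, HS = 0.20),
    miR1010a = c(CW = 1, CS = 1, HW = 0.25, HS = 0.25),
    miR1011a = c(CW = 1, CS = 1, HW = 4,    HS = 4),
    miR1012a = c(CW = 1, CS = 1, HW = 0.20, HS = 0.20),
    # spermidine-responsive only (CS/CW, HS/CW, HS/HW; HW/CW ratio 1)
    miR1013a = c(CW = 1, CS = 4,    HW = 1, HS = 4),
    miR1014a = c(CW = 1, CS = 0.25, HW = 1, HS = 0.25),
    miR1015a = c(CW = 1, CS = 4,    HW = 1, HS = 4))
  set <- c(rep("both", 8), rep("heat", 4), rep("spd", 3))
  names(set) <- names(eff)
  baseline <- c(rep(2500, 7), 300, rep(1200, 4), rep(1200, 3))
  names(baseline) <- names(eff)
  attr(eff, "set") <- set
  attr(eff, "baseline") <- baseline
  eff
}

#' Simulation configuration
#'
#' The stated world of the synthetic libraries: four single libraries (CW,
#' CS, HW, HS), 3' adapter-ligated inserts of 18-30 nt read at a fixed read
#' length, phred64 qualities, contaminant classes injected at rates echoing
#' published library-cleaning summaries (about 3.4% of high-quality reads
#' removed, dominated by short inserts), log-normal baseline abundances, and
#' planted multiplicative fold effects defining the responsive sets.
#'
#' @param seed integer seed; a fixed seed yields byte-identical outputs
#' @param n_reads_per_library reads per library (default 100,000)
#' @param libraries the four condition labels
#' @param adapter3,adapter5 adapter sequences
#' @param read_length sequenced read length in nt (36)
#' @param encoding `"phred64"` (default) or `"phred33"`
#' @param contaminant_rates named fractions per removal class; each in
#'   \[0, 1) and summing to < 1
#' @param baseline_logmean,baseline_logsd log-normal parameters of
#'   non-planted known-miRNA abundances (expected reads per 100,000)
#' @param de_effects planted effects, see [default_de_effects()]
#' @param novel_hairpin_count planted novel hairpin loci (6)
#' @param category_weights expected clean-read fractions per non-miRNA
#'   category
#' @return list of class `spidmir_sim_config`
#' @export
simulation_config <- function(seed = 1L, n_reads_per_library = 100000L,
                              libraries = .LIBS,
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                              read_length = 36L,
                              encoding = c("phred64", "phred33"),
                              contaminant_rates = c(
                                low_quality = 7e-4, high_N = 2e-4,
                                adapter5_contaminant = 1e-3,
                                insert_null = 1e-4, adapter3_null = 4e-3,
                                polyA = 1e-4, short = 0.028),
                              baseline_logmean = log(60),
                              baseline_logsd = 1.2,
                              de_effects = default_de_effects(),
                              novel_hairpin_count = 6L,
                              category_weights = c(
                                rRNA = 0.18, tRNA = 0.017, snRNA = 0.003,
                                snoRNA = 0.0025, repeat_ = 0.005,
                                exon_sense = 0.004, exon_antisense = 0.0015,
                                intron_sense = 0.007, intron_antisense = 0.004,
                                novel = 0.008, unannotated = 0.55)) {
  encoding <- match.arg(encoding)
  need <- c("low_quality", "high_N", "adapter5_contaminant", "insert_null",
            "adapter3_null", "polyA", "short")
  stopifnot(length(libraries) == 4L, !anyDuplicated(libraries),
            all(need %in% names(contaminant_rates)),
            all(contaminant_rates >= 0), all(contaminant_rates < 1),
            sum(contaminant_rates) < 1,
            novel_hairpin_count >= 0L, n_reads_per_library > 0L)
  for (e in de_effects) stopifnot(all(e > 0), all(libraries %in% names(e)))
  structure(list(seed = as.integer(seed),
                 n_reads_per_library = as.integer(n_reads_per_library),
                 libraries = libraries, adapter3 = adapter3,
                 adapter5 = adapter5, read_length = as.integer(read_length),
                 encoding = encoding,
                 contaminant_rates = contaminant_rates[need],
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd,
                 de_effects = de_effects,
                 novel_hairpin_count = as.integer(novel_hairpin_count),
                 category_weights = category_weights),
            class = "spidmir_sim_config")
}

# mutate k random positions of a DNA string to a different base
mutate_bases <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), min(k, length(s)))
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# mutate k interior positions (away from both ends), keeping stem ends intact
mutate_middle <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(5:(length(s) - 4L), min(k, length(s) - 8L))
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# TRUE for insert sequences that, read as insert + 3' adapter at the
# configured read length, survive all seven filter rules and trim back to
# themselves (assuming clean qualities)
insert_is_clean <- function(insert, config, params = filter_params()) {
  read <- substr(paste0(insert, config$adapter3), 1L, config$read_length)
  seed5 <- substr(config$adapter5, 1L,
                  min(nchar(config$adapter5), params$adapter5_seed))
  ilen <- locate_adapter3(read, config$adapter3, params$adapter3_seed)
  ok <- !is.na(ilen) & ilen == nchar(insert) & !startsWith(read, seed5) &
    nchar(insert) >= params$min_length &
    count_chars(insert, "A") / nchar(insert) < params$polya_fraction
  ok & !grepl("N", insert)
}

# sample a non-overlapping layout of feature lengths along the chromosomes;
# returns data.table(chrom, start (0-based), end, strand) in input order
place_features <- function(lengths, chrom_sizes, min_gap = 120L, max_gap = 420L) {
  n <- length(lengths)
  ord <- sample(n)
  chroms <- names(chrom_sizes)
  ci <- 1L
  cursor <- sample(min_gap:max_gap, 1)
  out <- data.table::data.table(chrom = character(n), start = integer(n),
                                end = integer(n), strand = character(n))
  for (k in ord) {
    gap <- sample(min_gap:max_gap, 1)
    if (cursor + lengths[k] + gap > chrom_sizes[[ci]]) {
      ci <- ci + 1L
      if (ci > length(chroms))
        stop("genome too small for the requested features", call. = FALSE)
      cursor <- sample(min_gap:max_gap, 1)
    }
    out[k, `:=`(chrom = chroms[ci], start = cursor,
                end = cursor + lengths[k],
                strand = sample(c("+", "-"), 1))]
    cursor <- cursor + lengths[k] + gap
  }
  out
}

#' Build the toy reference bundle
#'
#' Generates a ~100 kb two-contig genome with planted, non-overlapping
#' features (rRNA/tRNA/snRNA/snoRNA/repeat/exon/intron loci), ~50 known
#' miRNA precursors in ~20 families (each mature a perfect substring of its
#' precursor, each precursor mapping exactly once to the genome), planted
#' novel hairpins (two reverse-complementary arms around a loop) in
#' unannotated sequence, a transcriptome with planted complementarity sites
#' for the target-bearing responsive miRNAs, and a term-to-gene map with a
#' planted enriched term. When `dir` is given, the bundle is written out as
#' FASTA/GFF3/BED/TSV (GFF3 1-based closed; BED 0-based half-open).
#'
#' @param config a [simulation_config()]
#' @param dir optional output directory
#' @return list of class `spidmir_reference`: `genome` (named character),
#'   `features` (`GRanges` with `type`), `known` (data.frame `mirna`,
#'   `family`, `mature`, `precursor`, `chrom`, `start`, `strand`),
#'   `novel_loci` (planted hairpins: `id`, `chrom`, `start`, `end`,
#'   `strand`, `mature`, `precursor`), `species` (non-miRNA clean-read
#'   species: `sequence`, `category`, `source_id`), `transcripts`,
#'   `term_map`, `target_truth` (planted miRNA-gene links), `paths`
#' @export
build_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "spidmir_sim_config"))
  with_seed(config$seed, build_reference_impl(config, dir))
}

build_reference_impl <- function(config, dir) {
  chrom_sizes <- c(chr1 = 60000L, chr2 = 40000L)
  genome <- vapply(chrom_sizes, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))

  # known miRNAs: 20 families, 48 members; the planted responsive ids are
  # the 'a' members of families miR1001-miR1015
  fam_sizes <- c(4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L,
                 3L, 3L, 2L, 2L, 1L)
  fams <- sprintf("miR%04d", 1000L + seq_along(fam_sizes))
  mirna_ids <- unlist(lapply(seq_along(fams), function(i)
    paste0(fams[i], letters[seq_len(fam_sizes[i])])))
  mirna_fam <- rep(fams, fam_sizes)

  matures <- random_dna(length(mirna_ids), sample(20:22, length(mirna_ids),
                                                  replace = TRUE))
  loops <- random_dna(length(mirna_ids), sample(12:18, length(mirna_ids),
                                                replace = TRUE))
  stars <- vapply(matures, function(m) mutate_bases(revcomp(m), 2L), character(1),
                  USE.NAMES = FALSE)
  precursors <- paste0(matures, loops, stars)

  # novel hairpins: two reverse-complementary arms around an 8-40 nt loop;
  # the 5' arm is the mature. Two interior star mutations keep the arm tag
  # mapping exactly once while leaving >= arm-2 paired stem bases.
  nh <- config$novel_hairpin_count
  novel_arms <- if (nh > 0) random_dna(nh, sample(20:22, nh, replace = TRUE))
                else character()
  novel_loops <- if (nh > 0) random_dna(nh, sample(8:40, nh, replace = TRUE))
                 else character()
  novel_stars <- vapply(novel_arms, function(a)
    mutate_middle(revcomp(a), 2L), character(1), USE.NAMES = FALSE)
  novel_prec <- if (nh > 0) paste0(novel_arms, novel_loops, novel_stars)
                else character()

  feat_spec <- data.table::data.table(
    type = c(rep("rRNA", 4), rep("tRNA", 6), rep("snRNA", 4),
             rep("snoRNA", 4), rep("repeat", 5), rep("exon", 30),
             rep("intron", 20)),
    length = c(sample(120:300, 4, TRUE), sample(70:90, 6, TRUE),
               sample(80:150, 4, TRUE), sample(70:200, 4, TRUE),
               sample(150:400, 5, TRUE), sample(150:300, 30, TRUE),
               sample(100:250, 20, TRUE)))
  all_lens <- c(feat_spec$length, nchar(precursors), nchar(novel_prec))
  layout <- place_features(all_lens, chrom_sizes)

  nf <- nrow(feat_spec)
  np <- length(precursors)
  feat_layout <- layout[seq_len(nf)]
  prec_layout <- layout[nf + seq_len(np)]
  novel_layout <- if (nh > 0) layout[nf + np + seq_len(nh)] else layout[0]
  prec_layout[, strand := "+"]          # precursors planted on the plus strand
  if (nh > 0) novel_layout[, strand := "+"]

  plant <- function(genome, chrom, start, seq) {
    s <- genome[[chrom]]
    genome[[chrom]] <- paste0(substr(s, 1, start), seq,
                              substr(s, start + nchar(seq) + 1L, nchar(s)))
    genome
  }
  for (i in seq_len(np))
    genome <- plant(genome, prec_layout$chrom[i], prec_layout$start[i],
                    precursors[i])
  for (i in seq_len(nh))
    genome <- plant(genome, novel_layout$chrom[i], novel_layout$start[i],
                    novel_prec[i])

  features <- GenomicRanges::GRanges(
    feat_layout$chrom,
    IRanges::IRanges(feat_layout$start + 1L, feat_layout$end),
    strand = feat_layout$strand, type = feat_spec$type)

  # reference sanity: matures unique in their precursor, precursors unique
  # in the genome (both strands)
  gset <- Biostrings::DNAStringSet(genome)
  for (i in seq_len(np)) {
    if (length(gregexpr(matures[i], precursors[i], fixed = TRUE)[[1]]) != 1L)
      stop("mature occurs more than once in its precursor", call. = FALSE)
    n_hits <- sum(Biostrings::vcountPattern(precursors[i], gset)) +
      sum(Biostrings::vcountPattern(revcomp(precursors[i]), gset))
    if (n_hits != 1L)
      stop("precursor '", mirna_ids[i], "' does not map exactly once",
           call. = FALSE)
  }

  known <- data.frame(mirna = mirna_ids, family = mirna_fam,
                      mature = matures, precursor = precursors,
                      chrom = prec_layout$chrom, start = prec_layout$start,
                      strand = "+", stringsAsFactors = FALSE)
  novel_loci <- data.frame(
    id = if (nh > 0) sprintf("hairpin%02d", seq_len(nh)) else character(),
    chrom = novel_layout$chrom, start = novel_layout$start,
    end = novel_layout$end, strand = novel_layout$strand,
    mature = novel_arms, precursor = novel_prec, stringsAsFactors = FALSE)

  species <- build_species(config, genome, feat_layout, feat_spec, layout)

  # transcriptome with planted target sites for the target-bearing
  # both-responsive miRNAs (three of the eight get none)
  genes <- sprintf("g%04d", 1:60)
  transcripts <- stats::setNames(random_dna(60, sample(350:500, 60, TRUE)), genes)
  both_ids <- names(attr(config$de_effects, "set"))[
    attr(config$de_effects, "set") == "both"]
  both_ids <- both_ids[both_ids %in% mirna_ids]
  target_truth <- data.frame(mirna = character(), gene = character(),
                             stringsAsFactors = FALSE)
  if (length(both_ids) >= 5) {
    n_targets <- c(12L, 3L, 2L, 1L, 1L)        # five bearers, three without
    bearers <- both_ids[c(6, 7, 1, 2, 3)]      # flips first (most targets)
    pool <- sample(genes)
    taken <- 0L
    for (bi in seq_along(bearers)) {
      gs <- pool[taken + seq_len(n_targets[bi])]
      taken <- taken + n_targets[bi]
      mseq <- matures[match(bearers[bi], mirna_ids)]
      for (g in gs) {
        tx <- transcripts[[g]]
        pos <- sample(seq_len(nchar(tx) - nchar(mseq) + 1L), 1)
        transcripts[[g]] <- paste0(substr(tx, 1, pos - 1L), revcomp(mseq),
                                   substr(tx, pos + nchar(mseq), nchar(tx)))
      }
      target_truth <- rbind(target_truth,
                            data.frame(mirna = bearers[bi], gene = gs,
                                       stringsAsFactors = FALSE))
    }
  }

  term_map <- build_term_map(genes, target_truth)

  ref <- structure(list(genome = genome, features = features, known = known,
                        novel_loci = novel_loci, species = species,
                        transcripts = transcripts, term_map = term_map,
                        target_truth = target_truth, paths = NULL),
                   class = "spidmir_reference")
  if (!is.null(dir)) ref$paths <- write_reference(ref, dir)
  ref
}

# clean-read species for the non-miRNA categories: genome substrings that
# overlap the right feature (right strand for exon/intron sense/antisense)
# or intergenic space, each validated to survive the seven filter rules
build_species <- function(config, genome, feat_layout, feat_spec, layout) {
  n_species <- c(rRNA = 40L, tRNA = 20L, snRNA = 8L, snoRNA = 8L,
                 repeat_ = 15L, exon_sense = 25L, exon_antisense = 10L,
                 intron_sense = 20L, intron_antisense = 12L,
                 unannotated = 120L)
  frag_from <- function(row, antisense = FALSE) {
    L <- sample(18:28, 1)
    flen <- row$end - row$start
    off <- sample(0:(flen - L), 1)
    s <- substr(genome[[row$chrom]], row$start + off + 1L, row$start + off + L)
    onstrand <- if (antisense) setdiff(c("+", "-"), row$strand) else row$strand
    if (onstrand == "-") s <- revcomp(s)
    s
  }
  out <- list()
  for (cat in names(n_species)) {
    base <- sub("_sense$|_antisense$", "", cat)
    base <- sub("_$", "", base)
    anti <- grepl("_antisense$", cat)
    rows <- if (cat == "unannotated") NULL else which(feat_spec$type == base)
    seqs <- character(0)
    guard <- 0L
    while (length(seqs) < n_species[[cat]] && guard < 5000L) {
      guard <- guard + 1L
      s <- if (cat == "unannotated") {
        intergenic_fragment(genome, layout)
      } else {
        frag_from(feat_layout[sample(rows, 1)], antisense = anti)
      }
      if (insert_is_clean(s, config) && !(s %in% seqs)) seqs <- c(seqs, s)
    }
    if (length(seqs) < n_species[[cat]])
      stop("could not build enough clean species for ", cat, call. = FALSE)
    out[[cat]] <- data.table::data.table(
      sequence = seqs,
      category = if (cat == "repeat_") "repeat" else cat,
      source_id = paste0(if (cat == "repeat_") "repeat" else cat,
                         "_", seq_along(seqs)))
  }
  data.table::rbindlist(out)
}

# random intergenic substring (no overlap with any planted element)
intergenic_fragment <- function(genome, layout) {
  repeat {
    chrom <- sample(names(genome), 1)
    L <- sample(18:28, 1)
    maxs <- nchar(genome[[chrom]]) - L
    st <- sample(0:maxs, 1)
    occ <- layout[layout$chrom == chrom &
                    layout$start < st + L & layout$end > st, ]
    if (nrow(occ) == 0)
      return(substr(genome[[chrom]], st + 1L, st + L))
  }
}

# gene-to-term map over three GO-like classes plus pathways, with one term
# deliberately concentrated on the planted target genes (the enrichment
# ground truth)
build_term_map <- function(genes, target_truth) {
  terms <- data.frame(
    term = c(sprintf("T%04d", 1:6), sprintf("T%04d", 11:14),
             sprintf("T%04d", 21:24), sprintf("P%04d", 1:5)),
    class = c(rep("biological_process", 6), rep("cellular_component", 4),
              rep("molecular_function", 4), rep("pathway", 5)),
    stringsAsFactors = FALSE)
  rows <- list()
  for (g in genes) {
    pick <- sample(nrow(terms), sample(2:4, 1))
    rows[[g]] <- data.frame(gene = g, term = terms$term[pick],
                            class = terms$class[pick],
                            stringsAsFactors = FALSE)
  }
  tm <- unique(do.call(rbind, rows))
  if (nrow(target_truth) > 0) {
    # planted enrichment: targets of the top bearer share one pathway term
    top <- target_truth$gene[target_truth$mirna == target_truth$mirna[1]]
    extra <- data.frame(gene = unique(top), term = "P0001", class = "pathway",
                        stringsAsFactors = FALSE)
    tm <- unique(rbind(tm, extra))
  }
  rownames(tm) <- NULL
  tm
}

write_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    features_gff3 = file.path(dir, "features.gff3"),
    features_bed = file.path(dir, "features.bed"),
    mature = file.path(dir, "known_mature.fa"),
    precursor = file.path(dir, "known_precursor.fa"),
    known_tsv = file.path(dir, "known_mirnas.tsv"),
    transcripts = file.path(dir, "transcripts.fa"),
    term_map = file.path(dir, "term_map.tsv"),
    novel_loci = file.path(dir, "synthetic_novel_hairpins.tsv"))
  g <- Biostrings::DNAStringSet(ref$genome)
  Biostrings::writeXStringSet(g, paths$genome)
  mat <- Biostrings::DNAStringSet(stats::setNames(ref$known$mature,
                                                  ref$known$mirna))
  Biostrings::writeXStringSet(mat, paths$mature)
  pre <- Biostrings::DNAStringSet(stats::setNames(ref$known$precursor,
                                                  ref$known$mirna))
  Biostrings::writeXStringSet(pre, paths$precursor)
  tx <- Biostrings::DNAStringSet(ref$transcripts)
  Biostrings::writeXStringSet(tx, paths$transcripts)
  write.table(ref$known, paths$known_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ref$term_map, paths$term_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ref$novel_loci, paths$novel_loci, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    rtracklayer::export(ref$features, paths$features_gff3, format = "gff3")
    bed <- ref$features
    names(bed) <- paste0(S4Vectors::mcols(bed)$type, "_", seq_along(bed))
    rtracklayer::export(bed, paths$features_bed, format = "bed")
  } else {
    # minimal fallbacks so the bundle is complete without rtracklayer
    df <- as.data.frame(ref$features)
    gff <- data.frame(df$seqnames, "spidmir", df$type, df$start, df$end, ".",
                      df$strand, ".", paste0("ID=", df$type, "_", seq_len(nrow(df))))
    writeLines(c("##gff-version 3",
                 apply(gff, 1, paste, collapse = "\t")), paths$features_gff3)
    bed <- data.frame(df$seqnames, df$start - 1L, df$end,
                      paste0(df$type, "_", seq_len(nrow(df))), 0L, df$strand)
    write.table(bed, paths$features_bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  paths
}

#' Simulate the four FASTQ libraries and the ground-truth manifest
#'
#' Clean reads are insert + 3' adapter truncated to the read length, with
#' per-position qualities drawn from 30-41; per-read removal classes are
#' drawn at the configured contaminant rates and each contaminant is
#' constructed to fail exactly its intended filter rule (low-quality reads
#' carry at least four sub-10 qualities; high-N reads exceed 10% N; and so
#' on). Clean reads are drawn multinomially over the species pool - known
#' miRNA matures weighted by baseline x planted effect, novel hairpin arms,
#' and category fragments - so the manifest's true expression is the exact
#' sampling proportion.
#'
#' @param config a [simulation_config()]
#' @param ref reference bundle from [build_reference()]
#' @param dir optional output directory for FASTQ files and manifest JSON
#' @return list of class `spidmir_sim`: `reads` (per-library data.frames
#'   `id`, `sequence`, `quality`), `manifest` (list: `per_read` class per
#'   read id, `tag_truth`, `true_expression` TPM matrix, `responsive_sets`,
#'   `novel_loci`), `paths`
#' @export
simulate_libraries <- function(config, ref, dir = NULL) {
  stopifnot(inherits(config, "spidmir_sim_config"),
            inherits(ref, "spidmir_reference"))
  if (config$adapter3 %in% ref$known$mature ||
      config$adapter3 %in% ref$novel_loci$mature)
    stop("3' adapter equals a mature sequence; this would confound trimming",
         call. = FALSE)
  with_seed(config$seed + 1L, simulate_libraries_impl(config, ref, dir))
}

simulate_libraries_impl <- function(config, ref, dir) {
  eff <- config$de_effects
  eff_set <- attr(eff, "set")
  eff_base <- attr(eff, "baseline")
  known <- ref$known
  libs <- config$libraries

  # species table: sequence, id, category, per-library weight (expected
  # reads per 100,000)
  planted <- intersect(names(eff), known$mirna)
  other <- setdiff(known$mirna, planted)
  base_other <- stats::setNames(rlnorm(length(other), config$baseline_logmean,
                                       config$baseline_logsd), other)
  w_mirna <- matrix(0, nrow = nrow(known), ncol = 4,
                    dimnames = list(known$mirna, libs))
  for (m in planted) w_mirna[m, ] <- eff_base[[m]] * eff[[m]][libs]
  for (m in other) w_mirna[m, ] <- base_other[[m]]

  cw <- config$category_weights * 1e5
  sp <- data.table::copy(ref$species)
  sp[, weight := {
    w <- rlnorm(.N, 0, 1)
    w / sum(w)
  }, by = category]
  catkey <- ifelse(sp$category == "repeat", "repeat_", sp$category)
  sp[, weight := weight * cw[catkey]]

  nh <- nrow(ref$novel_loci)
  novel_w <- if (nh > 0) {
    w <- rlnorm(nh, 0, 0.5); w / sum(w) * cw[["novel"]]
  } else numeric()

  species <- data.table::rbindlist(list(
    data.table::data.table(sequence = known$mature, source_id = known$mirna,
                           category = "miRNA_known"),
    if (nh > 0) data.table::data.table(sequence = ref$novel_loci$mature,
                                       source_id = ref$novel_loci$id,
                                       category = "novel"),
    sp[, .(sequence, source_id, category)]))
  species <- species[!duplicated(sequence)]

  # validate every clean species once more against the filter
  ok <- insert_is_clean(species$sequence, config)
  if (!all(ok))
    stop("species failed the clean-read filter: ",
         paste(utils::head(species$sequence[!ok], 3), collapse = ", "),
         call. = FALSE)

  weights <- matrix(0, nrow = nrow(species), ncol = 4,
                    dimnames = list(species$source_id, libs))
  ki <- match(rownames(weights), rownames(w_mirna))
  weights[!is.na(ki), ] <- w_mirna[ki[!is.na(ki)], ]
  if (nh > 0) {
    ni <- match(rownames(weights), ref$novel_loci$id)
    weights[!is.na(ni), ] <- matrix(rep(novel_w[ni[!is.na(ni)]], 4), ncol = 4)
  }
  si <- match(rownames(weights), sp$source_id)
  weights[!is.na(si), ] <- matrix(rep(sp$weight[si[!is.na(si)]], 4), ncol = 4)

  true_tpm <- sweep(weights, 2, colSums(weights), "/") * 1e6

  rates <- config$contaminant_rates
  classes <- c(names(rates), "clean")
  probs <- c(rates, clean = 1 - sum(rates))
  n <- config$n_reads_per_library
  rl <- config$read_length
  offset <- if (config$encoding == "phred64") 64L else 33L
  qhigh <- intToUtf8(offset + 30:41, multiple = TRUE)
  qlow <- intToUtf8(offset + 0:9, multiple = TRUE)

  qual_strings <- function(k) {
    m <- matrix(sample(qhigh, k * rl, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  reads_list <- list(); per_read <- list()
  for (lib in libs) {
    cls <- sample(classes, n, replace = TRUE, prob = probs)
    seqs <- character(n)
    quals <- qual_strings(n)

    i_clean <- which(cls == "clean")
    sp_idx <- sample.int(nrow(species), length(i_clean), replace = TRUE,
                         prob = weights[, lib])
    seqs[i_clean] <- substr(paste0(species$sequence[sp_idx], config$adapter3),
                            1L, rl)

    i_lq <- which(cls == "low_quality")
    if (length(i_lq)) {
      seqs[i_lq] <- substr(paste0(random_dna(length(i_lq), 20), config$adapter3),
                           1L, rl)
      quals[i_lq] <- vapply(quals[i_lq], function(q) {
        pos <- sample(rl, sample(4:6, 1))
        s <- strsplit(q, "")[[1]]
        s[pos] <- sample(qlow, length(pos), replace = TRUE)
        paste(s, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    i_n <- which(cls == "high_N")
    if (length(i_n)) {
      seqs[i_n] <- vapply(random_dna(length(i_n), rl), function(s) {
        pos <- sample(rl, 5)
        ss <- strsplit(s, "")[[1]]; ss[pos] <- "N"
        paste(ss, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    i_a5 <- which(cls == "adapter5_contaminant")
    if (length(i_a5))
      seqs[i_a5] <- substr(paste0(config$adapter5,
                                  random_dna(length(i_a5), rl)), 1L, rl)
    i_in <- which(cls == "insert_null")
    if (length(i_in))
      seqs[i_in] <- substr(paste0(config$adapter3,
                                  random_dna(length(i_in), rl)), 1L, rl)
    i_a3 <- which(cls == "adapter3_null")
    if (length(i_a3))
      seqs[i_a3] <- make_adapter3_null(length(i_a3), config)
    i_pa <- which(cls == "polyA")
    if (length(i_pa)) {
      alen <- sample(18:25, length(i_pa), replace = TRUE)
      seqs[i_pa] <- substr(paste0(strrep("A", alen), config$adapter3), 1L, rl)
    }
    i_sh <- which(cls == "short")
    if (length(i_sh))
      seqs[i_sh] <- make_short(length(i_sh), config)

    ids <- sprintf("%s_%07d", lib, seq_len(n))
    perm <- sample.int(n)
    reads_list[[lib]] <- data.frame(id = ids, sequence = seqs[perm],
                                    quality = quals[perm],
                                    stringsAsFactors = FALSE)
    per_read[[lib]] <- data.frame(id = ids, class = cls[perm],
                                  stringsAsFactors = FALSE)
  }

  responsive <- lapply(c(both = "both", heat = "heat", spd = "spd"),
                       function(s) {
    ids <- names(eff_set)[eff_set == s]
    ids <- intersect(ids, known$mirna)
    lapply(stats::setNames(ids, ids), function(m) {
      fcs <- vapply(.PAIRS, function(p)
        log2(true_tpm[m, p[1]] / true_tpm[m, p[2]]), numeric(1))
      list(effects = eff[[m]][libs], true_log2fc = fcs,
           pattern = paste(ifelse(fcs < 0, "down", "up"), collapse = ","))
    })
  })

  manifest <- list(per_read = per_read,
                   tag_truth = as.data.frame(species),
                   true_expression = true_tpm,
                   responsive_sets = responsive,
                   novel_loci = ref$novel_loci,
                   n_reads_per_library = n,
                   seed = config$seed)
  sim <- structure(list(reads = reads_list, manifest = manifest, paths = NULL),
                   class = "spidmir_sim")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fq <- stats::setNames(file.path(dir, paste0(libs, ".fastq")), libs)
    for (lib in libs) write_fastq(reads_list[[lib]], fq[[lib]])
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(list(
      per_read = lapply(per_read, function(d) list(id = d$id, class = d$class)),
      tag_truth = manifest$tag_truth,
      true_expression = list(mirna = rownames(true_tpm),
                             library = colnames(true_tpm),
                             tpm = unname(as.data.frame(true_tpm))),
      responsive_sets = responsive,
      novel_loci = ref$novel_loci,
      n_reads_per_library = n, seed = config$seed),
      mpath, auto_unbox = TRUE, digits = NA)
    sim$paths <- list(fastq = fq, manifest = mpath)
  }
  sim
}

# random reads with no trace of the 3' adapter (and no other rule tripped
# before rule 5)
make_adapter3_null <- function(k, config, params = filter_params()) {
  seed5 <- substr(config$adapter5, 1L,
                  min(nchar(config$adapter5), params$adapter5_seed))
  out <- character(0)
  while (length(out) < k) {
    cand <- random_dna(k - length(out), config$read_length)
    ok <- is.na(locate_adapter3(cand, config$adapter3, params$adapter3_seed)) &
      !startsWith(cand, seed5)
    out <- c(out, cand[ok])
  }
  out
}

# inserts of 12-17 nt (non-poly(A), adapter cleanly locatable) padded with
# random sequence after the adapter
make_short <- function(k, config, params = filter_params()) {
  seed5 <- substr(config$adapter5, 1L,
                  min(nchar(config$adapter5), params$adapter5_seed))
  rl <- config$read_length
  out <- character(0)
  while (length(out) < k) {
    need <- k - length(out)
    ins <- random_dna(need, sample(12:17, need, replace = TRUE))
    reads <- substr(paste0(ins, config$adapter3, random_dna(need, rl)), 1L, rl)
    ilen <- locate_adapter3(reads, config$adapter3, params$adapter3_seed)
    ok <- !is.na(ilen) & ilen == nchar(ins) & ilen > 0L &
      !startsWith(reads, seed5) &
      count_chars(ins, "A") / nchar(ins) < params$polya_fraction
    out <- c(out, reads[ok])
  }
  out
}
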