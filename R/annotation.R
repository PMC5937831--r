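#' Exact genome mapping of unique tags
#'
#' Reports every zero-mismatch occurrence of each tag on both strands of the
#' genome. Minus-strand hits are occurrences of the tag's reverse complement
#' on the forward sequence. Coordinates are 0-based half-open internally
#' (converted at I/O boundaries).
#'
#' @param tags character vector of tag sequences (ACGT; tags containing N can
#'   never match and get no hits; any other letter is rejected)
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences
#' @return data.table with columns `tag`, `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`
#' @export
map_to_genome <- function(tags, genome) {
  stopifnot(length(tags) > 0)
  bad <- grepl("[^ACGTN]", tags)
  if (any(bad))
    stop("tags contain characters other than A/C/G/T/N: e.g. '",
         tags[bad][1], "'", call. = FALSE)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))

  clean <- unique(tags[!grepl("N", tags)])
  hits <- list()
  if (length(clean)) {
    widths <- nchar(clean)
    for (w in sort(unique(widths))) {
      grp <- clean[widths == w]
      for (strand in c("+", "-")) {
        pats <- if (strand == "+") grp else revcomp(grp)
        pd <- Biostrings::PDict(pats)
        for (chrom in names(genome)) {
          m <- Biostrings::matchPDict(pd, genome[[chrom]])
          cnt <- S4Vectors::elementNROWS(m)
          if (sum(cnt) == 0) next
          st <- unlist(lapply(m, BiocGenerics::start))
          hits[[length(hits) + 1L]] <- data.table::data.table(
            tag = rep(grp, cnt), chrom = chrom,
            start = st - 1L, end = st - 1L + w, strand = strand)
        }
      }
    }
  }
  if (!length(hits))
    return(data.table::data.table(tag = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  out <- data.table::rbindlist(hits)
  data.table::setorder(out, tag, chrom, start, strand)
  out[]
}

#' Match tags against the known-miRNA reference
#'
#' A tag is accepted as a known miRNA when it is a perfect substring of a
#' reference precursor and its position overlaps the annotated mature
#' sequence by at least `min_overlap` nt (offsets from the mature ends are
#' otherwise allowed). Ties across reference entries are broken by the
#' longest mature overlap, then by lexicographic miRNA name.
#'
#' @param tags character vector of tag sequences
#' @param known_ref data.frame with columns `mirna`, `family`, `precursor`,
#'   `mature` (mature must be a substring of its precursor)
#' @param min_overlap minimum tag/mature overlap in nt (default 16)
#' @return data.table `tag`, `mirna`, `family`, `precursor_offset` (1-based),
#'   `mature_overlap`; one best row per matching tag
#' @export
match_known_mirna <- function(tags, known_ref, min_overlap = 16L) {
  stopifnot(all(c("mirna", "family", "precursor", "mature") %in% names(known_ref)))
  mat_off <- vapply(seq_len(nrow(known_ref)), function(i) {
    p <- regexpr(known_ref$mature[i], known_ref$precursor[i], fixed = TRUE)
    if (p < 1) stop("mature of '", known_ref$mirna[i],
                    "' is not a substring of its precursor", call. = FALSE)
    as.integer(p)
  }, integer(1))

  res <- list()
  utags <- unique(tags)
  for (ti in seq_along(utags)) {
    tag <- utags[ti]
    wt <- nchar(tag)
    best <- NULL
    for (i in seq_len(nrow(known_ref))) {
      off <- as.integer(regexpr(tag, known_ref$precursor[i], fixed = TRUE))
      if (off < 1L) next
      m1 <- mat_off[i]; m2 <- m1 + nchar(known_ref$mature[i]) - 1L
      ov <- min(off + wt - 1L, m2) - max(off, m1) + 1L
      if (ov < min_overlap) next
      cand <- list(mirna = known_ref$mirna[i], family = known_ref$family[i],
                   precursor_offset = off, mature_overlap = ov)
      if (is.null(best) || cand$mature_overlap > best$mature_overlap ||
          (cand$mature_overlap == best$mature_overlap && cand$mirna < best$mirna))
        best <- cand
    }
    if (!is.null(best))
      res[[length(res) + 1L]] <- data.table::data.table(
        tag = tag, mirna = best$mirna, family = best$family,
        precursor_offset = best$precursor_offset,
        mature_overlap = best$mature_overlap)
  }
  if (!length(res))
    return(data.table::data.table(tag = character(), mirna = character(),
                                  family = character(),
                                  precursor_offset = integer(),
                                  mature_overlap = integer()))
  data.table::rbindlist(res)
}

# category priority: earlier wins (single-assignment accounting)
.CATEGORIES <- c("rRNA", "snRNA", "snoRNA", "tRNA", "repeat",
                 "exon_sense", "exon_antisense", "intron_sense",
                 "intron_antisense", "miRNA_known", "unannotated")

#' Hierarchically classify unique tags
#'
#' Assigns each tag exactly one category by priority: rRNA > snRNA > snoRNA >
#' tRNA > repeat > exon (sense, then antisense) > intron (sense, then
#' antisense) > known miRNA > unannotated. Structural-RNA and repeat
#' categories require a zero-mismatch genome hit overlapping a feature of
#' that type; exon/intron sense/antisense is relative to the feature strand;
#' known-miRNA acceptance follows [match_known_mirna()]. Tags matching
#' nothing (including tags with no genome hit) are unannotated.
#'
#' @param tags tag table from [collapse_tags()] (`sequence` + library count
#'   columns)
#' @param hits genome hits from [map_to_genome()]
#' @param features `GenomicRanges::GRanges` with a `type` metadata column
#'   (values among rRNA, snRNA, snoRNA, tRNA, repeat, exon, intron)
#' @param known_ref known-miRNA reference (see [match_known_mirna()])
#' @param min_overlap minimum tag/mature overlap for the known-miRNA rule
#' @return list with `assignments` (data.table `sequence`, `category`,
#'   `mirna`, `mapped`) and the input tag table merged in
#' @export
classify_tags <- function(tags, hits, features, known_ref, min_overlap = 16L) {
  tags <- data.table::as.data.table(tags)
  seqs <- tags$sequence
  category <- rep("unannotated", length(seqs))
  names(category) <- seqs

  if (nrow(hits) > 0 && length(features) > 0) {
    gr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$start + 1L, hits$end),
                                 strand = hits$strand)
    ov <- GenomicRanges::findOverlaps(gr, features, ignore.strand = TRUE)
    if (length(ov)) {
      ftype <- as.character(S4Vectors::mcols(features)$type)[S4Vectors::subjectHits(ov)]
      fstrand <- as.character(BiocGenerics::strand(features))[S4Vectors::subjectHits(ov)]
      tstrand <- hits$strand[S4Vectors::queryHits(ov)]
      sense <- ifelse(fstrand == "*", TRUE, tstrand == fstrand)
      cat_hit <- ifelse(ftype %in% c("exon", "intron"),
                        paste0(ftype, ifelse(sense, "_sense", "_antisense")),
                        ftype)
      dt <- data.table::data.table(
        tag = hits$tag[S4Vectors::queryHits(ov)],
        pri = match(cat_hit, .CATEGORIES))
      best <- dt[, .(pri = min(pri)), by = tag]
      category[best$tag] <- .CATEGORIES[best$pri]
    }
  }

  mirna <- rep(NA_character_, length(seqs))
  names(mirna) <- seqs
  open <- seqs[category[seqs] == "unannotated"]
  if (length(open) && nrow(known_ref)) {
    km <- match_known_mirna(open, known_ref, min_overlap = min_overlap)
    if (nrow(km)) {
      category[km$tag] <- "miRNA_known"
      mirna[km$tag] <- km$mirna
    }
  }

  mapped <- seqs %in% unique(hits$tag)
  assignments <- data.table::data.table(
    sequence = seqs,
    category = factor(category[seqs], levels = .CATEGORIES),
    mirna = mirna[seqs], mapped = mapped)
  list(assignments = cbind(assignments, tags[, !"sequence"]))
}

#' Per-library annotation summary (classification table)
#'
#' For each library and category: number of unique tags and total reads, with
#' percentages of the library's unique-tag and clean-read totals (two
#' decimals, half-up), plus a closing `total` row. Sum of category totals
#' equals clean reads; sum of unique counts equals unique tags.
#'
#' @param assignments output `assignments` of [classify_tags()]
#' @param libraries library count columns (default: all count columns)
#' @return data.frame in long form: `category`, `library`, `unique_tags`,
#'   `unique_percent`, `total_reads`, `total_percent`
#' @export
annotation_summary <- function(assignments, libraries = NULL) {
  a <- data.table::as.data.table(assignments)
  if (is.null(libraries))
    libraries <- setdiff(names(a), c("sequence", "category", "mirna", "mapped"))
  out <- list()
  for (lib in libraries) {
    counts <- a[[lib]]
    present <- counts > 0L
    lib_unique <- sum(present)
    lib_total <- sum(counts)
    per_cat <- a[present, .(unique_tags = .N, total_reads = sum(get(lib))),
                 by = category]
    per_cat <- per_cat[data.table::data.table(category = factor(.CATEGORIES,
                                                                levels = .CATEGORIES)),
                       on = "category"]
    per_cat[is.na(unique_tags), `:=`(unique_tags = 0L, total_reads = 0L)]
    per_cat[, `:=`(library = lib,
                   unique_percent = round_half_up(100 * unique_tags / lib_unique, 2),
                   total_percent = round_half_up(100 * total_reads / lib_total, 2))]
    total_row <- data.table::data.table(
      category = "total", unique_tags = lib_unique, total_reads = lib_total,
      library = lib, unique_percent = NA_real_, total_percent = NA_real_)
    out[[lib]] <- rbind(per_cat[, .(category = as.character(category), library,
                                    unique_tags, unique_percent, total_reads,
                                    total_percent)],
                        total_row[, .(category, library, unique_tags,
                                      unique_percent, total_reads, total_percent)])
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Base bias of identified miRNA tags
#'
#' Either the composition of the first base stratified by tag length
#' (`first_position_by_length`) or the composition at every position over all
#' tags (`per_position`). Fractions within a length (or position) sum to 1.
#'
#' @param sequences character vector of tag sequences
#' @param which `"first_position_by_length"` or `"per_position"`
#' @param weights optional per-tag read counts; default weights each unique
#'   tag equally
#' @return a fraction matrix (rows: lengths or positions; columns: A/C/G/T)
#' @export
base_bias <- function(sequences,
                      which = c("first_position_by_length", "per_position"),
                      weights = NULL) {
  which <- match.arg(which)
  stopifnot(length(sequences) > 0)
  if (is.null(weights)) weights <- rep(1, length(sequences))
  bases <- c("A", "C", "G", "T")
  if (which == "first_position_by_length") {
    len <- nchar(sequences)
    first <- substr(sequences, 1, 1)
    lens <- sort(unique(len))
    m <- t(vapply(lens, function(L) {
      sel <- len == L
      w <- vapply(bases, function(b) sum(weights[sel][first[sel] == b]),
                  numeric(1))
      w / sum(w)
    }, numeric(4)))
    dimnames(m) <- list(lens, bases)
    m
  } else {
    width <- max(nchar(sequences))
    m <- matrix(NA_real_, nrow = width, ncol = 4,
                dimnames = list(seq_len(width), bases))
    for (i in seq_len(width)) {
      b <- substr(sequences, i, i)
      sel <- b != ""
      w <- vapply(bases, function(x) sum(weights[sel][b[sel] == x]), numeric(1))
      m[i, ] <- w / sum(w)
    }
    m
  }
}
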