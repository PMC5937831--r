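#' Candidate precursor windows around an unannotated tag hit
#'
#' For each genome hit of a tag, two windows are extracted: one extending
#' `flank` nt upstream of the tag (tag on the 3' arm) and one extending
#' `flank` nt downstream (tag on the 5' arm). Windows are strand-aware: for
#' minus-strand hits the reverse-complemented sequence is returned and
#' "upstream" refers to the tag's own 5' direction. Windows truncated at a
#' contig edge are shrunk and flagged.
#'
#' @param hits data.table of genome hits (see [map_to_genome()]) for tags in
#'   unannotated space
#' @param genome named character vector or `DNAStringSet`
#' @param flank nt of flanking sequence beyond the tag (default 100)
#' @return data.table: `tag`, `chrom`, `start`, `end` (0-based half-open,
#'   genome coordinates), `strand`, `arm` (`"5p"`/`"3p"`: the arm the tag
#'   would occupy), `truncated`, `tag_offset` (0-based offset of the tag in
#'   the window sequence), `window` (sequence, tag strand)
#' @export
extract_precursor_windows <- function(hits, genome, flank = 100L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- list()
  flank <- as.integer(flank)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    L <- chrlen[[h$chrom]]
    for (side in c("up", "down")) {
      genomic_up <- (side == "up") == (h$strand == "+")
      ws <- if (genomic_up) max(0L, h$start - flank) else h$start
      we <- if (genomic_up) h$end else min(L, h$end + flank)
      truncated <- if (genomic_up) ws == 0L && h$start - flank < 0L
                   else we == L && h$end + flank > L
      seq <- substr(as.character(genome[[h$chrom]]), ws + 1L, we)
      if (h$strand == "-") seq <- revcomp(seq)
      tag_offset <- if (genomic_up == (h$strand == "+")) we - ws - (h$end - h$start)
                    else 0L
      out[[length(out) + 1L]] <- data.table::data.table(
        tag = h$tag, chrom = h$chrom, start = as.integer(ws),
        end = as.integer(we), strand = h$strand,
        arm = if (side == "up") "3p" else "5p",
        truncated = truncated, tag_offset = as.integer(tag_offset),
        window = seq)
    }
  }
  data.table::rbindlist(out)
}

# pair weight lookup for the stem search: Watson-Crick = 1, G:U wobble = 0.5,
# anything else (incl. N) = -2. The mismatch penalty sets the detector's
# specificity: at -2, >95% of random 100-mers fall short of the default
# score threshold (codes A1 C2 G3 T4 N5)
.pair_weight_table <- local({
  w <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  w["A", "T"] <- w["T", "A"] <- 1
  w["G", "C"] <- w["C", "G"] <- 1
  w["G", "T"] <- w["T", "G"] <- 0.5
  w
})

#' Fold a candidate window with a maximum-complementarity stem search
#'
#' A deterministic stand-in for thermodynamic folding: over every antiparallel
#' ungapped stem placement (pairing position `i` with position `j`, extending
#' outward/inward along the diagonal `i + j`), find the contiguous run
#' maximising `WC + 0.5*G:U - 2*mismatches`, subject to a minimum loop of
#' `min_loop` unpaired nt between the arms. The reported score is
#' `-(WC + 0.5*G:U)` over that run (more negative = more stable, a proxy for
#' minimum folding free energy); `paired` counts the paired bases (WC + G:U)
#' per arm.
#'
#' @param window a single DNA sequence (>= 50 nt for candidate calling;
#'   shorter sequences are scored all the same)
#' @param min_loop minimum loop length in nt (default 3)
#' @return list: `score`, `paired`, and `layout`, a data.frame of paired
#'   positions (`i` < `j`, 1-based) with pair `type` (`"WC"`/`"GU"`/`"MM"`)
#'   for the best stem run
#' @export
fold_and_score <- function(window, min_loop = 3L) {
  stopifnot(length(window) == 1L, nchar(window) > 0L)
  s <- strsplit(toupper(window), "")[[1]]
  code <- match(s, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  n <- length(code)
  wtab <- .pair_weight_table
  best <- list(sum = 0, from = NA_integer_, to = NA_integer_, d = NA_integer_)
  for (d in seq(3L, 2L * n - 1L)) {
    # pairing (t, d - t); t runs outermost -> innermost; loop constraint
    # applies to the innermost pair of any run ending at t
    t_lo <- max(1L, d - n)
    t_hi <- (d - min_loop - 1L) %/% 2L
    if (t_hi < t_lo) next
    run_sum <- 0; run_start <- t_lo
    for (t in t_lo:t_hi) {
      w <- wtab[code[t], code[d - t]]
      if (run_sum <= 0) { run_sum <- w; run_start <- t } else run_sum <- run_sum + w
      if (run_sum > best$sum) {
        best <- list(sum = run_sum, from = run_start, to = t, d = d)
      }
    }
  }
  if (is.na(best$from))
    return(list(score = 0, paired = 0L,
                layout = data.frame(i = integer(), j = integer(),
                                    type = character())))
  ts <- best$from:best$to
  i <- ts; j <- best$d - ts
  w <- wtab[cbind(code[i], code[j])]
  type <- ifelse(w == 1, "WC", ifelse(w == 0.5, "GU", "MM"))
  paired <- sum(w > 0)
  score <- -sum(w[w > 0])
  list(score = score, paired = as.integer(paired),
       layout = data.frame(i = i, j = j, type = type))
}

#' Default thresholds for novel miRNA candidate calling
#'
#' Conventions, not literature facts: at least `min_mature_pairs` paired
#' bases within the mature tag, loop of at least `min_loop` nt, stem score at
#' most `score_max`, and the tag's ends within `max_end_dist` nt of a stem
#' end (a Dicer-cut proxy). Candidates expressed in fewer than
#' `min_libraries` libraries are removed.
#'
#' @param min_mature_pairs minimum paired bases inside the tag (14)
#' @param min_loop minimum loop length (3)
#' @param score_max maximum (most positive) pairing score (-14)
#' @param max_end_dist maximum distance from tag end to stem end (3)
#' @param min_libraries minimum libraries with nonzero support (2)
#' @param flank window flank in nt (100)
#' @return list of thresholds
#' @export
novel_params <- function(min_mature_pairs = 14L, min_loop = 3L,
                         score_max = -14, max_end_dist = 3L,
                         min_libraries = 2L, flank = 100L) {
  list(min_mature_pairs = min_mature_pairs, min_loop = min_loop,
       score_max = score_max, max_end_dist = max_end_dist,
       min_libraries = min_libraries, flank = flank)
}

#' Call novel miRNA candidates from unannotated genome-mapped tags
#'
#' For every unannotated tag with a genome hit, flanking windows are folded
#' ([fold_and_score()]); a window qualifies when the stem satisfies
#' [novel_params()]. Overlapping candidate loci are merged (support counts
#' summed; the most abundant tag becomes the mature), and candidates
#' expressed in fewer than `min_libraries` libraries are dropped.
#'
#' @param tags tag table (`sequence` + library counts) restricted to, or
#'   filterable to, unannotated tags
#' @param hits genome hits for those tags ([map_to_genome()])
#' @param genome genome sequences
#' @param params thresholds from [novel_params()]
#' @param libraries library count columns (default: all except `sequence`)
#' @return data.table: `id`, `chrom`, `start`, `end` (0-based half-open locus
#'   of the folded stem region), `strand`, `mature`, `score`, `paired`, plus
#'   one support-count column per library
#' @export
call_novel_candidates <- function(tags, hits, genome, params = novel_params(),
                                  libraries = NULL) {
  tags <- data.table::as.data.table(tags)
  if (is.null(libraries)) libraries <- setdiff(names(tags), "sequence")
  hits <- data.table::as.data.table(hits)[tag %in% tags$sequence]
  empty <- data.table::data.table(
    id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), mature = character(),
    score = numeric(), paired = integer())
  for (l in libraries) empty[[l]] <- integer()
  if (nrow(hits) == 0) return(empty)

  wins <- extract_precursor_windows(hits, genome, flank = params$flank)
  cand <- list()
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    if (nchar(w$window) < 50L) next
    f <- fold_and_score(w$window, min_loop = params$min_loop)
    if (f$paired == 0L || f$score > params$score_max) next
    tag_len <- nchar(w$tag)
    t1 <- w$tag_offset + 1L; t2 <- w$tag_offset + tag_len   # 1-based in window
    pairpos <- c(f$layout$i[f$layout$type != "MM"], f$layout$j[f$layout$type != "MM"])
    mature_pairs <- sum(pairpos >= t1 & pairpos <= t2)
    if (mature_pairs < params$min_mature_pairs) next
    # Dicer proxy: both tag ends near the stem-arm ends on the tag's arm
    stem_i <- range(f$layout$i); stem_j <- range(f$layout$j)
    on_i <- t1 >= stem_i[1] - params$max_end_dist && t2 <= stem_i[2] + params$max_end_dist
    on_j <- t1 >= stem_j[1] - params$max_end_dist && t2 <= stem_j[2] + params$max_end_dist
    d_i <- min(abs(t1 - stem_i[1]), abs(t2 - stem_i[2]))
    d_j <- min(abs(t1 - stem_j[1]), abs(t2 - stem_j[2]))
    if (!((on_i && d_i <= params$max_end_dist) ||
          (on_j && d_j <= params$max_end_dist))) next
    # stem locus in genome coordinates
    lo <- min(f$layout$i) - 1L; hi <- max(f$layout$j)
    if (w$strand == "+") {
      g1 <- w$start + lo; g2 <- w$start + hi
    } else {
      g1 <- w$end - hi; g2 <- w$end - lo
    }
    cand[[length(cand) + 1L]] <- data.table::data.table(
      tag = w$tag, chrom = w$chrom, start = as.integer(g1),
      end = as.integer(g2), strand = w$strand, score = f$score,
      paired = f$paired)
  }
  if (!length(cand)) return(empty)
  cd <- unique(data.table::rbindlist(cand))

  # merge overlapping loci into candidates; a hairpin detected from both
  # strands is one locus
  gr <- GenomicRanges::GRanges(cd$chrom, IRanges::IRanges(cd$start + 1L, cd$end),
                               strand = cd$strand)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  BiocGenerics::strand(gr) <- "*"
  idx <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, merged))
  cd[, locus := idx]

  counts <- tags[, c("sequence", libraries), with = FALSE]
  out <- list()
  for (g in sort(unique(cd$locus))) {
    sub <- cd[locus == g]
    member_tags <- unique(sub$tag)
    cc <- counts[sequence %in% member_tags]
    support <- vapply(libraries, function(l) sum(cc[[l]]), numeric(1))
    if (sum(support > 0) < params$min_libraries) next
    tot <- rowSums(cc[, libraries, with = FALSE])
    mature <- cc$sequence[order(-tot, cc$sequence)][1]
    best <- sub[order(score, tag)][1]
    row <- data.table::data.table(
      id = NA_character_, chrom = best$chrom,
      start = min(sub$start), end = max(sub$end), strand = best$strand,
      mature = mature, score = best$score, paired = best$paired)
    for (l in libraries) row[[l]] <- as.integer(support[[l]])
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start)
  res[, id := sprintf("novel-m%04d", .I)]
  data.table::setcolorder(res, c("id", "chrom", "start", "end", "strand",
                                 "mature", "score", "paired", libraries))
  res[]
}
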