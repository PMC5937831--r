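#' Decode a FASTQ quality string
#'
#' Sequencing quality is stored one ASCII character per base; the numeric
#' quality is the character's ASCII value minus the encoding offset (64 for
#' phred64, the default of the HiSeq era this pipeline targets; 33 for
#' phred33). Valid qualities range from 0 to 41.
#'
#' @param quality a single quality string
#' @param encoding `"phred64"` (default) or `"phred33"`
#' @return integer vector of per-base qualities
#' @examples
#' decode_quality("h@J") # 40 0 10
#' @export
decode_quality <- function(quality, encoding = c("phred64", "phred33")) {
  encoding <- match.arg(encoding)
  stopifnot(is.character(quality), length(quality) == 1L, nchar(quality) > 0L)
  offset <- if (encoding == "phred64") 64L else 33L
  q <- utf8ToInt(quality) - offset
  if (any(q < 0L | q > 41L)) {
    other <- setdiff(c("phred64", "phred33"), encoding)
    stop("quality values outside [0, 41] under ", encoding,
         "; the file may be ", other, "-encoded", call. = FALSE)
  }
  q
}

#' Filtering parameters for raw small RNA reads
#'
#' Thresholds for the seven-rule contaminant filter. Defaults follow the
#' pipeline conventions documented in the methods vignette: a read is low
#' quality when at least `low_quality_bases` bases fall below
#' `low_quality_threshold`; the N rule removes reads whose fraction of
#' undetermined bases exceeds `max_n_fraction`; the 3' adapter is located by
#' exact match, falling back to a terminal adapter prefix of at least
#' `adapter3_seed` nt; poly(A) inserts are those with at least
#' `polya_fraction` adenines; inserts shorter than `min_length` nt are
#' removed.
#'
#' @param low_quality_threshold quality below which a base counts as low (10)
#' @param low_quality_bases number of low bases that flags a read (4)
#' @param max_n_fraction maximum tolerated fraction of N bases (0.10)
#' @param adapter5_seed length of the 5' adapter prefix used to detect 5'
#'   contaminants (8)
#' @param adapter3_seed minimum terminal 3'-adapter prefix accepted when the
#'   full adapter is truncated (6)
#' @param polya_fraction adenine fraction at or above which a trimmed insert
#'   is called poly(A) (0.80)
#' @param min_length minimum insert length kept (18)
#' @return a list of class `spidmir_filter_params`
#' @export
filter_params <- function(low_quality_threshold = 10L, low_quality_bases = 4L,
                          max_n_fraction = 0.10, adapter5_seed = 8L,
                          adapter3_seed = 6L, polya_fraction = 0.80,
                          min_length = 18L) {
  structure(list(low_quality_threshold = as.integer(low_quality_threshold),
                 low_quality_bases = as.integer(low_quality_bases),
                 max_n_fraction = max_n_fraction,
                 adapter5_seed = as.integer(adapter5_seed),
                 adapter3_seed = as.integer(adapter3_seed),
                 polya_fraction = polya_fraction,
                 min_length = as.integer(min_length)),
            class = "spidmir_filter_params")
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped)
#' @return data.frame with columns `id`, `sequence`, `quality`
#' @export
read_fastq <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs),
             quality = as.character(S4Vectors::mcols(seqs)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `quality`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

# locate the 3' adapter: first exact full-adapter occurrence, else the longest
# terminal prefix of the adapter (>= seed nt) at the read end. Returns the
# insert length, or NA when no adapter evidence is found (adapter3 null).
locate_adapter3 <- function(seqs, adapter3, seed) {
  pos <- regexpr(adapter3, seqs, fixed = TRUE)
  insert_len <- ifelse(pos > 0L, pos - 1L, NA_integer_)
  n <- nchar(seqs)
  for (k in seq(min(nchar(adapter3) - 1L, max(n)), seed)) {
    if (k < seed) break
    cand <- which(is.na(insert_len) & n >= k)
    if (!length(cand)) next
    hit <- substr(seqs[cand], n[cand] - k + 1L, n[cand]) == substr(adapter3, 1L, k)
    insert_len[cand[hit]] <- n[cand[hit]] - k
  }
  as.integer(insert_len)
}

#' Seven-rule filtering of raw small RNA reads
#'
#' Applies, in order: (1) low-quality removal (at least 4 bases with quality
#' below 10); (2) removal of reads whose proportion of N exceeds 10%;
#' (3) removal of 5' primer contaminants; (4) removal of reads without an
#' insert (3' adapter at position 1); (5) removal of reads without a 3'
#' adapter; (6) removal of poly(A) inserts; (7) removal of inserts shorter
#' than 18 nt. Each removed read is attributed to the first rule it fails;
#' survivors are emitted as trimmed inserts.
#'
#' @param reads data.frame from [read_fastq()] (columns `id`, `sequence`,
#'   `quality`), or a FASTQ path
#' @param adapter3 3' adapter sequence
#' @param adapter5 5' adapter sequence
#' @param params a [filter_params()] object
#' @param encoding quality encoding, `"phred64"` or `"phred33"`
#' @return list with `clean` (data.frame `id`, `insert`), `category`
#'   (per-read factor: clean or removal category) and `report`
#'   (a [filter_report()])
#' @export
filter_reads <- function(reads, adapter3, adapter5, params = filter_params(),
                         encoding = c("phred64", "phred33")) {
  encoding <- match.arg(encoding)
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)),
            nzchar(adapter3), nzchar(adapter5))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch in input reads", call. = FALSE)

  offset <- if (encoding == "phred64") 64L else 33L
  qual <- reads$quality
  bad <- grepl(sprintf("[^%s-%s]", intToUtf8(offset), intToUtf8(offset + 41L)),
               qual, perl = TRUE)
  if (any(bad)) {
    other <- setdiff(c("phred64", "phred33"), encoding)
    stop("quality characters outside [0, 41] under ", encoding, " in ",
         sum(bad), " read(s); the file may be ", other, "-encoded",
         call. = FALSE)
  }

  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  len <- nchar(seqs)

  # rule (1): >= low_quality_bases bases with quality < threshold
  low_class <- sprintf("[%s-%s]", intToUtf8(offset),
                       intToUtf8(offset + params$low_quality_threshold - 1L))
  n_low <- count_chars(qual, low_class)
  r1 <- n_low >= params$low_quality_bases

  # rule (2): proportion of N > max_n_fraction
  r2 <- count_chars(seqs, "N") / len > params$max_n_fraction

  # rule (3): 5' primer contaminant (read begins with the 5' adapter seed)
  seed5 <- substr(adapter5, 1L, min(nchar(adapter5), params$adapter5_seed))
  r3 <- startsWith(seqs, seed5)

  insert_len <- locate_adapter3(seqs, adapter3, params$adapter3_seed)
  r4 <- !is.na(insert_len) & insert_len == 0L        # insert null
  r5 <- is.na(insert_len)                            # 3' adapter null
  insert <- substr(seqs, 1L, ifelse(is.na(insert_len), 0L, insert_len))

  frac_a <- ifelse(insert_len > 0L & !is.na(insert_len),
                   count_chars(insert, "A") / pmax(insert_len, 1L), 0)
  r6 <- !is.na(insert_len) & insert_len > 0L & frac_a >= params$polya_fraction
  r7 <- !is.na(insert_len) & insert_len < params$min_length

  lev <- c("low_quality", "high_N", "adapter5_contaminant", "insert_null",
           "adapter3_null", "polyA", "shorter_than_18nt", "clean")
  cat_idx <- rep.int(8L, n)
  for (i in 7:1) {
    r <- switch(i, r1, r2, r3, r4, r5, r6, r7)
    cat_idx[r] <- i
  }
  category <- factor(lev[cat_idx], levels = lev)

  tab <- table(category)
  report <- filter_report(total_reads = n,
                          low_quality = tab[["low_quality"]],
                          high_N = tab[["high_N"]],
                          adapter3_null = tab[["adapter3_null"]],
                          insert_null = tab[["insert_null"]],
                          adapter5_contaminant = tab[["adapter5_contaminant"]],
                          shorter_than_18nt = tab[["shorter_than_18nt"]],
                          polyA = tab[["polyA"]])
  keep <- category == "clean"
  list(clean = data.frame(id = reads$id[keep], insert = insert[keep],
                          stringsAsFactors = FALSE),
       category = category, report = report)
}

#' Removal-category accounting for one library
#'
#' Closes the books on the filter: `high_quality = total - low_quality -
#' high_N`, and `clean = high_quality - (adapter3_null + insert_null +
#' adapter5_contaminant + shorter_than_18nt + polyA)`. Percentages of the
#' adapter/length/poly(A) categories and of clean reads are computed against
#' the high-quality count and rounded half-up to two decimals, the layout of
#' the standard library-cleaning summary table.
#'
#' Either pass `low_quality` and `high_N`, or pass `high_quality` directly
#' (as published summaries do, which pool the two quality rules).
#'
#' @param total_reads raw read count
#' @param low_quality,high_N reads removed by the two quality rules
#' @param high_quality optionally, the high-quality count itself
#' @param adapter3_null,insert_null,adapter5_contaminant,shorter_than_18nt,polyA
#'   reads removed by the adapter/length/poly(A) rules
#' @return a list of class `spidmir_filter_report` with the counts, the
#'   derived `high_quality` and `clean_reads`, and `percent` (named, two
#'   decimals, relative to high-quality reads)
#' @export
filter_report <- function(total_reads, low_quality = NULL, high_N = NULL,
                          high_quality = NULL, adapter3_null = 0,
                          insert_null = 0, adapter5_contaminant = 0,
                          shorter_than_18nt = 0, polyA = 0) {
  if (is.null(high_quality)) {
    stopifnot(!is.null(low_quality), !is.null(high_N))
    high_quality <- total_reads - low_quality - high_N
  }
  cats <- c(adapter3_null = adapter3_null, insert_null = insert_null,
            adapter5_contaminant = adapter5_contaminant,
            shorter_than_18nt = shorter_than_18nt, polyA = polyA)
  clean <- high_quality - sum(cats)
  stopifnot(high_quality >= 0, clean >= 0)
  percent <- round_half_up(100 * c(high_quality = high_quality, cats,
                                   clean_reads = clean) / high_quality, 2)
  structure(list(total_reads = total_reads,
                 low_quality = if (is.null(low_quality)) NA_real_ else low_quality,
                 high_N = if (is.null(high_N)) NA_real_ else high_N,
                 high_quality = high_quality,
                 adapter3_null = unname(adapter3_null),
                 insert_null = unname(insert_null),
                 adapter5_contaminant = unname(adapter5_contaminant),
                 shorter_than_18nt = unname(shorter_than_18nt),
                 polyA = unname(polyA),
                 clean_reads = clean, percent = percent),
            class = "spidmir_filter_report")
}

#' @export
print.spidmir_filter_report <- function(x, ...) {
  cat("Library cleaning summary\n")
  rows <- c("total_reads", "high_quality", "adapter3_null", "insert_null",
            "adapter5_contaminant", "shorter_than_18nt", "polyA", "clean_reads")
  for (r in rows) {
    pct <- if (r %in% names(x$percent)) sprintf(" (%.2f%%)", x$percent[[r]]) else ""
    cat(sprintf("  %-22s %12s%s\n", r, format(x[[r]], big.mark = ","), pct))
  }
  invisible(x)
}

#' Combine per-library filter reports into one table
#'
#' @param reports named list of [filter_report()] objects (names are library
#'   labels)
#' @return data.frame with one row per accounting category and count/percent
#'   columns per library
#' @export
filter_report_table <- function(reports) {
  rows <- c("total_reads", "high_quality", "adapter3_null", "insert_null",
            "adapter5_contaminant", "shorter_than_18nt", "polyA", "clean_reads")
  out <- data.frame(category = rows, stringsAsFactors = FALSE)
  for (lib in names(reports)) {
    rep <- reports[[lib]]
    out[[paste0(lib, "_count")]] <- vapply(rows, function(r) as.numeric(rep[[r]]),
                                           numeric(1))
    out[[paste0(lib, "_percent")]] <-
      vapply(rows, function(r) if (r %in% names(rep$percent))
        rep$percent[[r]] else NA_real_, numeric(1))
  }
  out
}

#' Collapse clean inserts into unique tags with per-library counts
#'
#' Identical insert sequences are grouped into one unique tag; the tag table
#' carries one count column per library. Totals report clean reads, unique
#' tags and the mean reads per unique sequence (rounded to the nearest
#' integer, the convention of published summaries).
#'
#' @param inserts_by_library named list of character vectors of trimmed
#'   inserts, one element per library
#' @return list with `tags` (data.table: `sequence` plus one count column per
#'   library), `totals` (data.frame per library: `total_reads`,
#'   `unique_reads`), `grand_total`, `grand_unique`,
#'   `mean_reads_per_unique`
#' @export
collapse_tags <- function(inserts_by_library) {
  stopifnot(is.list(inserts_by_library), length(names(inserts_by_library)) > 0)
  libs <- names(inserts_by_library)
  dt <- data.table::rbindlist(lapply(libs, function(l)
    data.table::data.table(sequence = inserts_by_library[[l]], library = l)))
  tags <- data.table::dcast(dt[, .N, by = .(sequence, library)],
                            sequence ~ library, value.var = "N", fill = 0L)
  for (l in setdiff(libs, names(tags))) tags[[l]] <- 0L
  data.table::setcolorder(tags, c("sequence", libs))
  totals <- data.frame(
    library = libs,
    total_reads = vapply(libs, function(l) sum(tags[[l]]), numeric(1)),
    unique_reads = vapply(libs, function(l) sum(tags[[l]] > 0L), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  grand_total <- sum(totals$total_reads)
  grand_unique <- nrow(tags)
  list(tags = tags[order(sequence)], totals = totals,
       grand_total = grand_total, grand_unique = grand_unique,
       mean_reads_per_unique = round_half_up(grand_total / grand_unique, 0))
}

#' Length distribution of clean reads
#'
#' Per-library percentage of clean reads by insert length (weighted by read
#' counts, not unique tags).
#'
#' @param tags tag table from [collapse_tags()]
#' @param libraries library columns to use (default: all count columns)
#' @return data.frame `length`, `library`, `reads`, `percent`
#' @export
length_distribution <- function(tags, libraries = NULL) {
  tags <- data.table::as.data.table(tags)
  if (is.null(libraries)) libraries <- setdiff(names(tags), "sequence")
  len <- nchar(tags$sequence)
  out <- data.table::rbindlist(lapply(libraries, function(l) {
    counts <- tags[[l]]
    tot <- sum(counts)
    if (tot == 0) stop("library '", l, "' has no clean reads", call. = FALSE)
    agg <- data.table::data.table(length = len, reads = counts)[
      , .(reads = sum(reads)), by = length][reads > 0][order(length)]
    agg[, `:=`(library = l, percent = 100 * reads / tot)]
    agg
  }))
  as.data.frame(out[, .(length, library, reads, percent)])
}

#' Per-position base composition and mean quality
#'
#' @param sequences character vector of reads or inserts
#' @param qualities optional matching quality strings
#' @param encoding quality encoding (see [decode_quality()])
#' @return list with `composition` (positions x A/C/G/T/N fractions) and,
#'   when qualities are given, `mean_quality` (per-position mean)
#' @export
base_profiles <- function(sequences, qualities = NULL,
                          encoding = c("phred64", "phred33")) {
  encoding <- match.arg(encoding)
  stopifnot(length(sequences) > 0)
  offset <- if (encoding == "phred64") 64L else 33L
  width <- max(nchar(sequences))
  bases <- c("A", "C", "G", "T", "N")
  comp <- matrix(0, nrow = width, ncol = length(bases),
                 dimnames = list(NULL, bases))
  meanq <- rep(NA_real_, width)
  for (i in seq_len(width)) {
    b <- substr(sequences, i, i)
    b <- b[b != ""]
    comp[i, ] <- vapply(bases, function(x) sum(b == x), numeric(1)) / length(b)
    if (!is.null(qualities)) {
      qc <- substr(qualities, i, i)
      qc <- qc[qc != ""]
      meanq[i] <- mean(vapply(qc, function(ch) utf8ToInt(ch) - offset,
                              numeric(1)))
    }
  }
  out <- list(composition = comp)
  if (!is.null(qualities)) out$mean_quality <- meanq
  out
}
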