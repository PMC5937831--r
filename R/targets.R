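#' Penalty score of a miRNA/target-site alignment
#'
#' Ungapped plant-style complementarity scoring: the miRNA (5' to 3') is
#' aligned position-by-position against the reverse complement of a
#' transcript window of the same length. Each mismatch costs 1, each G:U
#' wobble 0.5, and costs are doubled at miRNA positions 2-13 (the
#' seed/cleavage-critical region).
#'
#' @param mirna miRNA sequence, 5' to 3' (DNA letters; U accepted)
#' @param window transcript window of the same length, transcript 5' to 3'
#' @return list: `penalty`, `mismatches`, `gu`, `mismatch_positions`,
#'   `gu_positions` (1-based from the miRNA 5' end)
#' @export
score_target <- function(mirna, window) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  window <- toupper(window)
  if (nchar(mirna) != nchar(window))
    stop("window length must equal miRNA length (ungapped model)", call. = FALSE)
  m <- strsplit(mirna, "")[[1]]
  # antiparallel: miRNA position i pairs window position k - i + 1
  t <- rev(strsplit(window, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- unname(comp[m]) == t
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  mm <- !wc & !gu
  pos <- seq_along(m)
  weight <- ifelse(pos >= 2 & pos <= 13, 2, 1)
  penalty <- sum(weight[mm]) + 0.5 * sum(weight[gu])
  list(penalty = penalty, mismatches = sum(mm), gu = sum(gu),
       mismatch_positions = pos[mm], gu_positions = pos[gu])
}

#' Target-prediction rule presets
#'
#' Two honest, natively implemented rule presets standing in for the two
#' external plant target-prediction engines whose intersection defines the
#' final call: `strict` (maximum penalty 4.0, no mismatch at miRNA positions
#' 10-11) and `relaxed` (maximum penalty 5.0). Both use the ungapped
#' [score_target()] model.
#'
#' @param strict_max maximum penalty under the strict preset (4.0)
#' @param relaxed_max maximum penalty under the relaxed preset (5.0)
#' @return named list of preset definitions
#' @export
target_presets <- function(strict_max = 4.0, relaxed_max = 5.0) {
  list(strict = list(max_penalty = strict_max, no_mismatch_at = c(10L, 11L)),
       relaxed = list(max_penalty = relaxed_max, no_mismatch_at = integer()))
}

# vectorized penalty of one miRNA against all same-length windows of a transcript
scan_transcript <- function(mirna, tx) {
  k <- nchar(mirna)
  L <- nchar(tx)
  if (L < k) return(NULL)
  starts <- seq_len(L - k + 1L)
  m <- strsplit(mirna, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  penalty <- numeric(length(starts))
  mm_n <- integer(length(starts)); gu_n <- integer(length(starts))
  mm1011 <- logical(length(starts))
  for (i in seq_len(k)) {
    # miRNA position i pairs with window position k - i + 1
    tpos <- starts + (k - i)
    tb <- substr(rep(tx, length(starts)), tpos, tpos)
    wc <- tb == comp[[m[i]]]
    gu <- (m[i] == "G" & tb == "T") | (m[i] == "T" & tb == "G")
    mm <- !wc & !gu
    w <- if (i >= 2 && i <= 13) 2 else 1
    penalty <- penalty + w * mm + 0.5 * w * gu
    mm_n <- mm_n + mm; gu_n <- gu_n + gu
    if (i %in% c(10L, 11L)) mm1011 <- mm1011 | mm
  }
  data.frame(start = starts, penalty = penalty, mismatches = mm_n,
             gu = gu_n, mm_at_10_11 = mm1011)
}

#' Predict miRNA targets as the intersection of two rule presets
#'
#' Every window of every transcript is scored against every miRNA under each
#' preset; a gene is a predicted target of a miRNA only when found under
#' both presets (the intersection is taken per miRNA over gene sets).
#' Reported hits are the strict-preset sites of intersection genes.
#'
#' @param mirnas named character vector of mature miRNA sequences
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences; names are gene ids
#' @param presets from [target_presets()]
#' @return data.table `mirna`, `gene`, `start` (1-based site start on the
#'   transcript), `penalty`, `mismatches`, `gu`
#' @export
predict_targets <- function(mirnas, transcripts, presets = target_presets()) {
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)),
            !is.null(names(mirnas)))
  out <- list()
  for (mi in names(mirnas)) {
    mseq <- chartr("Uu", "Tt", toupper(mirnas[[mi]]))
    gene_sets <- list(); site_tab <- list()
    for (pn in names(presets)) {
      pr <- presets[[pn]]
      genes <- character(); sites <- list()
      for (g in names(transcripts)) {
        sc <- scan_transcript(mseq, toupper(transcripts[[g]]))
        if (is.null(sc)) next
        ok <- sc$penalty <= pr$max_penalty
        if (length(pr$no_mismatch_at)) ok <- ok & !sc$mm_at_10_11
        if (any(ok)) {
          genes <- c(genes, g)
          sites[[g]] <- cbind(gene = g, sc[ok, , drop = FALSE])
        }
      }
      gene_sets[[pn]] <- genes
      site_tab[[pn]] <- sites
    }
    common <- Reduce(intersect, gene_sets)
    for (g in common) {
      s <- site_tab[[1]][[g]]
      out[[length(out) + 1L]] <- data.table::data.table(
        mirna = mi, gene = g, start = s$start, penalty = s$penalty,
        mismatches = s$mismatches, gu = s$gu)
    }
  }
  if (!length(out))
    return(data.table::data.table(mirna = character(), gene = character(),
                                  start = integer(), penalty = numeric(),
                                  mismatches = integer(), gu = integer()))
  res <- data.table::rbindlist(out)
  data.table::setorder(res, mirna, gene, start)
  res[]
}

#' Hypergeometric term enrichment of a target-gene set
#'
#' For every functional term, tests whether the target set contains
#' unexpectedly many of the term's genes given the background: upper-tail
#' hypergeometric probability `P(X >= k)` with `k` term genes among the `n`
#' targets, `K` among the `N` background genes. P-values are corrected per
#' term class (default Benjamini-Hochberg); terms with corrected p < `alpha`
#' are flagged enriched. Terms absent from the background are skipped with a
#' warning.
#'
#' @param target_genes character vector (must be a subset of the background)
#' @param background_genes character vector of all annotated genes
#' @param term_map data.frame `gene`, `term`, `class` (e.g. GO ontology or
#'   pathway class)
#' @param method correction method passed to [stats::p.adjust()] ("BH")
#' @param alpha enrichment threshold on the corrected p-value (0.05)
#' @return data.frame `term`, `class`, `k`, `K`, `n`, `N`, `p`, `p_corrected`,
#'   `enriched`, `genes` (comma-joined target genes of the term)
#' @export
hypergeom_enrich <- function(target_genes, background_genes, term_map,
                             method = "BH", alpha = 0.05) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (!all(target_genes %in% background_genes))
    stop("target genes must be a subset of the background", call. = FALSE)
  stopifnot(all(c("gene", "term", "class") %in% names(term_map)))
  tm <- unique(term_map[term_map$gene %in% background_genes,
                        c("gene", "term", "class")])
  skipped <- setdiff(unique(term_map$term), unique(tm$term))
  if (length(skipped))
    warning("skipping ", length(skipped),
            " term(s) with no background gene (K = 0)", call. = FALSE)
  N <- length(background_genes)
  n <- length(target_genes)
  rows <- list()
  for (tr in unique(tm$term)) {
    genes_t <- tm$gene[tm$term == tr]
    K <- length(unique(genes_t))
    hit <- intersect(genes_t, target_genes)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[tr]] <- data.frame(term = tr, class = tm$class[tm$term == tr][1],
                             k = k, K = K, n = n, N = N, p = p,
                             genes = paste(sort(hit), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(), class = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), p_corrected = numeric(),
                      enriched = logical(), genes = character()))
  out <- do.call(rbind, rows)
  out$p_corrected <- NA_real_
  for (cl in unique(out$class)) {
    sel <- out$class == cl
    out$p_corrected[sel] <- p.adjust(out$p[sel], method = method)
  }
  out$enriched <- out$p_corrected < alpha
  out <- out[order(out$class, out$p, out$term),
             c("term", "class", "k", "K", "n", "N", "p", "p_corrected",
               "enriched", "genes")]
  rownames(out) <- NULL
  out
}
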