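#' Build a miRNA count matrix from annotated tags and novel candidates
#'
#' Counts for a known miRNA are the summed reads of all tags assigned to it;
#' novel candidates contribute their support counts.
#'
#' @param assignments `assignments` from [classify_tags()]
#' @param novel optional candidate table from [call_novel_candidates()]
#' @param libraries library count columns
#' @return integer matrix, rows = miRNA ids, columns = libraries; attribute
#'   `novel` marks novel rows
#' @export
mirna_counts <- function(assignments, novel = NULL, libraries = .LIBS) {
  a <- data.table::as.data.table(assignments)
  known <- a[category == "miRNA_known",
             lapply(.SD, sum), by = mirna, .SDcols = libraries]
  m <- as.matrix(known[, libraries, with = FALSE])
  rownames(m) <- known$mirna
  is_novel <- rep(FALSE, nrow(m))
  if (!is.null(novel) && nrow(novel) > 0) {
    nm <- as.matrix(data.table::as.data.table(novel)[, libraries, with = FALSE])
    rownames(nm) <- novel$id
    m <- rbind(m, nm)
    is_novel <- c(is_novel, rep(TRUE, nrow(nm)))
  }
  storage.mode(m) <- "integer"
  attr(m, "novel") <- stats::setNames(is_novel, rownames(m))
  m
}

#' Normalize miRNA counts to transcripts per million
#'
#' `normalized = count / clean_total * 1e6`. Zeros are imputed to 0.01 only
#' in the ratio matrix used for fold-change computation; the normalized
#' matrix itself keeps true zeros. miRNAs expressed in only one library are
#' excluded (they do not take part in differential expression analysis);
#' set `drop_single_library = FALSE` to keep them.
#'
#' @param counts miRNA x library count matrix
#' @param clean_totals named vector of clean-read totals per library
#' @param drop_single_library drop rows expressed in exactly one library
#'   (default TRUE)
#' @param zero_value imputation value for zeros in the ratio matrix (0.01)
#' @return object of class `spidmir_expr`: list with `counts`, `norm`,
#'   `ratio`, `clean_totals`, `dropped` (ids excluded by the one-library
#'   rule), `novel` (logical per kept row)
#' @export
normalize_expression <- function(counts, clean_totals,
                                 drop_single_library = TRUE,
                                 zero_value = 0.01) {
  stopifnot(is.matrix(counts), all(colnames(counts) %in% names(clean_totals)),
            all(clean_totals[colnames(counts)] > 0))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  novel_attr <- attr(counts, "novel")
  expressed <- rowSums(counts > 0)
  dropped <- character()
  if (drop_single_library) {
    dropped <- rownames(counts)[expressed == 1L]
    counts <- counts[expressed != 1L, , drop = FALSE]
  }
  totals <- clean_totals[colnames(counts)]
  norm <- sweep(counts, 2, totals, "/") * 1e6
  ratio <- norm
  ratio[ratio == 0] <- zero_value
  structure(list(counts = counts, norm = norm, ratio = ratio,
                 clean_totals = totals, dropped = dropped,
                 novel = if (is.null(novel_attr)) NULL
                         else novel_attr[rownames(counts)]),
            class = "spidmir_expr")
}

#' Log2 fold change between two expression values
#'
#' @param expr_treat,expr_ctrl normalized (zero-imputed) expression values
#' @return `log2(expr_treat / expr_ctrl)`
#' @export
fold_change <- function(expr_treat, expr_ctrl) {
  stopifnot(all(expr_treat > 0), all(expr_ctrl > 0))
  log2(expr_treat / expr_ctrl)
}

#' Exact tag-count p-value between two libraries
#'
#' Tests whether a tag's counts `x` (library of depth `N1`) and `y` (depth
#' `N2`) are compatible with equal underlying concentrations. Conditional on
#' the total `t = x + y`, under the null `x ~ Binomial(t, N1/(N1+N2))` - the
#' exact conditional form of the classic tag-count (Audic-Claverie-type)
#' test, with the library-size ratio entering through the binomial
#' probability. The two-sided p-value is `min(1, 2 * min(P(X <= x),
#' P(X >= x)))`. It is symmetric, `p(x, y, N1, N2) = p(y, x, N2, N1)`, and
#' equals 1 at `x = y = 0`.
#'
#' @param x,y non-negative integer counts (vectorized)
#' @param N1,N2 library depths (clean-read totals)
#' @return two-sided p-values in (0, 1]
#' @export
tagcount_pvalue <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), all(N1 > 0), all(N2 > 0),
            all(x == floor(x)), all(y == floor(y)))
  t <- x + y
  p0 <- N1 / (N1 + N2)
  lower <- pbinom(x, t, p0)
  upper <- pbinom(x - 1, t, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Per-pair differential expression calls
#'
#' For each comparison pair (treatment/control; the second library is the
#' control) computes the log2 fold change on zero-imputed normalized
#' expression and the exact tag-count p-value on raw counts. A miRNA is
#' significant when `|log2FC| > 1` (strict) and `p < 0.05`; `stars` marks
#' `"**"` for `p < 0.01` and `"*"` for `p < 0.05` among significant calls.
#'
#' @param expr `spidmir_expr` from [normalize_expression()]
#' @param pairs named list of `c(treatment, control)` label pairs; defaults
#'   to the four-pair design CS/CW, HW/CW, HS/CW, HS/HW
#' @param fc_cutoff absolute log2 fold-change threshold (1)
#' @param p_cutoff p-value threshold (0.05)
#' @return data.table `mirna`, `pair`, `log2fc`, `pvalue`, `significant`,
#'   `stars`, `novel`; attribute `method` records the p-value method
#' @export
call_de <- function(expr, pairs = .PAIRS, fc_cutoff = 1, p_cutoff = 0.05) {
  stopifnot(inherits(expr, "spidmir_expr"))
  ids <- rownames(expr$counts)
  out <- list()
  for (pname in names(pairs)) {
    tr <- pairs[[pname]][1]; ct <- pairs[[pname]][2]
    l2 <- fold_change(expr$ratio[, tr], expr$ratio[, ct])
    p <- tagcount_pvalue(expr$counts[, tr], expr$counts[, ct],
                         expr$clean_totals[[tr]], expr$clean_totals[[ct]])
    sig <- abs(l2) > fc_cutoff & p < p_cutoff
    out[[pname]] <- data.table::data.table(
      mirna = ids, pair = pname, log2fc = unname(l2), pvalue = unname(p),
      significant = unname(sig),
      stars = ifelse(sig & p < 0.01, "**", ifelse(sig, "*", "")),
      novel = if (is.null(expr$novel)) NA else unname(expr$novel))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, pair, mirna)
  data.table::setattr(res, "method", "exact conditional binomial tag-count test")
  res[]
}

#' Two-way fixed-effects ANOVA for a 2 x 2 replicated design
#'
#' Standard decomposition for temperature x spermidine with r >= 2 replicates
#' per cell; sums of squares partition the total exactly. Degenerate data
#' (zero variance everywhere) yields `degenerate = TRUE` with NA statistics.
#'
#' @param value numeric response (e.g. expression)
#' @param temperature factor/character with 2 levels
#' @param spd factor/character with 2 levels
#' @return data.frame rows `temperature`, `spd`, `temperature:spd` with `F`
#'   and `p`, plus attribute `degenerate`
#' @export
twoway_anova <- function(value, temperature, spd) {
  temperature <- factor(temperature); spd <- factor(spd)
  stopifnot(nlevels(temperature) == 2L, nlevels(spd) == 2L,
            length(value) == length(temperature),
            length(value) == length(spd))
  cell_n <- table(temperature, spd)
  if (any(cell_n < 2L)) stop("need at least 2 replicates per cell", call. = FALSE)
  if (length(unique(cell_n)) != 1L) stop("unbalanced design", call. = FALSE)
  if (stats::var(value) == 0) {
    out <- data.frame(term = c("temperature", "spd", "temperature:spd"),
                      F = NA_real_, p = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::aov(value ~ temperature * spd)
  tab <- summary(fit)[[1]]
  out <- data.frame(term = c("temperature", "spd", "temperature:spd"),
                    F = tab[1:3, "F value"], p = tab[1:3, "Pr(>F)"],
                    row.names = NULL)
  attr(out, "degenerate") <- FALSE
  out
}
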