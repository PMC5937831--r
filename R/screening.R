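#' Venn region counts for four differential-expression sets
#'
#' Disjoint-region counts for all 15 nonempty combinations of the four
#' comparison-pair sets; the counts sum to the size of the union.
#'
#' @param de_sets named list of 4 character vectors of miRNA ids
#' @return data.frame `region` (pair names joined by `&`), `count`
#' @export
venn_counts <- function(de_sets) {
  stopifnot(is.list(de_sets), length(de_sets) == 4L,
            !is.null(names(de_sets)))
  universe <- unique(unlist(de_sets))
  member <- vapply(de_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(de_sets)))
  regions <- list()
  for (k in 1:4) {
    for (combo in utils::combn(names(de_sets), k, simplify = FALSE)) {
      inside <- if (length(universe))
        rowSums(member[, combo, drop = FALSE]) == k &
        rowSums(member[, setdiff(names(de_sets), combo), drop = FALSE]) == 0
      else logical(0)
      regions[[paste(combo, collapse = "&")]] <- sum(inside)
    }
  }
  data.frame(region = names(regions), count = unlist(regions, use.names = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify miRNAs as heat-, spermidine- or both-responsive
#'
#' Membership is significance in a comparison pair. A miRNA responsive to
#' both high temperature and spermidine is significant in all four pairs;
#' heat-responsive miRNAs are significant in HW/CW and HS/CW;
#' spermidine-responsive miRNAs are significant in CS/CW, HS/CW and HS/HW;
#' `both` takes precedence, everything else is `other`. The direction
#' pattern records the sign of the log2 fold change in the pairs where the
#' miRNA is significant (non-member pairs are excluded from the pattern) and
#' is summarized as `all-down`, `all-up` or `inconsistent`.
#'
#' @param de DE table from [call_de()]
#' @param pairs the four pair names, in reporting order
#' @return data.frame of class `spidmir_screen`: per miRNA, membership
#'   logicals per pair, `class`, `pattern` (e.g. `"down,down,down,up"`),
#'   `consistency`, `novel`
#' @export
classify_responsiveness <- function(de, pairs = names(.PAIRS)) {
  de <- data.table::as.data.table(de)
  stopifnot(all(pairs %in% unique(de$pair)))
  wide_sig <- data.table::dcast(de, mirna ~ pair, value.var = "significant")
  wide_fc <- data.table::dcast(de, mirna ~ pair, value.var = "log2fc")
  novel <- de[, .(novel = novel[1]), by = mirna]

  mem <- as.matrix(wide_sig[, pairs, with = FALSE])
  mem[is.na(mem)] <- FALSE
  fc <- as.matrix(wide_fc[, pairs, with = FALSE])
  heat_pairs <- intersect(c("HW/CW", "HS/CW"), pairs)
  spd_pairs <- intersect(c("CS/CW", "HS/CW", "HS/HW"), pairs)

  cls <- character(nrow(mem))
  for (i in seq_len(nrow(mem))) {
    cls[i] <- if (all(mem[i, ])) "both"
      else if (all(mem[i, heat_pairs])) "heat"
      else if (all(mem[i, spd_pairs])) "spd"
      else "other"
  }
  pattern <- vapply(seq_len(nrow(mem)), function(i) {
    sel <- mem[i, ]
    if (!any(sel)) return("")
    paste(ifelse(fc[i, sel] < 0, "down", "up"), collapse = ",")
  }, character(1))
  consistency <- vapply(seq_len(nrow(mem)), function(i) {
    sel <- mem[i, ]
    if (!any(sel)) return(NA_character_)
    s <- sign(fc[i, sel])
    if (all(s < 0)) "all-down" else if (all(s > 0)) "all-up" else "inconsistent"
  }, character(1))

  out <- data.frame(mirna = wide_sig$mirna, stringsAsFactors = FALSE)
  for (p in pairs) out[[p]] <- mem[, p]
  out$class <- cls
  out$pattern <- pattern
  out$consistency <- consistency
  out$novel <- novel$novel[match(out$mirna, novel$mirna)]
  class(out) <- c("spidmir_screen", "data.frame")
  out
}

#' Responsive-set extraction from a screen report
#'
#' @param screen result of [classify_responsiveness()]
#' @param class responsiveness class to extract
#' @return character vector of miRNA ids
#' @export
responsive_set <- function(screen, class = c("both", "heat", "spd")) {
  class <- match.arg(class)
  # heat/spd sets are rule-based supersets: both-responsive miRNAs satisfy
  # the heat rule and the spd rule as well
  keep <- switch(class,
                 both = screen$class == "both",
                 heat = screen$class %in% c("heat", "both"),
                 spd = screen$class %in% c("spd", "both"))
  sort(screen$mirna[keep])
}
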