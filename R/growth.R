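#' Percent change between two trait means
#'
#' `100 * (value_b - value_a) / value_a`, rounded half-up to two decimals
#' (the convention that reproduces published growth-contrast percentages).
#'
#' @param value_a reference mean (must be > 0)
#' @param value_b comparison mean
#' @return percent change, two decimals
#' @export
percent_change <- function(value_a, value_b) {
  if (any(value_a <= 0)) stop("reference value must be positive", call. = FALSE)
  round_half_up(100 * (value_b - value_a) / value_a, 2)
}

#' Summarize replicate growth measurements
#'
#' @param measurements data.frame with columns `treatment`, `trait`, `value`
#' @param treatments treatments that must all be present (default CW, CS,
#'   HW, HS)
#' @return data.frame `treatment`, `trait`, `mean`, `sd` (sample SD), `n`
#' @export
summarize_growth <- function(measurements, treatments = .LIBS) {
  stopifnot(all(c("treatment", "trait", "value") %in% names(measurements)))
  missing <- setdiff(treatments, unique(measurements$treatment))
  if (length(missing))
    stop("missing treatment(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(measurements)
  out <- dt[, .(mean = mean(value), sd = stats::sd(value), n = .N),
            by = .(treatment, trait)]
  if (any(out$n < 2))
    stop("need at least 2 replicates per treatment/trait cell", call. = FALSE)
  as.data.frame(out)
}

#' Read a growth-trait table
#'
#' Tab-separated with columns `treatment`, `trait`, `mean`, `sd` and
#' optionally `letters` (post-hoc grouping letters, preserved as opaque
#' annotations).
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_growth_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("treatment", "trait", "mean") %in% names(tab)))
  tab
}

#' Growth contrasts between treatments
#'
#' Percent change of every trait mean between treatment pairs, e.g. the
#' effect of heat (CW vs HW) and of spermidine under heat (HW vs HS).
#'
#' @param growth_table data.frame `treatment`, `trait`, `mean` (see
#'   [read_growth_table()])
#' @param contrasts list of `c(reference, comparison)` treatment pairs
#' @return data.frame `contrast`, `trait`, `reference_mean`,
#'   `comparison_mean`, `percent_change`
#' @export
growth_contrasts <- function(growth_table,
                             contrasts = list(c("CW", "HW"), c("HW", "HS"))) {
  out <- list()
  for (ct in contrasts) {
    a <- growth_table[growth_table$treatment == ct[1], ]
    b <- growth_table[growth_table$treatment == ct[2], ]
    traits <- intersect(a$trait, b$trait)
    ma <- a$mean[match(traits, a$trait)]
    mb <- b$mean[match(traits, b$trait)]
    out[[length(out) + 1L]] <- data.frame(
      contrast = paste(ct[1], "vs", ct[2]), trait = traits,
      reference_mean = ma, comparison_mean = mb,
      percent_change = percent_change(ma, mb), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
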