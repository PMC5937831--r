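#' Run the full pipeline on synthetic libraries
#'
#' End-to-end chain: simulate -> preprocess -> annotate -> novel -> DE ->
#' screen -> targets -> enrich. All randomness flows from the configuration
#' seed; rerunning with the same configuration reproduces the summary
#' exactly. When `out_dir` is given, stage outputs are written as TSV (the
#' cleaning-summary, classification and DE tables mirror the standard
#' published layouts) plus a machine-readable `summary.json` embedding the
#' resolved configuration.
#'
#' @param config a [simulation_config()]
#' @param out_dir optional output directory
#' @param filter_par filtering thresholds ([filter_params()])
#' @param novel_par novel-candidate thresholds ([novel_params()])
#' @param verbose log stage progress to stderr
#' @return list of class `spidmir_run` with elements `ref`, `sim`,
#'   `filter_reports`, `collapsed`, `classified`, `annotation`,
#'   `novel`, `expr`, `de`, `screen`, `venn_known`, `venn_novel`,
#'   `targets`, `enrichment`, `summary`
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         filter_par = filter_params(),
                         novel_par = novel_params(), verbose = TRUE) {
  say <- function(stage, ...) if (verbose)
    message("[spidmir:", stage, "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  libs <- config$libraries

  say("simulate", "building reference and libraries (seed ", config$seed, ")")
  ref <- stage("simulate", build_reference(config))
  sim <- stage("simulate", simulate_libraries(config, ref))

  say("preprocess", "filtering ", config$n_reads_per_library, " reads x 4")
  filtered <- stage("preprocess", lapply(sim$reads, function(r)
    filter_reads(r, config$adapter3, config$adapter5, filter_par,
                 encoding = config$encoding)))
  reports <- lapply(filtered, `[[`, "report")
  collapsed <- stage("preprocess",
                     collapse_tags(lapply(filtered, function(f) f$clean$insert)))
  clean_totals <- stats::setNames(collapsed$totals$total_reads,
                                  collapsed$totals$library)

  say("annotate", collapsed$grand_unique, " unique tags")
  hits <- stage("annotate", map_to_genome(collapsed$tags$sequence, ref$genome))
  cls <- stage("annotate", classify_tags(collapsed$tags, hits, ref$features,
                                         ref$known))
  annot <- stage("annotate", annotation_summary(cls$assignments,
                                                libraries = libs))

  say("novel", "hairpin search over unannotated mapped tags")
  unann <- cls$assignments[cls$assignments$category == "unannotated" &
                             cls$assignments$mapped, ]
  novel <- stage("novel", call_novel_candidates(
    unann[, c("sequence", libs), with = FALSE], hits, ref$genome,
    params = novel_par, libraries = libs))

  say("de", "normalization and four-pair tests")
  counts <- stage("de", mirna_counts(cls$assignments, novel, libraries = libs))
  expr <- stage("de", normalize_expression(counts, clean_totals))
  de <- stage("de", call_de(expr))

  say("screen", "four-pair Venn classification")
  screen <- stage("screen", classify_responsiveness(de))
  de_known <- de[de$novel %in% FALSE, ]
  de_novel <- de[de$novel %in% TRUE, ]
  sets_of <- function(d) lapply(stats::setNames(names(.PAIRS), names(.PAIRS)),
                                function(p) d$mirna[d$pair == p & d$significant])
  venn_known <- stage("screen", venn_counts(sets_of(de_known)))
  venn_novel <- stage("screen", venn_counts(sets_of(de_novel)))

  say("targets", "scanning transcriptome for both-responsive miRNAs")
  both <- responsive_set(screen, "both")
  both_known <- intersect(both, ref$known$mirna)
  tg <- if (length(both_known)) {
    mir_seqs <- stats::setNames(
      ref$known$mature[match(both_known, ref$known$mirna)], both_known)
    stage("targets", predict_targets(mir_seqs, ref$transcripts))
  } else data.table::data.table(mirna = character(), gene = character(),
                                start = integer(), penalty = numeric(),
                                mismatches = integer(), gu = integer())

  say("enrich", "hypergeometric term enrichment")
  enr <- if (nrow(tg)) {
    stage("enrich", hypergeom_enrich(unique(tg$gene), names(ref$transcripts),
                                     ref$term_map))
  } else NULL

  summary <- list(
    seed = config$seed,
    n_reads_per_library = config$n_reads_per_library,
    clean_reads = as.list(clean_totals),
    unique_tags = collapsed$grand_unique,
    mean_reads_per_unique = collapsed$mean_reads_per_unique,
    known_mirnas_detected = sum(!expr$novel),
    novel_candidates = nrow(novel),
    significant_per_pair = lapply(stats::setNames(names(.PAIRS), names(.PAIRS)),
                                  function(p) sum(de$significant[de$pair == p])),
    both_responsive = sort(both),
    heat_responsive = responsive_set(screen, "heat"),
    spd_responsive = responsive_set(screen, "spd"),
    target_genes = sort(unique(tg$gene)),
    enriched_terms = if (!is.null(enr)) enr$term[enr$enriched] else character())

  run <- structure(list(ref = ref, sim = sim, filter_reports = reports,
                        collapsed = collapsed, classified = cls,
                        annotation = annot, novel = novel, expr = expr,
                        de = de, screen = screen, venn_known = venn_known,
                        venn_novel = venn_novel, targets = tg,
                        enrichment = enr, summary = summary),
                   class = "spidmir_run")
  if (!is.null(out_dir)) write_run(run, config, out_dir)
  run
}

write_run <- function(run, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(filter_report_table(run$filter_reports), "cleaning_summary.tsv")
  w(run$annotation, "classification_summary.tsv")
  w(length_distribution(run$collapsed$tags), "length_distribution.tsv")
  w(as.data.frame(run$novel), "novel_candidates.tsv")
  expr_out <- data.frame(mirna = rownames(run$expr$counts),
                         run$expr$counts, run$expr$norm,
                         check.names = FALSE)
  names(expr_out) <- c("mirna", paste0(colnames(run$expr$counts), "_count"),
                       paste0(colnames(run$expr$norm), "_tpm"))
  w(expr_out, "expression_matrix.tsv")
  w(as.data.frame(run$de), "de_results.tsv")
  w(as.data.frame(run$screen), "screen_report.tsv")
  w(run$venn_known, "venn_known.tsv")
  w(run$venn_novel, "venn_novel.tsv")
  w(as.data.frame(run$targets), "targets.tsv")
  if (!is.null(run$enrichment)) w(run$enrichment, "enrichment.tsv")
  jsonlite::write_json(
    c(run$summary,
      list(config = config[setdiff(names(config), "de_effects")],
           version = as.character(utils::packageVersion("spidmir")))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
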