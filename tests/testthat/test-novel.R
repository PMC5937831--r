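test_that("stem search scores constructed hairpins exactly", {
  set.seed(51)
  arm <- "GCTAGCTAGGATCCGATCGA"            # 20 nt
  hp <- paste0(arm, strrep("C", 10), revcomp(arm))   # non-pairing 10 nt loop
  f <- fold_and_score(hp)
  expect_identical(f$paired, 20L)
  expect_equal(f$score, -20)

  expect_identical(fold_and_score(strrep("A", 100))$paired, 0L)
  expect_equal(fold_and_score(strrep("A", 100))$score, 0)
})

test_that("stem search equals exhaustive enumeration over all placements", {
  set.seed(52)
  wts <- c(WC = 1, GU = 0.5, MM = -2)
  # the arg max may be non-unique on random sequence; the max itself is not,
  # so random windows are compared on the selection objective
  for (w in c(random_dna_chr(10, 60), random_dna_chr(5, 80))) {
    f <- fold_and_score(w)
    o <- fold_oracle(w)
    net_impl <- if (nrow(f$layout)) sum(wts[f$layout$type]) else 0
    expect_equal(net_impl, o$net)
  }
  # planted stems: the objective matches enumeration and the detected stem
  # covers at least the planted arm (runs tying on the objective may differ
  # in decomposition, so score/paired carry inequalities, not equalities)
  for (i in 1:5) {
    a <- random_dna_chr(1, sample(14:18, 1))
    w <- paste0(random_dna_chr(1, 10), a, random_dna_chr(1, sample(4:12, 1)),
                revcomp(a), random_dna_chr(1, 10))
    f <- fold_and_score(w)
    o <- fold_oracle(w)
    expect_equal(sum(wts[f$layout$type]), o$net)
    expect_gte(f$paired, nchar(a))
    expect_lte(f$score, -nchar(a))
  }
})

test_that("random 100-mers are almost always rejected at the default score threshold", {
  set.seed(53)
  scores <- vapply(random_dna_chr(1000, 100),
                   function(w) fold_and_score(w)$score, numeric(1),
                   USE.NAMES = FALSE)
  expect_gt(mean(scores > novel_params()$score_max), 0.95)
})

test_that("precursor windows are strand-aware and truncate at contig edges", {
  genome <- c(chr1 = paste0(strrep("C", 30), "ACGTACGTACGTACGTACGTA",
                            strrep("G", 200)))
  tag <- "ACGTACGTACGTACGTACGTA"
  hits <- map_to_genome(tag, genome)
  w <- extract_precursor_windows(hits, genome, flank = 100)
  up <- w[w$arm == "3p"]
  expect_true(up$truncated)          # only 30 nt available upstream
  expect_identical(up$start, 0L)
  expect_identical(substr(up$window, up$tag_offset + 1,
                          up$tag_offset + nchar(tag)), tag)
  down <- w[w$arm == "5p"]
  expect_identical(down$tag_offset, 0L)

  w0 <- extract_precursor_windows(hits, genome, flank = 0)
  expect_identical(unique(w0$end - w0$start), nchar(tag))

  # a planted hairpin's downstream window contains the full precursor
  fx <- sim_fixture()
  nl <- fx$ref$novel_loci[1, ]
  h1 <- map_to_genome(nl$mature, fx$ref$genome)
  wins <- extract_precursor_windows(h1, fx$ref$genome, flank = 100)
  expect_true(any(grepl(nl$precursor, wins$window, fixed = TRUE)))
})

test_that("candidate calling recovers planted hairpins with perfect precision", {
  fx <- sim_fixture()
  truth <- fx$sim$manifest$novel_loci
  # planted-only input: only the hairpin arm tags
  tags <- fx$cls$assignments[fx$cls$assignments$sequence %in% truth$mature,
                             c("sequence", fx$cfg$libraries), with = FALSE]
  hits <- fx$hits[fx$hits$tag %in% truth$mature]
  cand <- call_novel_candidates(tags, hits, fx$ref$genome)
  expect_identical(nrow(cand), nrow(truth))
  expect_setequal(cand$mature, truth$mature)
  # recovered loci lie within the planted precursor intervals
  m <- merge(as.data.frame(cand), truth, by = "mature")
  expect_true(all(m$start.x >= m$start.y & m$end.x <= m$end.y))

  # the one-library rule: support in a single library removes the candidate
  tags1 <- data.table::copy(tags)
  one <- tags1$sequence == truth$mature[1]
  for (l in c("CS", "HW", "HS")) tags1[[l]][one] <- 0L
  cand1 <- call_novel_candidates(tags1, hits, fx$ref$genome)
  expect_identical(nrow(cand1), nrow(truth) - 1L)
  expect_false(truth$mature[1] %in% cand1$mature)
})

test_that("tags on the same stem merge into one candidate with summed support", {
  set.seed(55)
  arm <- "GGATCCGATCGATCGGATGCAT"
  hp <- paste0(arm, "TTTCGATTACG", revcomp(arm))
  genome <- c(chr1 = paste0(random_dna_chr(1, 150), hp, random_dna_chr(1, 150)))
  t1 <- arm
  t2 <- substr(arm, 2, nchar(arm))     # 1 nt offset into the same stem
  tags <- data.table::data.table(sequence = c(t1, t2),
                                 CW = c(10L, 4L), CS = c(3L, 2L),
                                 HW = 0L, HS = 0L)
  hits <- map_to_genome(tags$sequence, genome)
  cand <- call_novel_candidates(tags, hits, genome)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$CW, 14L)
  expect_identical(cand$CS, 5L)
  expect_identical(cand$mature, t1)    # most abundant member tag
})
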