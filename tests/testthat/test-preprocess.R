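test_that("quality decoding follows the ASCII-minus-offset rule and flags the wrong encoding", {
  expect_identical(decode_quality("h"), 40L)
  expect_identical(decode_quality("@"), 0L)
  expect_identical(decode_quality("J"), 10L)
  expect_identical(decode_quality("h@J"), c(40L, 0L, 10L))
  expect_identical(decode_quality("I", "phred33"), 40L)
  # phred33-encoded characters decode negative under phred64
  expect_error(decode_quality("5?", "phred64"), "phred33")
  expect_error(decode_quality("~", "phred33"), "outside")
})

test_that("each of the seven filter rules fires at its stated boundary, first rule wins", {
  ad3 <- "TGGAATTCTCGGGTGCCAAGG"
  ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  insert18 <- "ACGTACGTACGTACGTAC"    # 18 nt, 50% A-free
  insert17 <- substr(insert18, 1, 17)
  mk <- function(seq, qual = NULL) {
    if (is.null(qual)) qual <- q64(35, nchar(seq))
    data.frame(id = "r", sequence = seq, quality = qual,
               stringsAsFactors = FALSE)
  }
  run1 <- function(reads) as.character(
    filter_reads(reads, ad3, ad5)$category)

  good <- substr(paste0(insert18, ad3), 1, 36)
  expect_identical(run1(mk(good)), "clean")

  # rule 1 boundary: exactly 4 sub-10 bases removes, 3 does not
  q_low4 <- paste0(strrep("I", 4), q64(35, 32))   # I = quality 9
  q_low3 <- paste0(strrep("I", 3), q64(35, 33))
  expect_identical(run1(mk(good, q_low4)), "low_quality")
  expect_identical(run1(mk(good, q_low3)), "clean")

  # rule 2: >10% N (4 of 36 = 11.1%) removed; 3 of 36 = 8.3% kept but the
  # N-containing tag still trims clean
  n4 <- paste0("NNNN", substr(good, 5, 36))
  expect_identical(run1(mk(n4)), "high_N")

  # rule 3: 5' adapter contaminant
  expect_identical(run1(mk(substr(paste0(ad5, good), 1, 36))),
                   "adapter5_contaminant")

  # rule 4: adapter at position 1 means no insert
  expect_identical(run1(mk(substr(paste0(ad3, good), 1, 36))), "insert_null")

  # rule 5: no trace of the 3' adapter
  expect_identical(run1(mk(strrep("ACGT", 9))), "adapter3_null")

  # rule 6: poly(A) insert (>= 80% A)
  expect_identical(run1(mk(substr(paste0(strrep("A", 20), ad3), 1, 36))),
                   "polyA")

  # rule 7 boundary: 17 nt removed, 18 nt kept
  expect_identical(run1(mk(substr(paste0(insert17, ad3), 1, 36))),
                   "shorter_than_18nt")
  res18 <- filter_reads(mk(substr(paste0(insert18, ad3), 1, 36)), ad3, ad5)
  expect_identical(as.character(res18$category), "clean")
  expect_identical(res18$clean$insert, insert18)

  # first matching rule wins: a poly(A) read with bad quality is low_quality
  expect_identical(run1(mk(substr(paste0(strrep("A", 20), ad3), 1, 36),
                           q_low4)), "low_quality")
})

test_that("filter accounting closes exactly on fuzzed inputs", {
  ad3 <- "TGGAATTCTCGGGTGCCAAGG"
  ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  set.seed(11)
  for (rep in 1:8) {
    n <- 300
    seqs <- random_dna_chr(n, 36)
    # random perturbations: adapters, Ns, poly-A spliced in at random
    pick <- sample(n, 120)
    seqs[pick[1:40]] <- substr(paste0(random_dna_chr(40, sample(10:30, 40, TRUE)),
                                      ad3, strrep("G", 36)), 1, 36)
    seqs[pick[41:60]] <- substr(paste0(ad5, random_dna_chr(20, 36)), 1, 36)
    seqs[pick[61:80]] <- vapply(seqs[pick[61:80]], function(s) {
      p <- sample(36, sample(2:8, 1)); ss <- strsplit(s, "")[[1]]
      ss[p] <- "N"; paste(ss, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    seqs[pick[81:100]] <- substr(paste0(strrep("A", 22), ad3), 1, 36)
    quals <- vapply(seq_len(n), function(i)
      paste(intToUtf8(64 + sample(0:41, 36, TRUE), multiple = TRUE),
            collapse = ""), character(1))
    reads <- data.frame(id = sprintf("r%03d", 1:n), sequence = seqs,
                        quality = quals, stringsAsFactors = FALSE)
    res <- filter_reads(reads, ad3, ad5)
    rp <- res$report
    expect_identical(rp$high_quality, rp$total_reads - rp$low_quality - rp$high_N)
    expect_identical(rp$clean_reads,
                     rp$high_quality - rp$adapter3_null - rp$insert_null -
                       rp$adapter5_contaminant - rp$shorter_than_18nt - rp$polyA)
    expect_identical(nrow(res$clean), rp$clean_reads)
    expect_identical(sum(table(res$category)), rp$total_reads)
  }
})

test_that("clean sets are invariant to filter bookkeeping, categories match the manifest", {
  fx <- sim_fixture()
  for (lib in fx$cfg$libraries) {
    truth <- fx$sim$manifest$per_read[[lib]]
    got <- data.frame(id = fx$sim$reads[[lib]]$id,
                      class = as.character(fx$filtered[[lib]]$category),
                      stringsAsFactors = FALSE)
    got$class[got$class == "shorter_than_18nt"] <- "short"
    merged <- merge(truth, got, by = "id")
    expect_identical(merged$class.x, merged$class.y)
  }
})

test_that("tag collapsing counts reads and unique tags per library", {
  col <- collapse_tags(list(L1 = c("AAAA", "AAAA", "AAAA", "CCCC", "CCCC"),
                            L2 = c("AAAA", "GGGG")))
  expect_identical(nrow(col$tags), 3L)
  expect_identical(col$totals$total_reads, c(5, 2))
  expect_identical(col$totals$unique_reads, c(2, 2))
  expect_identical(col$grand_total, 7)
  expect_identical(col$tags$L1[col$tags$sequence == "AAAA"], 3L)

  # closure on the fixture: collapsed totals equal clean read counts
  fx <- sim_fixture()
  expect_identical(unname(fx$collapsed$totals$total_reads),
                   unname(vapply(fx$filtered, function(f)
                     as.numeric(f$report$clean_reads), numeric(1))))
})

test_that("length distribution is read-weighted, sums to 100, order-invariant", {
  col <- collapse_tags(list(A = rep("ACGTACGTACGTACGTACGTA", 10)))
  ld <- length_distribution(col$tags)
  expect_identical(ld$length, 21L)
  expect_equal(ld$percent, 100)

  set.seed(3)
  ins <- sample(c(random_dna_chr(50, 21), random_dna_chr(30, 24)))
  c1 <- collapse_tags(list(A = ins))
  c2 <- collapse_tags(list(A = rev(ins)))
  expect_equal(length_distribution(c1$tags), length_distribution(c2$tags))
  expect_equal(sum(length_distribution(c1$tags)$percent), 100)

  # planted length shares recovered within 3 binomial SD on the fixture
  fx <- sim_fixture()
  tt <- fx$sim$manifest$tag_truth
  tpm <- fx$sim$manifest$true_expression
  ld <- length_distribution(fx$collapsed$tags, libraries = "CW")
  lens <- nchar(tt$sequence)
  for (L in c(20, 21, 22)) {
    p_true <- sum(tpm[tt$source_id[lens == L], "CW"]) / 1e6
    n_clean <- fx$filtered$CW$report$clean_reads
    got <- sum(ld$percent[ld$length == L]) / 100
    expect_lt(abs(got - p_true), 3 * sqrt(p_true * (1 - p_true) / n_clean))
  }

  expect_error(length_distribution(data.frame(sequence = "ACGT", A = 0L)),
               "no clean reads")
})

test_that("base profiles report composition fractions and mean qualities", {
  prof <- base_profiles(rep("AAAA", 5), rep(q64(30, 4), 5))
  expect_equal(unname(prof$composition[, "A"]), rep(1, 4))
  expect_equal(prof$mean_quality, rep(30, 4))

  set.seed(5)
  seqs <- random_dna_chr(4000, 10)
  prof <- base_profiles(seqs)
  sdev <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(prof$composition[, c("A", "C", "G", "T")] - 0.25) <
                    3.5 * sdev))
  expect_equal(rowSums(prof$composition), rep(1, 10))
})
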