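test_that("target penalty scoring weights mismatches, wobbles and the 2-13 region", {
  mir <- "TGACAGAAGAGAGTGAGCACA"            # 21 nt
  site <- revcomp(mir)                      # perfect complement
  expect_equal(score_target(mir, site)$penalty, 0)

  # G:U at miRNA position 20 costs 0.5; the same wobble at position 5 costs 1
  # (mirna position i pairs site position length - i + 1)
  mk_wobble <- function(pos) {
    s <- strsplit(site, "")[[1]]
    i <- nchar(mir) - pos + 1
    m <- substr(mir, pos, pos)
    # replace the site base with the wobble partner of the miRNA base
    s[i] <- if (m == "G") "T" else if (m == "T") "G" else NA
    paste(s, collapse = "")
  }
  m <- strsplit(mir, "")[[1]]
  p_out <- which(m %in% c("G", "T") & seq_along(m) > 13)[1]   # outside 2-13
  p_in <- which(m %in% c("G", "T") & seq_along(m) >= 2 & seq_along(m) <= 13)[1]
  sc_out <- score_target(mir, mk_wobble(p_out))
  sc_in <- score_target(mir, mk_wobble(p_in))
  expect_equal(sc_out$penalty, 0.5)
  expect_identical(sc_out$gu, 1L)
  expect_equal(sc_in$penalty, 1.0)

  expect_error(score_target(mir, substr(site, 1, 10)), "length")

  # random pairs agree with the per-position recount oracle
  set.seed(81)
  for (i in 1:60) {
    mi <- random_dna_chr(1, sample(20:22, 1))
    w <- random_dna_chr(1, nchar(mi))
    expect_equal(score_target(mi, w)$penalty, score_oracle(mi, w))
  }
})

test_that("targets are the intersection of the strict and relaxed presets", {
  set.seed(82)
  mir <- "TGACAGAAGAGAGTGAGCACA"
  perfect <- revcomp(mir)
  tx_hit <- paste0(random_dna_chr(1, 50), perfect, random_dna_chr(1, 50))

  # a site at penalty 4.5: passes relaxed (<= 5) but fails strict (<= 4)
  half <- strsplit(perfect, "")[[1]]
  k <- nchar(mir)
  flip_site_at <- function(s, mir_pos) {
    i <- k - mir_pos + 1
    m <- substr(mir, mir_pos, mir_pos)
    s[i] <- setdiff(c("A", "C", "G", "T"),
                    c(c(A = "T", C = "G", G = "C", T = "A")[[m]],
                      if (m == "G") "T", if (m == "T") "G"))[1]
    s
  }
  for (p in c(1, 14, 15, 16)) half <- flip_site_at(half, p)  # 4 x mismatch
  m17 <- substr(mir, 17, 17)
  half[k - 17 + 1] <- if (m17 == "G") "T" else if (m17 == "T") "G" else
    stop("pick another position")
  site45 <- paste(half, collapse = "")
  expect_equal(score_target(mir, site45)$penalty, 4.5)
  tx_45 <- paste0(random_dna_chr(1, 30), site45, random_dna_chr(1, 30))

  hits <- predict_targets(c(mirX = mir),
                          c(gHit = tx_hit, g45 = tx_45,
                            gNone = random_dna_chr(1, 150)))
  expect_identical(sort(unique(hits$gene)), "gHit")
  expect_identical(hits$start[1], 51L)

  # a miRNA with no complementary site anywhere gets an empty hit list
  none <- predict_targets(c(mirY = random_dna_chr(1, 21)),
                          c(g1 = random_dna_chr(1, 200)))
  expect_identical(nrow(none), 0L)

  # intersection is never larger than either preset's own gene set
  pr <- target_presets()
  one <- function(p) predict_targets(c(mirX = mir),
                                     c(gHit = tx_hit, g45 = tx_45),
                                     presets = pr[p])
  expect_true(all(unique(hits$gene) %in% unique(one("strict")$gene)))
  expect_true(all(unique(hits$gene) %in% unique(one("relaxed")$gene)))
})

test_that("hypergeometric enrichment equals exhaustive enumeration and corrects per class", {
  # N=10, K=4, n=5, k=4 -> C(4,4) C(6,1) / C(10,5) = 6/252
  genes <- sprintf("g%02d", 1:10)
  tm <- data.frame(gene = genes[1:4], term = "T1", class = "bp",
                   stringsAsFactors = FALSE)
  res <- hypergeom_enrich(genes[1:5], genes, tm)
  expect_equal(res$p[res$term == "T1"], 6 / 252)
  expect_equal(res$p, hyper_oracle(10, 4, 5, 4))

  # k = 0 gives p = 1; target = background saturates every term at p = 1
  res0 <- hypergeom_enrich(genes[5:6], genes, tm)
  expect_equal(res0$p, 1)
  res_all <- hypergeom_enrich(genes, genes, tm)
  expect_equal(res_all$p, 1)

  # random instances against the enumeration oracle (N <= 12)
  set.seed(83)
  for (i in 1:25) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    bg <- sprintf("G%02d", 1:N)
    tmap <- data.frame(gene = bg[1:K], term = "T", class = "c",
                       stringsAsFactors = FALSE)
    targ <- sample(bg, n)
    k <- sum(targ %in% bg[1:K])
    r <- hypergeom_enrich(targ, bg, tmap)
    expect_equal(r$p, hyper_oracle(N, K, n, k), tolerance = 1e-12)
  }

  # terms with no background gene are skipped with a warning
  tm2 <- rbind(tm, data.frame(gene = "absent", term = "T2", class = "bp"))
  expect_warning(hypergeom_enrich(genes[1:2], genes, tm2), "K = 0")

  # Bonferroni-enriched terms are a subset of BH-enriched terms
  set.seed(84)
  tm3 <- data.frame(gene = sample(genes, 30, TRUE),
                    term = sample(paste0("T", 1:6), 30, TRUE),
                    class = "bp", stringsAsFactors = FALSE)
  bh <- hypergeom_enrich(genes[1:4], genes, tm3, method = "BH")
  bf <- hypergeom_enrich(genes[1:4], genes, tm3, method = "bonferroni")
  expect_true(all(bf$term[bf$enriched] %in% bh$term[bh$enriched]))
})
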