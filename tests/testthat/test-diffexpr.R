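test_that("TPM normalization, zero imputation and the one-library rule behave as stated", {
  counts <- rbind(mA = c(CW = 0L, CS = 5L, HW = 10L, HS = 0L),
                  mB = c(2e6L, 0L, 0L, 0L),          # single-library
                  mC = c(5L, 5L, 5L, 5L))
  totals <- c(CW = 2e6, CS = 2e6, HW = 1e6, HS = 2e6)
  ex <- normalize_expression(counts, totals)
  expect_identical(ex$dropped, "mB")
  expect_equal(ex$norm["mA", "CW"], 0)
  expect_equal(ex$ratio["mA", "CW"], 0.01)
  expect_equal(ex$norm["mA", "CS"], 2.5)              # 5 / 2e6 * 1e6
  expect_equal(ex$norm["mA", "HW"], 10)

  ex2 <- normalize_expression(rbind(m = c(CW = 10L, CS = 10L, HW = 10L,
                                          HS = 10L)),
                              c(CW = 10, CS = 10, HW = 10, HS = 10))
  expect_equal(unname(ex2$norm[1, ]), rep(1e6, 4))    # count = clean total

  expect_error(normalize_expression(rbind(m = c(CW = -1L, CS = 1L, HW = 1L,
                                                HS = 1L)), totals),
               "negative")

  # closure: over the full tag set, normalized values sum to one million
  fx <- sim_fixture()
  tags <- fx$collapsed$tags
  for (lib in fx$cfg$libraries) {
    tot <- sum(tags[[lib]])
    expect_equal(sum(tags[[lib]] / tot * 1e6), 1e6, tolerance = 1e-9)
  }
})

test_that("fold changes use imputed ratios and are antisymmetric", {
  expect_equal(fold_change(4, 4), 0)
  expect_equal(fold_change(4, 1), 2)
  expect_equal(fold_change(0.01, 10.24), -10)         # zero imputed to 0.01
  x <- c(0.3, 7, 100); y <- c(5, 0.01, 42)
  expect_equal(fold_change(x, y), -fold_change(y, x))
})

test_that("tag-count p-values match exact-rational anchors and the summation oracle", {
  # frozen values computed with exact rational arithmetic (Python fractions)
  expect_equal(tagcount_pvalue(10, 0, 1000, 1000), 1 / 512,
               tolerance = 1e-12)
  expect_equal(tagcount_pvalue(5, 12, 1000, 1000), 4701 / 32768,
               tolerance = 1e-12)
  expect_equal(tagcount_pvalue(17, 40, 50000, 200000), 0.10093134097857585,
               tolerance = 1e-12)
  expect_equal(tagcount_pvalue(3, 10, 2000, 1000), 0.0032954426424256565,
               tolerance = 1e-12)
  expect_equal(tagcount_pvalue(0, 4, 1000, 3000), 81 / 128, tolerance = 1e-12)

  expect_equal(tagcount_pvalue(0, 0, 1000, 5000), 1)
  expect_equal(tagcount_pvalue(5, 0, 1000, 1000),
               tagcount_pvalue(0, 5, 1000, 1000))

  # symmetry and oracle agreement over a grid
  set.seed(61)
  for (case in 1:60) {
    x <- sample(0:50, 1); y <- sample(0:50, 1)
    N1 <- sample(c(1e3, 1e6), 1); N2 <- sample(c(1e3, 1e6), 1)
    p <- tagcount_pvalue(x, y, N1, N2)
    expect_equal(p, tagcount_pvalue(y, x, N2, N1), tolerance = 1e-12)
    expect_equal(p, ac_oracle(x, y, N1, N2), tolerance = 1e-12)
  }

  # for fixed x and equal depths, p attains its maximum (1) at y = x
  for (x in c(3, 10, 25)) {
    ps <- vapply(0:60, function(y) tagcount_pvalue(x, y, 1000, 1000),
                 numeric(1))
    expect_equal(ps[x + 1], max(ps))
    expect_equal(max(ps), 1)
    expect_lt(ps[x + 21], 0.05)    # and decays away from the diagonal
  }
})

test_that("DE calls apply the strict fold-change rule and swap symmetry", {
  counts <- rbind(eq2 = c(CW = 5L, CS = 10L, HW = 5L, HS = 5L),
                  flat = c(100L, 100L, 100L, 100L),
                  up = c(50L, 400L, 50L, 50L))
  totals <- c(CW = 1e5, CS = 1e5, HW = 1e5, HS = 1e5)
  ex <- normalize_expression(counts, totals)
  de <- call_de(ex)
  # |log2FC| exactly 1 is not significant (strict inequality)
  r <- de[de$mirna == "eq2" & de$pair == "CS/CW", ]
  expect_equal(r$log2fc, 1)
  expect_false(r$significant)
  expect_false(any(de$significant[de$mirna == "flat"]))
  r2 <- de[de$mirna == "up" & de$pair == "CS/CW", ]
  expect_true(r2$significant)
  expect_identical(r2$stars, "**")

  # swapping treatment and control negates log2FC and preserves p
  de_sw <- call_de(ex, pairs = list("CS/CW" = c("CW", "CS")))
  m <- merge(as.data.frame(de[de$pair == "CS/CW", ]),
             as.data.frame(de_sw), by = "mirna")
  expect_equal(m$log2fc.x, -m$log2fc.y)
  expect_equal(m$pvalue.x, m$pvalue.y)

  # row order does not matter
  ex_rev <- normalize_expression(counts[3:1, ], totals)
  de_rev <- call_de(ex_rev)
  expect_equal(as.data.frame(de), as.data.frame(de_rev))
})

test_that("planted fold effects are recovered by the DE stage", {
  fx <- sim_fixture()
  tpm <- fx$sim$manifest$true_expression
  filtered <- fx$filtered
  clean_totals <- setNames(vapply(filtered, function(f)
    as.numeric(f$report$clean_reads), numeric(1)), names(filtered))
  counts <- mirna_counts(fx$cls$assignments)
  ex <- normalize_expression(counts, clean_totals)
  de <- call_de(ex)
  # at 8,000 reads/library expect recovery within 1 log2 unit for the
  # strongly expressed planted miRNAs (tighter bounds belong to the
  # full-depth acceptance run)
  both <- names(fx$cfg$de_effects)[1:7]   # baseline 2500/100k
  prs <- list("CS/CW" = c("CS", "CW"), "HW/CW" = c("HW", "CW"),
              "HS/CW" = c("HS", "CW"), "HS/HW" = c("HS", "HW"))
  for (m in both) {
    sub <- de[de$mirna == m, ]
    sub <- sub[match(names(prs), sub$pair), ]
    truth <- vapply(prs, function(pr) log2(tpm[m, pr[1]] / tpm[m, pr[2]]),
                    numeric(1))
    expect_equal(sub$log2fc, unname(truth), tolerance = 1)
    expect_true(all(sub$significant))
  }
})

test_that("two-way ANOVA decomposes a replicated 2x2 design and flags degeneracy", {
  set.seed(62)
  temp <- rep(c("C", "H"), each = 6)
  spd <- rep(rep(c("W", "S"), each = 3), 2)

  d <- twoway_anova(rep(1, 12), temp, spd)
  expect_true(attr(d, "degenerate"))

  expect_error(twoway_anova(rnorm(6), rep(c("C", "H"), each = 3),
                            c("W", "W", "S", "W", "S", "S")),
               "replicates|unbalanced")

  # large planted interaction is detected with high power
  hits <- 0
  for (i in 1:200) {
    inter <- ifelse(temp == "H" & spd == "S", 6, 0)
    y <- rnorm(12, mean = 10 + inter, sd = 1)
    a <- twoway_anova(y, temp, spd)
    if (a$p[a$term == "temperature:spd"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)

  # sums of squares partition the total exactly
  y <- rnorm(12, mean = 5)
  fit <- stats::aov(y ~ factor(temp) * factor(spd))
  ss <- summary(fit)[[1]][, "Sum Sq"]
  expect_equal(sum(ss), sum((y - mean(y))^2))
})
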