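# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# direct-summation oracle for the exact conditional tag-count test: binomial
# pmf built by forward ratio recurrence (no pbinom, no lgamma)
ac_oracle <- function(x, y, N1, N2) {
  t <- x + y
  p <- N1 / (N1 + N2)
  pmf <- numeric(t + 1)
  pmf[1] <- (1 - p)^t
  if (t > 0) for (k in 0:(t - 1))
    pmf[k + 2] <- pmf[k + 1] * (t - k) / (k + 1) * p / (1 - p)
  lower <- sum(pmf[seq_len(x + 1)])
  upper <- sum(pmf[(x + 1):(t + 1)])
  min(1, 2 * min(lower, upper))
}

# brute-force exact mapping: check every offset on both strands by substring
# comparison
naive_scan <- function(tag, genome) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- list()
  w <- nchar(tag)
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    L <- nchar(g)
    if (L < w) next
    kmers <- substring(g, 1:(L - w + 1), w:L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else rc(tag)
      pos <- which(kmers == pat)
      for (p in pos)
        out[[length(out) + 1L]] <- data.frame(
          tag = tag, chrom = chrom, start = p - 1L, end = p - 1L + w,
          strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(tag = character(), chrom = character(),
                                      start = integer(), end = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

# exhaustive stem enumeration over all (left arm start, right arm end, run
# length) placements; same objective as the implementation, different path
fold_oracle <- function(window, min_loop = 3L) {
  s <- strsplit(toupper(window), "")[[1]]
  pw <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(1)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(0.5)
    -2
  }
  n <- length(s)
  best_sum <- 0; best <- NULL
  for (i in 1:(n - 1)) for (j in n:(i + 1)) {
    maxL <- min(j - i + 1 - min_loop - 1, n)
    if (maxL < 1) next
    run <- 0
    for (L in 1:((maxL + 1) %/% 2)) {
      a <- i + L - 1L; b <- j - L + 1L
      if (b - a - 1L < min_loop) break
      run <- run + pw(s[a], s[b])
      if (run > best_sum) {
        best_sum <- run
        best <- list(i = i, j = j, L = L)
      }
    }
  }
  if (is.null(best)) return(list(score = 0, paired = 0L, net = 0))
  idx <- seq_len(best$L) - 1L
  w <- mapply(function(a, b) pw(s[a], s[b]), best$i + idx, best$j - idx)
  list(score = -sum(w[w > 0]), paired = as.integer(sum(w > 0)),
       net = best_sum)
}

# exhaustive hypergeometric upper tail by enumerating all draws (N <= 12)
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # label genes 1..K as term members
  mean(hits >= k)
}

# per-position recount of the plant target penalty
score_oracle <- function(mirna, window) {
  m <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  k <- length(m)
  pen <- 0
  for (i in seq_len(k)) {
    tb <- w[k - i + 1]
    wc <- tb == c(A = "T", C = "G", G = "C", T = "A")[[m[i]]]
    gu <- (m[i] == "G" && tb == "T") || (m[i] == "T" && tb == "G")
    unit <- if (i >= 2 && i <= 13) 2 else 1
    if (!wc) pen <- pen + if (gu) 0.5 * unit else unit
  }
  pen
}

# per-element membership enumeration for Venn region counts
venn_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  key <- vapply(universe, function(e) {
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(key)
  regions <- unlist(lapply(1:4, function(k)
    vapply(utils::combn(names(sets), k, simplify = FALSE),
           paste, character(1), collapse = "&")))
  counts <- as.integer(tab[regions])
  counts[is.na(counts)] <- 0L
  data.frame(region = regions, count = counts, stringsAsFactors = FALSE)
}

random_dna_chr <- function(n, len) {
  vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
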