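# Shared synthetic fixture, built once per test run: a moderate-depth
# simulation plus its preprocessing and annotation, reused by several files.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  cfg <- simulation_config(seed = 101L, n_reads_per_library = 8000L)
  ref <- build_reference(cfg)
  sim <- simulate_libraries(cfg, ref)
  filtered <- lapply(sim$reads, function(r)
    filter_reads(r, cfg$adapter3, cfg$adapter5, encoding = cfg$encoding))
  collapsed <- collapse_tags(lapply(filtered, function(f) f$clean$insert))
  hits <- map_to_genome(collapsed$tags$sequence, ref$genome)
  cls <- classify_tags(collapsed$tags, hits, ref$features, ref$known)
  .fixture_env$fx <- list(cfg = cfg, ref = ref, sim = sim,
                          filtered = filtered, collapsed = collapsed,
                          hits = hits, cls = cls)
  .fixture_env$fx
}

# a minimal known-miRNA reference for targeted unit tests
tiny_known_ref <- function() {
  mature <- "TGACAGAAGAGAGTGAGCACA"          # 21 nt
  loop <- "GTCGATTTCGA"
  star <- "TGTGCTCACTCTGTTCTGTCA"            # imperfect star not needed here
  data.frame(mirna = c("miR0001a", "miR0002a"),
             family = c("miR0001", "miR0002"),
             mature = c(mature, "AGCTTCGGACTAGCTAGGATT"),
             precursor = c(paste0(mature, loop, star),
                           paste0("CCGGT", "AGCTTCGGACTAGCTAGGATT",
                                  "TTTGACGTA", "AATCCTAGGTAGTCCGAAGGT")),
             stringsAsFactors = FALSE)
}

# quality string of constant value under phred64
q64 <- function(q, len) strrep(intToUtf8(64 + q), len)
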