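test_that("planted family proportions are exact arithmetic on the truth table", {
  fams <- list(repeat_family("sat43", "tandem", 43, 1000, 1000))
  pair <- build_genome_pair(genome_sim_spec(fams, 1e6, 1e6, seed = 5))
  expect_equal(pair$truth$prop_male, 0.043)
  expect_equal(pair$truth$prop_female, 0.043)
  expect_equal(nchar(pair$male), 1e6)
  # truth proportion == family bp / genome bp for arbitrary specs
  fams2 <- list(repeat_family("a", "tandem", 55, 200, 300),
                repeat_family("b", "dispersed", 210, 40, 10))
  pair2 <- build_genome_pair(genome_sim_spec(fams2, 25e4, 2e5, seed = 6))
  expect_equal(pair2$truth$prop_male,
               c(55 * 200, 210 * 40) / 25e4)
  expect_equal(pair2$truth$prop_female,
               c(55 * 300, 210 * 10) / 2e5)
  # coordinates cover exactly copies * unit_length bp per family
  co <- pair2$coords
  bp <- tapply(co$end - co$start + 1L, list(co$sex, co$family), sum)
  expect_equal(bp["male", "a"], 55 * 200)
  expect_equal(bp["female", "b"], 210 * 10)
})

test_that("a fixed seed reproduces genomes byte-identically", {
  fams <- list(repeat_family("sat", "tandem", 43, 500, 400, divergence = 0.02),
               repeat_family("el", "dispersed", 300, 30, 30, divergence = 0.05))
  spec <- genome_sim_spec(fams, 2.05e5, 2e5, seed = 11)
  p1 <- build_genome_pair(spec)
  p2 <- build_genome_pair(spec)
  expect_identical(p1$male, p2$male)
  expect_identical(p1$female, p2$female)
  expect_identical(p1$coords, p2$coords)
})

test_that("oversized family footprints raise a sizing error", {
  fams <- list(repeat_family("big", "tandem", 1000, 300, 300))
  expect_error(build_genome_pair(genome_sim_spec(fams, 1e5, 1e5, seed = 1)),
               "exceeds genome size")
})

test_that("copy divergence produces the expected mean pairwise identity", {
  fams <- list(repeat_family("el", "dispersed", 400, 50, 50,
                             divergence = 0.05))
  pair <- build_genome_pair(genome_sim_spec(fams, 1e5, 1e5, seed = 21))
  co <- pair$coords[pair$coords$sex == "male", ]
  copies <- substring(pair$male, co$start, co$end)
  # measure identity with the independent alignment engine
  idx <- replowpass:::with_seed(3, {
    cbind(sample(50, 40, replace = TRUE), sample(50, 40, replace = TRUE))
  })
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  st <- replowpass:::sw_stats_biostrings(copies[idx[, 1]], copies[idx[, 2]])
  ident <- st[, "matches"] / st[, "columns"]
  # two copies each 5% diverged from the master: expected identity ~ 0.905
  expect_lt(abs(mean(ident) - 0.905), 0.02)
})

test_that("long-read simulation matches its coverage arithmetic", {
  g <- random_dna(2e5, 0.4)
  cfg <- read_sim_config("long", 2000, mean_length = 250, length_sd = 50,
                         seed = 3)
  reads <- simulate_reads(g, cfg, "r")
  total <- sum(nchar(reads$seq))
  expect_lt(abs(total / (2000 * 250) - 1), 0.05)
  expect_true(all(nchar(reads$seq) >= 50 - 25))  # indel-free here: >= 50
  expect_true(all(reads$strand %in% c("+", "-")))
  # unbiased sampling reproduces the genome GC within 1%
  expect_lt(abs(mean(gc_content(reads$seq)) - gc_content(g)), 0.01)
})

test_that("duplicate_rate plants the expected number of exact duplicates", {
  g <- random_dna(5e5, 0.5)
  cfg <- read_sim_config("long", 10000, duplicate_rate = 0.1, seed = 8)
  reads <- simulate_reads(g, cfg, "r")
  n_dup <- sum(duplicated(reads$seq))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_dup, ci[1])
  expect_lte(n_dup, ci[2])
})

test_that("an empty read request warns and returns an empty set", {
  cfg <- read_sim_config("long", 0, seed = 1)
  expect_warning(reads <- simulate_reads(random_dna(1000), cfg), "empty")
  expect_equal(nrow(reads), 0)
})

test_that("GC-biased sampling shifts read GC in the slope direction", {
  g <- paste0(random_dna(5e4, 0.3), random_dna(5e4, 0.7))
  base <- simulate_reads(g, read_sim_config("long", 3000, seed = 4), "r")
  biased <- simulate_reads(g, read_sim_config("long", 3000,
                                              gc_bias_slope = 4, seed = 4), "r")
  expect_gt(mean(gc_content(biased$seq)), mean(gc_content(base$seq)) + 0.02)
})

test_that("spike-in mass fractions follow the requested split", {
  ctrl <- c(lambda = random_dna(8000, 0.5), t4 = random_dna(8000, 0.35))
  cfg <- read_sim_config("short", 20000, seed = 3)
  reads <- simulate_reads(random_dna(5e4, 0.4), cfg, "m")
  # 3% total split 3:1 -> 2.25% and 0.75%
  aug <- add_spike_ins(reads, ctrl, c(lambda = 0.03 * 3 / 4, t4 = 0.03 / 4),
                       cfg, seed = 5)
  truth <- attr(aug, "spike_in_truth")
  expect_equal(truth$requested, c(0.0225, 0.0075))
  expect_lt(max(abs(truth$realized - truth$requested)), 0.001)
  # 1:3 is the mirror image
  aug2 <- add_spike_ins(reads, ctrl, c(lambda = 0.03 / 4, t4 = 0.03 * 3 / 4),
                        cfg, seed = 5)
  expect_equal(attr(aug2, "spike_in_truth")$requested, c(0.0075, 0.0225))
  # zero fractions leave the pool unchanged
  aug0 <- add_spike_ins(reads, ctrl, c(lambda = 0, t4 = 0), cfg)
  expect_equal(nrow(aug0), nrow(reads))
  expect_error(add_spike_ins(reads, c(x = ""), 0.01, cfg), "empty control")
})
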