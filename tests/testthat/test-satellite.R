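test_that("the k-mer census counts every window once", {
  sp <- kmer_census(c("ACGTACGTAC"), 4, strand_policy = "as-is")
  expect_equal(sp$counts[sort(names(sp$counts))],
               c(ACGT = 2L, CGTA = 2L, GTAC = 2L, TACG = 1L))
  expect_equal(sum(kmer_census(c("ACGTACGTAC"), 10,
                               strand_policy = "as-is")$counts), 1L)
  expect_length(kmer_census(character(0), 4)$counts, 0)
  expect_error(kmer_census(c("ACGT"), 5), "exceeds")
  # both-strands doubles the total mass and is strand-symmetric
  sp2 <- kmer_census(c("ACGTTGCAAC"), 5)
  expect_equal(sum(sp2$counts), 2L * 6L)
  expect_equal(unname(sp2$counts[revcomp(names(sp2$counts))]),
               unname(sp2$counts))
})

test_that("planted monomers are recovered exactly from clean tags", {
  mono <- replowpass:::with_seed(121, random_dna(60, 0.4))
  arr <- paste(rep(mono, 50), collapse = "")
  tags <- simulate_clean_tags(arr, 1500, seed = 122)
  m <- reconstruct_monomer(kmer_census(tags, 12))
  expect_true(m$circular)
  expect_equal(m$length, 60)
  expect_true(replowpass:::rotation_equivalent(m$sequence, mono))
  expect_true(all(m$support == 1))

  # rotation invariance: tags from a rotated array give the same canonical form
  rot <- paste0(substr(mono, 21, 60), substr(mono, 1, 20))
  tags_rot <- simulate_clean_tags(paste(rep(rot, 50), collapse = ""), 1500,
                                  seed = 123)
  m2 <- reconstruct_monomer(kmer_census(tags_rot, 12))
  expect_equal(m2$sequence, m$sequence)

  # monotonicity: more tags never change the consensus
  tags_more <- rbind(tags, simulate_clean_tags(arr, 1500, seed = 124))
  m3 <- reconstruct_monomer(kmer_census(tags_more, 12))
  expect_equal(m3$sequence, m$sequence)
})

test_that("random tags yield no circular consensus", {
  tags <- replowpass:::with_seed(131, {
    data.frame(id = sprintf("t%d", 1:300),
               seq = vapply(1:300, function(i) random_dna(30, 0.5),
                            character(1)))
  })
  m <- reconstruct_monomer(kmer_census(tags, 14))
  expect_false(is.null(m))
  expect_false(m$circular)
  # an all-noise spectrum can also fall below the floor entirely
  expect_warning(reconstruct_monomer(kmer_census(character(0), 12)), "empty")
})

test_that("planted point variants are called at their frequency", {
  replowpass:::with_seed(141, {
    mono <- random_dna(100, 0.4)
    alt <- mono
    substr(alt, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(mono, 40, 40))[1]
    copies <- c(rep(mono, 80), rep(alt, 20))[sample(100)]
    arr <- paste(copies, collapse = "")
    tags <- simulate_clean_tags(arr, 5000, seed = 142)
    spec <- kmer_census(tags, 14)
    m <- reconstruct_monomer(spec)
    expect_true(replowpass:::rotation_equivalent(m$sequence, mono))
    v <- call_variants(spec, m)
    expect_equal(nrow(v), 1)
    expect_equal(v$start, v$end)
    expect_lt(abs(v$freq - 0.2), 0.05)
    # substituting the variant into the consensus reproduces the planted
    # variant monomer (up to rotation/strand)
    withvar <- m$sequence
    substr(withvar, v$start, v$end) <- v$sequence
    expect_true(replowpass:::rotation_equivalent(withvar, alt))
    # thresholds: nothing at min_rel_freq = 1; nothing without variants
    expect_equal(nrow(call_variants(spec, m, min_rel_freq = 1)), 0)
    clean <- kmer_census(simulate_clean_tags(paste(rep(mono, 100), collapse = ""),
                                             5000, seed = 143), 14)
    m0 <- reconstruct_monomer(clean)
    expect_equal(nrow(call_variants(clean, m0)), 0)
  })
})

test_that("probe windows maximise minimum support and honour tie rules", {
  mono <- replowpass:::with_seed(151, random_dna(80, 0.4))
  cons <- structure(list(sequence = mono, length = 80L, circular = TRUE,
                         support = rep(1, 80), k = 14L),
                    class = "consensus_monomer")
  p <- design_probe(cons)
  # uniform support: longest window, leftmost start on the canonical rotation
  expect_equal(p$start, 1L)
  expect_equal(p$length, 50L)
  expect_equal(p$probe, substr(paste0(mono, mono), 1, 50))

  # a low-support stretch is avoided
  cons2 <- cons
  cons2$support[10:20] <- 0.3
  p2 <- design_probe(cons2)
  covered <- ((p2$start - 1L) + seq_len(p2$length) - 1L) %% 80L + 1L
  expect_false(any(covered %in% 10:20))
  expect_equal(p2$min_support, 1)

  short <- cons; short$length <- 20L; short$sequence <- substr(mono, 1, 20)
  short$support <- rep(1, 20)
  expect_error(design_probe(short), "shorter")
})

test_that("variant-targeting probes carry the variant bases", {
  replowpass:::with_seed(161, {
    mono <- random_dna(100, 0.4)
    alt <- mono
    substr(alt, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(mono, 50, 50))[1]
    arr <- paste(c(rep(mono, 75), rep(alt, 25))[sample(100)], collapse = "")
    tags <- simulate_clean_tags(arr, 5000, seed = 162)
    spec <- kmer_census(tags, 14)
    m <- reconstruct_monomer(spec)
    v <- call_variants(spec, m)
    expect_equal(nrow(v), 1)
    pv <- design_probe(m, variant = v[1, ])
    offset <- v$start[1] - pv$start + 1L
    expect_gte(offset, 1L)
    expect_lte(offset, pv$length)
    expect_equal(substr(pv$probe, offset, offset), v$sequence[1])
  })
})

test_that("the consensus is identical across k for clean simulations", {
  mono <- replowpass:::with_seed(171, random_dna(120, 0.45))
  tags <- simulate_clean_tags(paste(rep(mono, 40), collapse = ""), 3000,
                              seed = 172)
  seqs <- vapply(c(12L, 14L, 17L), function(k)
    reconstruct_monomer(kmer_census(tags, k))$sequence, character(1))
  expect_equal(seqs[2], seqs[1])
  expect_equal(seqs[3], seqs[1])
})
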