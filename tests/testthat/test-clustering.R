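test_that("a tandem family clusters apart from unique background reads", {
  mono <- replowpass:::with_seed(61, random_dna(43, 0.4))
  arr <- paste(rep(mono, 120), collapse = "")
  fam_reads <- simulate_reads(arr,
                              read_sim_config("long", 30, mean_length = 250,
                                              length_sd = 20, seed = 62), "fam")
  bg <- random_reads(30, 250, seed = 63)
  reads <- rbind(fam_reads[, c("id", "seq")], bg)
  e <- find_overlaps(reads)
  cl <- build_clusters(reads, e)
  expect_equal(unname(cl$sizes["CL1"]), 30L)
  expect_length(cl$sizes, 1)
  expect_setequal(cl$unclustered, bg$id)
})

test_that("two unrelated families give two clusters matching truth", {
  fx <- fixture_two_family()
  fam_map <- cluster_family_map(fx$clusters, fx$reads, fx$labs)
  big <- names(fx$clusters$sizes)[fx$clusters$sizes >= 10]
  expect_length(big, 2)
  expect_setequal(unname(fam_map[big]), c("satA", "elem"))
  # recall: family reads land in their family's cluster; purity is looser
  # because reads dominated by flanking sequence carry the background label
  for (cl in big) {
    ids <- fx$clusters$membership$read_id[fx$clusters$membership$cluster == cl]
    labs <- fx$labs[match(ids, fx$reads$id)]
    expect_gte(mean(labs == fam_map[cl]), 0.6)
    fam_ids <- fx$reads$id[fx$labs == fam_map[cl]]
    expect_gte(mean(fam_ids %in% ids), 0.85)
  }
})

test_that("an empty edge set yields no clusters, only singletons", {
  reads <- random_reads(10, 100, seed = 3)
  cl <- build_clusters(reads, find_overlaps(reads))
  expect_length(cl$sizes, 0)
  expect_setequal(cl$unclustered, reads$id)
  s <- cluster_summary(cl, 10)
  expect_equal(attr(s, "clustered_fraction"), 0)
})

test_that("cluster summary reports proportions, cumulative mass and k_half", {
  cl <- list(sizes = c(CL1 = 60L, CL2 = 30L, CL3 = 10L),
             reads = data.frame(id = character(200)))
  class(cl) <- "read_clusters"
  s <- cluster_summary(cl, 200)
  expect_equal(s$proportion, c(0.30, 0.15, 0.05))
  expect_equal(s$cumulative, c(0.30, 0.45, 0.50))
  expect_equal(attr(s, "k_half"), 3L)
  expect_equal(attr(s, "clustered_fraction"), 0.5)
  expect_error(cluster_summary(cl, 0), "positive")
})

test_that("cluster labels are invariant to read input order", {
  fx <- fixture_two_family()
  reads <- fx$reads
  perm <- replowpass:::with_seed(8, sample(nrow(reads)))
  cl1 <- fx$clusters
  cl2 <- build_clusters(reads[perm, ], find_overlaps(reads[perm, ]))
  m1 <- cl1$membership[order(cl1$membership$read_id), ]
  m2 <- cl2$membership[order(cl2$membership$read_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("graph shapes separate tandem rings, dispersed bands and satellites", {
  # long-unit tandem array: reads tile a 2000-bp ring
  unit <- replowpass:::with_seed(71, random_dna(2000, 0.45))
  ring_genome <- paste(rep(unit, 5), collapse = "")
  ring_reads <- simulate_reads(ring_genome,
                               read_sim_config("long", 120, mean_length = 250,
                                               length_sd = 20, seed = 72), "ring")
  cl_ring <- build_clusters(ring_reads, find_overlaps(ring_reads),
                            split_density_max = 0)
  expect_equal(classify_graph_shape(cl_ring, "CL1"), "circular")

  # dispersed 5-kb element: reads tile a linear band
  el <- replowpass:::with_seed(73, random_dna(5000, 0.4))
  band_reads <- simulate_reads(el,
                               read_sim_config("long", 260, mean_length = 250,
                                               length_sd = 20, seed = 74), "band")
  cl_band <- build_clusters(band_reads, find_overlaps(band_reads),
                            split_density_max = 0)
  expect_equal(classify_graph_shape(cl_band, "CL1"), "linear")

  # short-monomer satellite: near-clique
  mono <- replowpass:::with_seed(75, random_dna(43, 0.35))
  sat_reads <- simulate_reads(paste(rep(mono, 200), collapse = ""),
                              read_sim_config("long", 40, mean_length = 250,
                                              length_sd = 20, seed = 76), "sat")
  cl_sat <- build_clusters(sat_reads, find_overlaps(sat_reads),
                           split_density_max = 0)
  expect_equal(classify_graph_shape(cl_sat, "CL1"), "globular")

  # small clusters are not classified
  expect_equal(classify_graph_shape(cl_sat, "CL999"), "other")
})

test_that("tandem periodicity is detected by the self-alignment lag scan", {
  expect_equal(detect_tandem_period(paste(rep("ACGTT", 20), collapse = "")), 5L)

  rnd <- replowpass:::with_seed(81, random_dna(300, 0.5))
  expect_true(is.na(detect_tandem_period(rnd)))
  # independent check: no lag reaches 80% ungapped identity
  bases <- strsplit(rnd, "")[[1]]
  idents <- vapply(1:100, function(p)
    mean(bases[1:(300 - p)] == bases[(p + 1):300]), numeric(1))
  expect_true(all(idents < 0.8))

  mono <- replowpass:::with_seed(82, random_dna(43, 0.4))
  arr <- replowpass:::with_seed(83, {
    paste(vapply(1:12, function(i) replowpass:::mutate_sequence(mono, 0.02),
                 character(1)), collapse = "")
  })
  expect_equal(detect_tandem_period(arr), 43L)
})
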