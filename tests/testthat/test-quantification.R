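# Two hand-built clusters with a shared-but-diverged 30-nt window, used to
# probe assignment distances and tie-breaks.
make_assignment_fixture <- function(n_a = 3, n_b = 2) {
  replowpass:::with_seed(101, {
    w <- random_dna(30, 0.5)
    w1 <- w; substr(w1, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                         substr(w, 5, 5))[1]
    w2 <- w; substr(w2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                           substr(w, 20, 20))[1]
    x <- paste0(random_dna(110, 0.5), w1, random_dna(110, 0.5))
    y <- paste0(random_dna(110, 0.5), w2, random_dna(110, 0.5))
    reads <- data.frame(
      id = c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b))),
      seq = c(rep(x, n_a), rep(y, n_b)), stringsAsFactors = FALSE)
    cl <- build_clusters(reads, find_overlaps(reads))
    list(reads = reads, clusters = cl, w = w, w1 = w1, w2 = w2, x = x, y = y)
  })
}

test_that("tags assign to the minimal-edit-distance cluster within two edits", {
  fx <- make_assignment_fixture()
  idx <- build_tag_index(fx$clusters)
  cl_a <- fx$clusters$membership$cluster[fx$clusters$membership$read_id == "a1"]
  cl_b <- fx$clusters$membership$cluster[fx$clusters$membership$read_id == "b1"]

  # exact substring: distance 0
  t0 <- substr(fx$x, 31, 60)
  a <- assign_tags(data.frame(id = "t0", seq = t0), idx)
  expect_equal(a$cluster, cl_a)
  expect_equal(a$distance, 0L)

  # distance 1 to cluster A, 2 to cluster B: distance dominates size
  t1 <- fx$w1
  substr(t1, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(t1, 25, 25))[1]
  # t1 is 1 edit from w1 (in A) and 2 from w2? no: w1 vs w2 differ at 5 and 20
  # t1 differs from w1 at 25 only (d=1) and from w2 at 5, 20, 25 (d=3)
  a1 <- assign_tags(data.frame(id = "t1", seq = t1), idx)
  expect_equal(a1$cluster, cl_a)
  expect_equal(a1$distance, 1L)

  # three edits from everything: unassigned
  t3 <- fx$w1
  for (p in c(10, 18, 27))
    substr(t3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(t3, p, p))[1]
  a3 <- assign_tags(data.frame(id = "t3", seq = t3), idx)
  expect_true(is.na(a3$cluster))

  # reverse-complement tags assign identically
  arc <- assign_tags(data.frame(id = "t0rc", seq = revcomp(t0)), idx)
  expect_equal(arc$cluster, cl_a)
  expect_equal(arc$distance, 0L)
})

test_that("equal-distance ties go to the larger cluster, then the smaller id", {
  fx <- make_assignment_fixture(n_a = 3, n_b = 2)
  idx <- build_tag_index(fx$clusters)
  # the unmutated window w is 1 edit from w1 (cluster A) and 1 from w2 (B)
  a <- assign_tags(data.frame(id = "w", seq = fx$w), idx)
  big <- names(fx$clusters$sizes)[which.max(fx$clusters$sizes)]
  expect_equal(a$cluster, big)
  expect_equal(a$distance, 1L)

  # with equal sizes the smaller cluster id wins
  fx2 <- make_assignment_fixture(n_a = 2, n_b = 2)
  idx2 <- build_tag_index(fx2$clusters)
  a2 <- assign_tags(data.frame(id = "w", seq = fx2$w), idx2)
  expect_equal(a2$cluster, "CL1")
})

test_that("seeded assignment equals the brute-force edit-distance scan", {
  fx <- fixture_two_family()
  tags <- simulate_clean_tags(fx$pair$male, 400, seed = 102)
  # add some mutated and some random tags
  tags$seq[1:50] <- vapply(tags$seq[1:50], function(s)
    replowpass:::mutate_sequence(s, 0.04), character(1))
  tags$seq[51:70] <- vapply(51:70, function(i) random_dna(30, 0.5), character(1))
  a_fast <- assign_tags(tags, build_tag_index(fx$clusters))
  a_slow <- assign_tags_bruteforce(tags, fx$clusters)
  expect_identical(a_fast$cluster, a_slow$cluster)
  expect_identical(a_fast$distance, a_slow$distance)
  # conservation: every tag is counted exactly once
  expect_equal(sum(is.na(a_fast$cluster)) + sum(!is.na(a_fast$cluster)),
               nrow(tags))
})

test_that("the male/female ratio statistic matches its anchor values", {
  expect_equal(mf_ratio(0.02, 0.02), 0.5)
  expect_equal(round(mf_ratio(0.04, 0.02), 2), 0.67)
  expect_equal(round(mf_ratio(0.01, 0.03), 2), 0.25)
  expect_true(is.na(mf_ratio(0, 0)))
  # antisymmetry
  p <- replowpass:::with_seed(5, runif(50))
  q <- replowpass:::with_seed(6, runif(50))
  expect_equal(mf_ratio(p, q), 1 - mf_ratio(q, p))
})

test_that("proportion tables are tag fractions with a reporting floor", {
  am <- data.frame(id = sprintf("m%d", 1:1500),
                   cluster = c(rep("CL1", 1000), rep("CL2", 500)),
                   distance = 0L)
  af <- data.frame(id = sprintf("f%d", 1:1004),
                   cluster = c(rep("CL1", 1000), rep("CL2", 4)),
                   distance = 0L)
  tab <- quantify(am, af, total_male = 1e5, total_female = 1e5)
  expect_equal(tab$p_male[tab$cluster == "CL1"], 0.01)
  expect_equal(tab$mf_ratio[tab$cluster == "CL1"], 0.5)
  expect_false(tab$reliable[tab$cluster == "CL2"] &&
                 (tab$p_male[tab$cluster == "CL2"] +
                    tab$p_female[tab$cluster == "CL2"]) / 2 < 5e-5)
  expect_error(quantify(am, af, total_male = 0), "positive")
})

test_that("control calibration flags only clusters beyond the envelope", {
  tab <- data.frame(cluster = c("CL1", "CL2", "CL3", "CL9", "CL10"),
                    tags_male = c(100, 225, 75, 980, 100),
                    tags_female = c(100, 75, 225, 20, 101),
                    p_male = c(0.01, 0.0225, 0.0075, 0.098, 0.01),
                    p_female = c(0.01, 0.0075, 0.0225, 0.002, 0.0101),
                    stringsAsFactors = FALSE)
  tab$mf_ratio <- mf_ratio(tab$p_male, tab$p_female)
  tab$gc <- 0.4
  tab$reliable <- TRUE
  class(tab) <- c("proportion_table", "data.frame")
  controls <- data.frame(cluster = c("CL2", "CL3"),
                         expected_male = c(0.0225, 0.0075),
                         expected_female = c(0.0075, 0.0225))
  out <- calibrate_with_controls(tab, controls)
  expect_equal(out$cluster[out$flagged], "CL9")
  expect_gte(attr(out, "envelope"), 0.25)

  # all-equal table: nothing flagged
  tab2 <- tab
  tab2$p_female <- tab2$p_male
  tab2$mf_ratio <- 0.5
  out2 <- calibrate_with_controls(tab2, controls)
  expect_false(any(out2$flagged[!tab2$cluster %in% controls$cluster]))

  expect_warning(calibrate_with_controls(tab, NULL), "disabled")
})

test_that("copy number and genome coverage follow their defining formulas", {
  expect_equal(copy_number(0, 1e9, 300), 0)
  expect_equal(copy_number(0.01, 3e9, 300), 1e5)
  expect_error(copy_number(0.01, 1e9, 0), "positive")
  expect_equal(genome_coverage(0, 1e9), 0)
  expect_equal(genome_coverage(1e9, 1e9), 1)
  expect_error(genome_coverage(1, 0), "positive")
  expect_equal(sex_linked_abundance_ratio(0, 0.5, 10), 1)
})

test_that("the GC-bias diagnostic detects association and degeneracy", {
  replowpass:::with_seed(111, {
    gc <- runif(60, 0.25, 0.75)
    dev <- -0.4 * (gc - 0.5) + rnorm(60, 0, 0.03)
    tab <- data.frame(cluster = sprintf("CL%d", 1:60), gc = gc,
                      mf_ratio = 0.5 + dev)
    d <- gc_bias_diagnostic(tab, n_perm = 999, seed = 2)
    expect_lt(d$rho, 0)
    expect_lt(d$p_value, 0.05)

    # under the null the rejection rate stays near the nominal level
    rejections <- sum(vapply(1:20, function(i) {
      tab_null <- tab
      tab_null$mf_ratio <- 0.5 + rnorm(60, 0, 0.03)
      gc_bias_diagnostic(tab_null, n_perm = 499, seed = i)$p_value < 0.05
    }, logical(1)))
    expect_lte(rejections, 3)

    tab_const <- tab
    tab_const$gc <- 0.5
    dc <- gc_bias_diagnostic(tab_const, n_perm = 99, seed = 2)
    expect_true(is.na(dc$rho))
  })
})
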