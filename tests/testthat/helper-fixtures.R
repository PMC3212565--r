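# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Random reads with no shared structure.
random_reads <- function(n, len = 250, seed = 99, gc = 0.5) {
  replowpass:::with_seed(seed, {
    data.frame(id = sprintf("rnd_%04d", seq_len(n)),
               seq = vapply(seq_len(n), function(i) random_dna(len, gc),
                            character(1)),
               stringsAsFactors = FALSE)
  })
}

# Two short-unit families plus background: the workhorse clustering fixture.
# Unit lengths are chosen to be spanned by single reads so each family forms
# one dense graph component.
fixture_two_family <- function() fixture("two_family", function() {
  fams <- list(
    repeat_family("satA", "tandem", 43, 2500, 2500, divergence = 0.01,
                  gc_target = 0.35),
    repeat_family("elem", "dispersed", 200, 450, 450, divergence = 0.03,
                  gc_target = 0.45))
  spec <- genome_sim_spec(fams, 1e6, 1e6, seed = 42)
  pair <- build_genome_pair(spec)
  cfg <- read_sim_config("long", 500, mean_length = 250, length_sd = 40,
                         seed = 7)
  reads <- simulate_reads(pair$male, cfg, "m")
  labs <- label_reads(reads, pair, "male")
  edges <- find_overlaps(reads)
  clusters <- build_clusters(reads, edges)
  list(pair = pair, reads = reads, labs = labs, edges = edges,
       clusters = clusters)
})

# Plain Rand index between two partitions given as label vectors.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    sa <- a[i] == a[(i + 1L):n]
    sb <- b[i] == b[(i + 1L):n]
    agree <- agree + sum(sa == sb)
  }
  agree / choose(n, 2)
}

# Map each cluster to the majority truth family of its member reads.
cluster_family_map <- function(clusters, reads, labs) {
  m <- merge(clusters$membership,
             data.frame(read_id = reads$id, lab = labs,
                        stringsAsFactors = FALSE))
  tab <- table(m$cluster, m$lab)
  stats::setNames(colnames(tab)[apply(tab, 1L, which.max)], rownames(tab))
}

# Direct 30-nt tags (positions 3-32 of simulated error-free short reads).
simulate_clean_tags <- function(genome, n, seed, id_prefix = "tag") {
  cfg <- read_sim_config("short", n, error_from_quality = FALSE, seed = seed)
  reads <- simulate_reads(genome, cfg, id_prefix)
  data.frame(id = reads$id, seq = substr(reads$seq, 3L, 32L),
             start = reads$start, stringsAsFactors = FALSE)
}
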