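#' Default demo run configuration
#'
#' A desk-scale configuration exercising the whole pipeline: a 300 kb
#' genome pair carrying a dispersed retroelement-like family, a short-
#' monomer satellite, an rDNA-like tandem unit and two spike-in controls
#' mixed 3:1 (male) versus 1:3 (female) at 3% of each sample.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `run_config` list; see [validate_run_config()] for the fields.
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    families = list(
      list(name = "retro1", kind = "dispersed", unit_length = 2000L,
           copies_male = 25L, copies_female = 25L, divergence = 0.03,
           gc_target = 0.40),
      list(name = "satA", kind = "tandem", unit_length = 43L,
           copies_male = 450L, copies_female = 450L, divergence = 0.01,
           gc_target = 0.35),
      list(name = "rdna", kind = "rdna_like", unit_length = 3000L,
           copies_male = 6L, copies_female = 6L, divergence = 0.005,
           gc_target = 0.50),
      list(name = "lambda_ctrl", kind = "spike_in", unit_length = 2000L,
           copies_male = 0L, copies_female = 0L, divergence = 0,
           gc_target = 0.50),
      list(name = "t4_ctrl", kind = "spike_in", unit_length = 2000L,
           copies_male = 0L, copies_female = 0L, divergence = 0,
           gc_target = 0.35)),
    genome_1C_male = 300000L, genome_1C_female = 300000L,
    background_gc = 0.37,
    long_reads = list(n_male = 400L, n_female = 400L, mean_length = 250,
                      length_sd = 50, sub_rate = 0.005, ins_rate = 0.002,
                      del_rate = 0.002, duplicate_rate = 0.02),
    short_reads = list(n_male = 60000L, n_female = 86000L,
                       gc_bias_slope = 0),
    spike_in = list(total = 0.03, male_split = c(3, 1), female_split = c(1, 3)),
    subsample_n = 40000L,
    thresholds = list(min_identity = 0.90, min_shorter_coverage = 0.55,
                      max_mismatches = 2L, trim_window = c(3L, 32L),
                      min_q = 10L, min_frac = 0.9, k = 14L,
                      reporting_floor = 5e-5))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Validate a run configuration
#'
#' Checks every threshold against its documented domain before any stage
#' runs; errors carry class `replowpass_validation_error`.
#'
#' @param config A `run_config` list.
#' @return The config, invisibly, when valid.
#' @export
validate_run_config <- function(config) {
  fail <- function(msg) stop(structure(
    class = c("replowpass_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
  th <- config$thresholds
  if (is.null(th)) fail("missing thresholds")
  if (!is.numeric(th$min_identity) || th$min_identity <= 0 || th$min_identity > 1)
    fail("min_identity must be in (0, 1]")
  if (th$min_shorter_coverage <= 0 || th$min_shorter_coverage > 1)
    fail("min_shorter_coverage must be in (0, 1]")
  if (th$max_mismatches < 0 || th$max_mismatches > 5)
    fail("max_mismatches must be in 0..5")
  if (length(th$trim_window) != 2 || th$trim_window[1] < 1 ||
      th$trim_window[2] <= th$trim_window[1])
    fail("trim_window must be an increasing pair of positive positions")
  if (th$min_q < 0 || th$min_frac <= 0 || th$min_frac > 1)
    fail("quality rule out of domain")
  if (th$k < 10 || th$k > 17) fail("k must be in 10..17")
  if (th$reporting_floor < 0 || th$reporting_floor > 0.01)
    fail("reporting_floor must be a small fraction")
  if (config$genome_1C_male <= 0 || config$genome_1C_female <= 0)
    fail("genome sizes must be positive")
  sp <- config$spike_in
  if (!is.null(sp) && (sp$total < 0 || sp$total >= 0.5))
    fail("spike-in total must be in [0, 0.5)")
  invisible(config)
}

#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and write run configurations
#'
#' Round-trips a `run_config` through a YAML file losslessly.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @name run_config_io
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml flattens length-1 vectors; restore integer types where they matter
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_genome_spec <- function(config) {
  fams <- lapply(config$families, function(f)
    repeat_family(name = f$name, kind = f$kind, unit_length = f$unit_length,
                  copies_male = f$copies_male, copies_female = f$copies_female,
                  divergence = f$divergence, gc_target = f$gc_target))
  genome_sim_spec(fams, genome_1C_male = config$genome_1C_male,
                  genome_1C_female = config$genome_1C_female,
                  background_gc = config$background_gc,
                  seed = derive_seed(config$seed, 1L))
}

#' Run the full pipeline on a simulated dataset
#'
#' Executes the stages in dependency order — genome simulation, long- and
#' short-read simulation with spike-ins, long-read deduplication, overlap
#' detection and clustering, tag trimming/filtering/subsampling, tag
#' assignment and quantification with control calibration, and satellite
#' consensus reconstruction for tandem clusters — writing each stage's
#' tables under `out_dir` together with a manifest of file checksums, seeds
#' and read/tag conservation counts. Rerunning with the same config
#' reproduces byte-identical tables.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return A list with the main in-memory results (`pair`, `clusters`,
#'   `summary`, `proportions`, `monomers`, `manifest`), invisibly.
#' @export
run_all <- function(config, out_dir = tempfile("replowpass_run_")) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_line("stage ", name, " done")
    res
  }

  pair <- stage("simulate_genomes", build_genome_pair(config_genome_spec(config)))

  lr <- config$long_reads
  make_long <- function(sex, n, seed_off, id_prefix) {
    cfg <- read_sim_config("long", n, mean_length = lr$mean_length,
                           length_sd = lr$length_sd, sub_rate = lr$sub_rate,
                           ins_rate = lr$ins_rate, del_rate = lr$del_rate,
                           duplicate_rate = lr$duplicate_rate,
                           seed = derive_seed(config$seed, seed_off))
    simulate_reads(pair[[sex]], cfg, id_prefix = id_prefix)
  }
  sp <- config$spike_in
  spike_fracs <- function(split)
    stats::setNames(sp$total * split / sum(split),
                    utils::head(names(pair$controls), length(split)))
  long_reads <- stage("simulate_long_reads", {
    lm <- make_long("male", lr$n_male, 2L, "m454")
    lf <- make_long("female", lr$n_female, 3L, "f454")
    if (!is.null(sp) && sp$total > 0 && length(pair$controls) >= 2) {
      cfgm <- read_sim_config("long", 1L, mean_length = lr$mean_length,
                              length_sd = lr$length_sd,
                              seed = derive_seed(config$seed, 4L))
      lm <- add_spike_ins(lm, pair$controls, spike_fracs(sp$male_split),
                          cfgm, seed = derive_seed(config$seed, 5L),
                          id_prefix = "spkm454")
      lf <- add_spike_ins(lf, pair$controls, spike_fracs(sp$female_split),
                          cfgm, seed = derive_seed(config$seed, 6L),
                          id_prefix = "spkf454")
    } else {
      lm$control <- NA_character_; lf$control <- NA_character_
    }
    combined <- rbind(lm, lf)
    combined$sample <- rep(c("male", "female"), c(nrow(lm), nrow(lf)))
    attr(combined, "platform") <- "long"
    combined
  })

  deduped <- stage("dedup", dedup_long_reads(long_reads))
  log_line("reads in ", nrow(long_reads), ", after dedup ", nrow(deduped))

  clusters <- stage("cluster", {
    edges <- find_overlaps(deduped, min_identity = th$min_identity,
                           min_shorter_coverage = th$min_shorter_coverage)
    build_clusters(deduped, edges)
  })
  summary_tab <- cluster_summary(clusters)

  make_short <- function(sex, n, seed_off, id_prefix, profile) {
    cfg <- read_sim_config("short", n,
                           gc_bias_slope = config$short_reads$gc_bias_slope,
                           quality_profile = profile,
                           seed = derive_seed(config$seed, seed_off))
    reads <- simulate_reads(pair[[sex]], cfg, id_prefix = id_prefix)
    if (!is.null(sp) && sp$total > 0 && length(pair$controls) >= 2) {
      split <- if (sex == "male") sp$male_split else sp$female_split
      reads <- add_spike_ins(reads, pair$controls, spike_fracs(split), cfg,
                             seed = derive_seed(config$seed, seed_off + 10L),
                             id_prefix = paste0("spk", substr(sex, 1, 1)))
    }
    reads
  }
  tags <- stage("tags", {
    sm <- make_short("male", config$short_reads$n_male, 20L, "mtag",
                     default_quality_profile("male"))
    sf <- make_short("female", config$short_reads$n_female, 21L, "ftag",
                     default_quality_profile("female"))
    tm <- trim_and_filter(sm, window = th$trim_window, min_q = th$min_q,
                          min_frac = th$min_frac)$tags
    tf <- trim_and_filter(sf, window = th$trim_window, min_q = th$min_q,
                          min_frac = th$min_frac)$tags
    n_sub <- min(config$subsample_n, nrow(tm), nrow(tf))
    list(male = subsample_tags(tm, n_sub, derive_seed(config$seed, 22L)),
         female = subsample_tags(tf, n_sub, derive_seed(config$seed, 23L)),
         raw_male = nrow(sm), raw_female = nrow(sf))
  })
  log_line("tags male ", nrow(tags$male), " of ", tags$raw_male,
           "; female ", nrow(tags$female), " of ", tags$raw_female)

  proportions <- stage("quantify", {
    index <- build_tag_index(clusters, tag_length = diff(th$trim_window) + 1L)
    am <- assign_tags(tags$male, index, th$max_mismatches)
    af <- assign_tags(tags$female, index, th$max_mismatches)
    tab <- quantify(am, af, clusters = clusters,
                    reporting_floor = th$reporting_floor)
    if (!is.null(sp) && sp$total > 0 && length(pair$controls) >= 2) {
      ctrl_cl <- control_clusters(clusters, long_reads)
      ctrl_cl <- ctrl_cl[ctrl_cl$cluster %in% tab$cluster, , drop = FALSE]
      if (nrow(ctrl_cl)) {
        fm <- spike_fracs(sp$male_split); ff <- spike_fracs(sp$female_split)
        ctrl_cl$expected_male <- fm[ctrl_cl$control]
        ctrl_cl$expected_female <- ff[ctrl_cl$control]
        tab <- calibrate_with_controls(tab, ctrl_cl)
      }
    }
    tab
  })

  monomers <- stage("satellites", {
    out <- list()
    all_tags <- rbind(tags$male, tags$female)
    index <- build_tag_index(clusters, diff(th$trim_window) + 1L)
    assigned <- assign_tags(all_tags, index, th$max_mismatches)
    for (cl in names(clusters$sizes)) {
      if (clusters$sizes[[cl]] < 10L) next
      rep_read <- cluster_reads(clusters, cl)
      # poll several of the longest members: any one with detectable
      # periodicity marks the cluster as tandem
      rep_seqs <- utils::head(rep_read$seq[order(-nchar(rep_read$seq))], 5L)
      periods <- vapply(rep_seqs, detect_tandem_period, integer(1))
      if (all(is.na(periods))) next
      cl_tags <- all_tags[!is.na(assigned$cluster) & assigned$cluster == cl, ,
                          drop = FALSE]
      if (nrow(cl_tags) < 50L) next
      spec <- kmer_census(cl_tags, th$k)
      mono <- reconstruct_monomer(spec)
      if (!is.null(mono)) out[[cl]] <- mono
    }
    out
  })

  # persist tables
  utils::write.table(pair$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(clusters$membership, file.path(out_dir, "membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary_tab, file.path(out_dir, "cluster_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(proportions),
                     file.path(out_dir, "proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(monomers)) {
    cons <- data.frame(cluster = names(monomers),
                       length = vapply(monomers, `[[`, numeric(1), "length"),
                       circular = vapply(monomers, `[[`, logical(1), "circular"),
                       sequence = vapply(monomers, `[[`, character(1), "sequence"))
    utils::write.table(cons, file.path(out_dir, "monomers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_line("run complete")
  invisible(list(pair = pair, clusters = clusters, summary = summary_tab,
                 proportions = proportions, monomers = monomers,
                 manifest = manifest, out_dir = out_dir))
}

#' Identify the clusters formed by spike-in control reads
#'
#' Returns every cluster in which control reads are the majority of the
#' members, mapped to its majority control. Control material can fragment
#' into more than one cluster at low coverage; all such clusters carry the
#' control's expected male/female ratio and must be treated as controls
#' (and excluded from sex-differential flagging).
#'
#' @param clusters A `read_clusters` object.
#' @param long_reads The long-read pool with its `control` column.
#' @return `data.frame` with `control` and `cluster`, one row per
#'   control-dominated cluster.
#' @export
control_clusters <- function(clusters, long_reads) {
  memb <- clusters$membership
  ctrl_of <- stats::setNames(long_reads$control, long_reads$id)
  memb$control <- as.character(ctrl_of[memb$read_id])
  out <- do.call(rbind, lapply(split(memb, memb$cluster), function(d) {
    n_ctrl <- sum(!is.na(d$control))
    if (n_ctrl <= nrow(d) / 2) return(NULL)
    top <- names(sort(table(d$control), decreasing = TRUE))[1L]
    data.frame(control = top, cluster = d$cluster[1L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(control = character(0), cluster = character(0)))
  rownames(out) <- NULL
  out[order(out$control, out$cluster), , drop = FALSE]
}
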