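#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the analysis
#' defaults: mislabel cutoff 0.015, N = 5 representatives, classification
#' posterior cutoff 0.9, compound-name threshold 0.05, island cutoff 0.02,
#' log continuity constant 0.5, top-30% taxon trimming, read filters
#' (min length 200 nt, mean quality 35, clip windows of 30 bases at Phred
#' 15 with 90% coverage).
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_samples,frac_bv,race_mix cohort design (defaults mirror a
#'   220-woman STD-clinic cohort: 44.5% BV by Amsel, race mix
#'   Black/White/Other = 0.34/0.44/0.22).
#' @param n_taxa,seqs_per_taxon,seq_length reference world size.
#' @param placement_spread stray posterior mass fraction for simulated
#'   placements.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "qc", "refpkg", "classify", "massmath", "edgepca",
#'   "ecology", "assoc")`.
#' @param n_boot squash bootstrap replicates (0 disables the bootstrap).
#' @param effect an [effect_config()].
#' @param mislabel_cutoff,n_representatives,classify_cutoff,
#'   compound_threshold,island_cutoff,top_frac,min_len,min_avg_qual,
#'   window,q_threshold,min_frac,enet_alpha,enet_folds stage tunables (see
#'   the stage functions).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("placemass_run_"),
                            seed = 1,
                            n_samples = 60, frac_bv = 0.445,
                            race_mix = c(Black = 0.34, White = 0.44, Other = 0.22),
                            n_taxa = 12, seqs_per_taxon = 5, seq_length = 300,
                            placement_spread = 0.02,
                            stages = c("simulate", "qc", "refpkg", "classify",
                                       "massmath", "edgepca", "ecology", "assoc"),
                            n_boot = 0,
                            effect = effect_config(),
                            mislabel_cutoff = 0.015, n_representatives = 5,
                            classify_cutoff = 0.9, compound_threshold = 0.05,
                            island_cutoff = 0.02, top_frac = 0.30,
                            min_len = 200, min_avg_qual = 35,
                            window = 30, q_threshold = 15, min_frac = 0.9,
                            enet_alpha = 0.5, enet_folds = 10) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the placement pipeline end to end
#'
#' Executes the toggled stages in order — simulate (reference world,
#' cohort, placements, FASTQ) -> read QC -> reference package curation ->
#' classification -> tree-mass analysis (KR distances, squash clustering)
#' -> edge PCA -> ecology -> association models — writing CSV / newick /
#' jplace / JSON artifacts and a provenance manifest into
#' `config$out_dir`. Reruns with the same config are reproducible.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "qc", "refpkg", "classify", "massmath",
                  "edgepca", "ecology", "assoc")
  stages <- intersect(all_stages, cfg$stages)
  res <- list(out_dir = cfg$out_dir)
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[placemass %6.1fs] stage: %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), name))
  }
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop("stage '", stage, "' needs '", what,
           "' from an earlier stage that was not run", call. = FALSE)
    }
    res[[what]]
  }

  if ("simulate" %in% stages) {
    log_stage("simulate")
    res$world <- simulate_reference_world(
      n_taxa = cfg$n_taxa, seqs_per_taxon = cfg$seqs_per_taxon,
      seq_length = cfg$seq_length, seed = cfg$seed
    )
    species <- res$world$taxonomy$taxid[res$world$taxonomy$rank == "species"]
    res$cohort <- simulate_cohort(
      n_samples = cfg$n_samples, frac_bv = cfg$frac_bv,
      race_mix = cfg$race_mix, taxa = species, config = cfg$effect,
      seed = cfg$seed + 1
    )
    res$placements <- simulate_placements(
      res$cohort$counts, res$world,
      placement_spread = cfg$placement_spread, seed = cfg$seed + 2
    )
    utils::write.csv(res$cohort$meta, file.path(cfg$out_dir, "meta.csv"),
                     row.names = FALSE)
    utils::write.csv(res$cohort$counts, file.path(cfg$out_dir, "counts.csv"),
                     row.names = FALSE)
  }

  if ("qc" %in% stages) {
    log_stage("qc")
    world <- need("world", "qc")
    cohort <- need("cohort", "qc")
    # raw-run emulation on a subsample keeps the demo quick
    qc_counts <- dplyr::mutate(cohort$counts,
                               count = pmin(.data$count, 30L))
    run <- write_fastq_run(
      qc_counts, world,
      path = file.path(cfg$out_dir, "raw_run.fastq"),
      fail_frac = c(bad_barcode = 0.03, short = 0.04, low_quality = 0.03),
      seed = cfg$seed + 3
    )
    qc <- demultiplex_and_filter(
      read_fastq(run$path), run$barcodes, primer = "ATTAGAWACCC",
      min_len = cfg$min_len, min_avg_qual = cfg$min_avg_qual,
      window = cfg$window, q_threshold = cfg$q_threshold,
      min_frac = cfg$min_frac
    )
    res$qc <- qc
    res$injection_log <- run$injection_log
    jsonlite::write_json(
      list(
        n_input = qc$report$n_input, n_retained = qc$report$n_retained,
        discards = qc$report$discards
      ),
      file.path(cfg$out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA
    )
  }

  if ("refpkg" %in% stages) {
    log_stage("refpkg")
    world <- need("world", "refpkg")
    res$refpkg <- build_reference_package(
      world$sequences, world$taxonomy,
      cutoff = cfg$mislabel_cutoff, n_representatives = cfg$n_representatives
    )
    write_refpkg(res$refpkg, file.path(cfg$out_dir, "refpkg"))
  }

  if ("classify" %in% stages) {
    log_stage("classify")
    refpkg <- need("refpkg", "classify")
    placements <- need("placements", "classify")
    # placements are simulated on the world tree; classify on that tree
    world <- need("world", "classify")
    seq_taxids <- stats::setNames(world$sequences$taxid, world$sequences$seq_id)
    res$edge_labels <- label_edges(world$tree, world$taxonomy, seq_taxids)
    res$classification <- classify_reads(
      placements, res$edge_labels, world$taxonomy,
      cutoff = cfg$classify_cutoff, compound_threshold = cfg$compound_threshold
    )
    utils::write.csv(res$classification,
                     file.path(cfg$out_dir, "classification.csv"),
                     row.names = FALSE)
    write_jplace(placements[placements$sample == placements$sample[1], ],
                 world$tree, file.path(cfg$out_dir, "sample1.jplace"))
  }

  if ("massmath" %in% stages) {
    log_stage("massmath")
    world <- need("world", "massmath")
    placements <- need("placements", "massmath")
    res$mass_maps <- mass_map_from_placements(placements, world$tree)
    samples <- sort(unique(res$mass_maps$sample))
    maps <- lapply(samples, function(s) res$mass_maps[res$mass_maps$sample == s, ])
    n <- length(samples)
    dm <- matrix(0, n, n, dimnames = list(samples, samples))
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        dm[i, j] <- dm[j, i] <- kr_distance(maps[[i]], maps[[j]], world$tree)
      }
    }
    res$kr_matrix <- dm
    utils::write.csv(dm, file.path(cfg$out_dir, "kr_distances.csv"))
    res$squash <- if (cfg$n_boot > 0) {
      squash_bootstrap(placements, world$tree, n_boot = cfg$n_boot,
                       seed = cfg$seed + 4)
    } else {
      squash_cluster(res$mass_maps, world$tree)
    }
    ape::write.tree(res$squash$tree, file.path(cfg$out_dir, "squash.nwk"))
    # island clustering targets the provisional (uncultivated) taxa, the
    # reads for which placement micro-structure is informative; capped so
    # the read-by-read path-distance matrix stays tractable
    prov <- world$taxonomy$taxid[world$taxonomy$provisional &
                                   world$taxonomy$rank == "species"]
    island_pl <- placements[placements$true_taxid %in% prov, ]
    if (nrow(island_pl) == 0) island_pl <- placements
    keep_reads <- unique(island_pl$read_id)
    if (length(keep_reads) > 1500) {
      keep_reads <- keep_reads[seq(1, length(keep_reads), length.out = 1500)]
      island_pl <- island_pl[island_pl$read_id %in% keep_reads, ]
    }
    res$islands <- island_cluster(
      island_pl, world$tree, cutoff = cfg$island_cutoff,
      classifications = res$classification
    )
    utils::write.csv(res$islands, file.path(cfg$out_dir, "islands.csv"),
                     row.names = FALSE)
  }

  if ("edgepca" %in% stages) {
    log_stage("edgepca")
    world <- need("world", "edgepca")
    mm <- need("mass_maps", "edgepca")
    res$edge_matrix <- edge_mass_matrix(mm, world$tree)
    res$edge_pca <- edge_pca(res$edge_matrix, n_components = 2)
    utils::write.csv(res$edge_pca$scores,
                     file.path(cfg$out_dir, "edgepca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(res$edge_pca$vectors,
                     file.path(cfg$out_dir, "edgepca_loadings.csv"),
                     row.names = FALSE)
  }

  if ("ecology" %in% stages) {
    log_stage("ecology")
    cohort <- need("cohort", "ecology")
    res$diversity <- diversity_table(cohort$counts)
    res$trimmed <- trim_taxa(cohort$counts, top_frac = cfg$top_frac)
    res$cooccurrence <- cooccurrence(res$trimmed)
    res$summaries <- community_summaries(cohort$counts, cohort$meta,
                                         bv_definition = "nugent")
    utils::write.csv(res$diversity, file.path(cfg$out_dir, "diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(res$cooccurrence$correlation,
                     file.path(cfg$out_dir, "cooccurrence.csv"))
    utils::write.csv(res$summaries$taxon_summary,
                     file.path(cfg$out_dir, "taxon_summary.csv"),
                     row.names = FALSE)
  }

  if ("assoc" %in% stages) {
    log_stage("assoc")
    cohort <- need("cohort", "assoc")
    res$lrt <- interaction_lrt(cohort$counts, cohort$meta,
                               bv_col = "bv_nugent")
    res$signs <- sign_association_table(cohort$counts, cohort$meta,
                                        alpha = cfg$enet_alpha,
                                        k_folds = cfg$enet_folds,
                                        seed = cfg$seed + 5)
    utils::write.csv(res$lrt, file.path(cfg$out_dir, "interaction_lrt.csv"),
                     row.names = FALSE)
    utils::write.csv(res$signs$membership,
                     file.path(cfg$out_dir, "sign_membership.csv"),
                     row.names = FALSE)
  }

  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(
    cfg[setdiff(names(cfg), c("effect"))],
    cfg_json, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  manifest <- list(
    package = "placemass",
    package_version = as.character(utils::packageVersion("placemass")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(cfg_json)),
    created = "see config; outputs are a pure function of it"
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
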