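#' Run the full small-RNA analysis pipeline on simulated data
#'
#' Config-driven orchestration of the package's stages on seeded synthetic
#' inputs: count simulation, ocm normalization, tissue-specificity
#' profiling, editing detection, strain differential expression, ping-pong
#' signature analysis and piRNA cluster calling. Each selected stage writes
#' its primary output as TSV/BED under `outdir`; a `manifest.yaml` records
#' the resolved parameters, package version and seed so that reruns with an
#' equal manifest (minus timestamp) are byte-identical.
#'
#' @param config a named list or path to a YAML file. Recognized fields:
#'   `seed` (integer, default 1), `stages` (character subset of
#'   `counts`, `profile`, `editing`, `de`, `pingpong`, `clusters`; default
#'   all), and per-stage parameter blocks (`counts`, `editing`, `pingpong`,
#'   `clusters`) overriding simulator defaults.
#' @param outdir output directory (created if needed).
#' @param dry_run if `TRUE`, print the stage plan and write nothing.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), outdir = "srnatlas_out",
                         dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  all_stages <- c("counts", "profile", "editing", "de", "pingpong",
                  "clusters")
  stages <- if (is.null(config$stages)) all_stages
            else match.arg(config$stages, all_stages, several.ok = TRUE)
  if ("profile" %in% stages || "de" %in% stages)
    stages <- union(stages, "counts")
  stages <- all_stages[all_stages %in% stages]
  if (dry_run) {
    message("stage plan: ", paste(stages, collapse = " -> "))
    return(invisible(list(stages = stages, seed = seed)))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = "run_pipeline", seed = seed, stages = stages,
                   version = as.character(utils::packageVersion("srnatlas")),
                   parameters = config,
                   timestamp = format(Sys.time(), tz = "UTC"))
  norm <- NULL
  if ("counts" %in% stages) {
    args <- c(list(seed = seed), config$counts)
    sim <- do.call(simulate_counts, args)
    write_count_matrix(sim$counts, file.path(outdir, "counts.tsv"))
    norm <- ocm_normalize(sim$counts)
    write_count_matrix(norm, file.path(outdir, "norm.tsv"))
  }
  if ("profile" %in% stages) {
    calls <- rbind(call_specific(norm), call_avoidant(norm))
    utils::write.table(calls, file.path(outdir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_heatmap(mirna_tree(norm), file.path(outdir, "heatmap.tsv"))
    rho <- sample_correlation(norm)
    utils::write.table(round(rho, 6), file.path(outdir, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if ("editing" %in% stages) {
    args <- c(list(seed = seed + 1L), config$editing)
    if (is.null(args$sites))
      args$sites <- data.frame(precursor = "mirE1", position = 15,
                               rate = 0.37, stringsAsFactors = FALSE)
    sim <- do.call(simulate_editing_reads, args)
    sites <- scan_editing(sim$reads, sim$ann, sim$genome)
    write_editing(filter_edited(sites), file.path(outdir, "editing.tsv"))
  }
  if ("de" %in% stages) {
    de <- sliding_window_de(norm, tissue = "liver")
    utils::write.table(de, file.path(outdir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("pingpong" %in% stages) {
    args <- c(list(seed = seed + 2L), config$pingpong)
    sim <- do.call(simulate_pingpong_reads, args)
    prof <- overlap_histogram(sim$reads)
    ctl <- randomized_control(nchar(sim$region_sequence), prof$n_plus,
                              prof$n_minus, seed = seed + 3L)
    write_pingpong(prof, file.path(outdir, "pingpong.tsv"), control = ctl)
    utils::write.table(positional_content(sim$reads),
                       file.path(outdir, "positional.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("clusters" %in% stages) {
    args <- c(list(seed = seed + 4L), config$clusters)
    sim <- do.call(simulate_cluster_reads, args)
    cl <- call_pirna_clusters(sim$reads)
    cl$name <- sprintf("cluster%03d", seq_len(nrow(cl)))
    cl$score <- cl$n_unique_starts
    write_bed(cl, file.path(outdir, "clusters.bed"))
    merged <- merge_adjacent(cl)
    merged$name <- merged$orientation_class
    merged$score <- merged$n_unique_starts
    merged$strand <- "."
    write_bed(merged, file.path(outdir, "locations.bed"))
    summ <- cluster_characteristics(merged, genes = sim$genes,
                                    repeats = sim$repeats,
                                    conservation = sim$conservation,
                                    chrom_lengths = sim$chrom_lengths)
    utils::write.table(summ, file.path(outdir, "cluster_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
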