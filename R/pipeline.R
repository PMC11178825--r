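PIPELINE_STAGES <- c("simulate", "quantify", "window", "offtarget", "profile")

#' Default run configuration
#'
#' Returns the fully populated default configuration for [run_pipeline()],
#' a plain nested list that can also be written/read as YAML. All seeds are
#' explicit; there are no wall-clock defaults.
#'
#' @param seed master seed from which every stage seed is derived.
#' @param outdir output directory.
#' @return named list (see [run_pipeline()]).
#' @export
default_run_config <- function(seed = 1, outdir = "baseedit_run") {
  list(
    stages = PIPELINE_STAGES,
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(
      n_sites = 3, n_reads = 2000, amplicon_length = 250,
      editor = "dual", peak = 0.5,
      genome = list(n_chrom = 2, chrom_length = 20000),
      offtarget_mismatches = c(0, 1, 2, 3),
      cohort = list(n_plants = 4, mean_snvs = 50, mean_indels = 10)
    ),
    thresholds = list(
      max_mm = 3, pam_pattern = "NGG",
      het_threshold = 0.3, hom_threshold = 0.7,
      window_threshold = 0.5, min_identity = 0.6
    )
  )
}

#' Validate a run configuration
#'
#' Checks every threshold against its documented range and that seeds are
#' explicit, before any computation runs.
#'
#' @param config nested list (see [default_run_config()]), or a YAML path.
#' @return the normalized config, invisibly on success; errors otherwise.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- default_run_config()
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed) || !is_count(config$seed, min = 0))
    stop("config$seed must be an explicit non-negative integer")
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  th <- config$thresholds
  if (th$max_mm < 0 || th$max_mm > 6) stop("max_mm must lie in 0..6")
  for (f in c("het_threshold", "hom_threshold", "window_threshold",
              "min_identity")) {
    if (!is.numeric(th[[f]]) || th[[f]] <= 0 || th[[f]] >= 1)
      stop(f, " must lie strictly between 0 and 1")
  }
  if (th$het_threshold >= th$hom_threshold)
    stop("het_threshold must be below hom_threshold")
  if (nchar(th$pam_pattern) != 3) stop("pam_pattern must have length 3")
  invisible(config)
}

derive_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 1000L + k

#' Run the full characterization pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' generated from the config seed: target-site simulation and read
#' generation, per-site quantification, editing-window aggregation,
#' off-target enumeration and SNV attribution, and plant-cohort variant
#' profiling. All stage outputs are written under `config$outdir` and listed
#' with md5 checksums in the returned manifest (also written as
#' `manifest.json`). Identical config and inputs produce identical
#' checksums.
#'
#' @param config nested list or YAML path; see [default_run_config()] and
#'   [validate_run_config()].
#' @return the run manifest, invisibly: inputs, package version, seeds,
#'   parameter values and per-file checksums.
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  sim <- config$simulate
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% config$stages]
  outputs <- character(0)
  add_out <- function(p) outputs <<- c(outputs, p)

  sites <- NULL; sims <- NULL; quants <- NULL
  genome <- NULL; registry <- NULL; cohort <- NULL

  if (any(c("simulate", "quantify", "window", "offtarget", "profile")
          %in% stages)) {
    # Simulation underpins every later stage of the synthetic run.
    profile <- preset_profile(sim$editor, peak = sim$peak)
    sites <- lapply(seq_len(sim$n_sites), function(i)
      make_target_site(derive_seed(config$seed, i),
                       amplicon_length = sim$amplicon_length,
                       pam_pattern = th$pam_pattern,
                       site_id = sprintf("site%02d", i)))
    sims <- lapply(seq_along(sites), function(i)
      simulate_amplicon_reads(sites[[i]], restrict_profile(profile, sites[[i]]),
                              sim$n_reads,
                              seed = derive_seed(config$seed, 100L + i)))
    g <- make_toy_genome(sim$genome$n_chrom, sim$genome$chrom_length,
                         seed = derive_seed(config$seed, 200L))
    mms <- sim$offtarget_mismatches
    placements <- data.frame(
      chrom = rep(names(g)[1], length(mms)),
      offset = 1000L + 200L * seq_along(mms),
      strand = rep(c("+", "-"), length.out = length(mms)),
      n_mismatches = mms)
    planted <- plant_candidate_sites(g, sites[[1]]$protospacer, placements,
                                     pam_pattern = th$pam_pattern,
                                     seed = derive_seed(config$seed, 201L))
    genome <- planted$genome; registry <- planted$registry
    registry$site_id <- sprintf("offtarget%02d", seq_len(nrow(registry)))
    # Plant one on-target style edit at a window position whose base admits
    # it (the first C or A among positions 4..8 of the planted sequence).
    edit_spec <- NULL
    wseq <- chars(substr(registry$planted_seq[1], 4, 8))
    wi <- which(wseq %in% c("C", "A"))
    if (length(wi) > 0) {
      pos <- 3L + wi[1]
      edit_spec <- data.frame(
        site_id = registry$site_id[1], chrom = registry$chrom[1],
        start = registry$start[1], strand = registry$strand[1],
        position = pos,
        conversion = if (wseq[wi[1]] == "C") "C>T" else "A>G",
        af = 0.85, stringsAsFactors = FALSE)
    }
    cohort <- simulate_plant_cohort(
      genome, edit_spec = edit_spec,
      background = list(mean_snvs = sim$cohort$mean_snvs,
                        mean_indels = sim$cohort$mean_indels),
      n_plants = sim$cohort$n_plants,
      seed = derive_seed(config$seed, 300L))
  }

  if ("simulate" %in% stages) {
    add_out(write_sites_tsv(sites, file.path(outdir, "target_sites.tsv")))
    for (i in seq_along(sims)) {
      add_out(write_reads_fastq(
        sims[[i]]$reads,
        file.path(outdir, sprintf("%s.fastq", sites[[i]]$site_id))))
    }
    add_out(write_genome_fasta(genome, file.path(outdir, "genome.fasta")))
    for (nm in names(cohort$plants)) {
      add_out(write_plant_vcf(cohort$plants[[nm]],
                              file.path(outdir, paste0(nm, ".vcf")),
                              genome = genome))
    }
    truth <- list(
      per_read = lapply(sims, function(s) s$truth$per_read),
      planted_sites = registry,
      cohort_truth = cohort$truth)
    p <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, p, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    add_out(p)
  }

  if (any(c("quantify", "window") %in% stages)) {
    quants <- lapply(seq_along(sites), function(i) {
      oc <- analyze_reads(sims[[i]]$reads, sites[[i]],
                          min_identity = th$min_identity)
      quantify_site(oc, sites[[i]])
    })
  }

  if ("quantify" %in% stages) {
    for (i in seq_along(quants)) {
      sid <- sites[[i]]$site_id
      p1 <- file.path(outdir, sprintf("%s_profile.tsv", sid))
      write.table(quants[[i]]$profile, p1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      add_out(p1)
      p2 <- file.path(outdir, sprintf("%s_alleles.tsv", sid))
      write.table(top_alleles(quants[[i]], k = 10), p2, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      add_out(p2)
    }
    p <- file.path(outdir, "site_summaries.json")
    jsonlite::write_json(lapply(quants, function(q) q$summary), p,
                         auto_unbox = TRUE, digits = NA)
    add_out(p)
  }

  if ("window" %in% stages) {
    ws <- aggregate_positions(lapply(quants, function(q) q$profile))
    p <- file.path(outdir, "window_summary.tsv")
    write.table(as.data.frame(ws), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_out(p)
    windows <- list()
    for (conv in c("C>T", "A>G")) {
      w <- tryCatch(infer_window(ws, conv, th$window_threshold),
                    error = function(e) NULL)
      if (!is.null(w))
        windows[[conv]] <- list(start = unname(w[1]), end = unname(w[2]))
    }
    p <- file.path(outdir, "windows.json")
    jsonlite::write_json(windows, p, auto_unbox = TRUE, digits = NA)
    add_out(p)
  }

  candidates <- NULL
  if (any(c("offtarget", "profile") %in% stages)) {
    candidates <- enumerate_sites(genome, sites[1], max_mm = th$max_mm,
                                  pam_pattern = th$pam_pattern)
  }

  if ("offtarget" %in% stages) {
    add_out(write_candidates_bed(candidates,
                                 file.path(outdir, "candidates.bed")))
    all_snvs <- do.call(rbind, lapply(cohort$plants, function(tb)
      tb[tb$type == "SNV", , drop = FALSE]))
    att <- attribute_snvs(all_snvs, candidates)
    p <- file.path(outdir, "attributions.tsv")
    write.table(att, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(p)
  }

  if ("profile" %in% stages) {
    counts <- per_plant_counts(cohort$plants)
    p <- file.path(outdir, "per_plant_counts.tsv")
    write.table(counts$per_plant, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_out(p)
    gf <- vapply(cohort$plants, function(tb)
      if (any(nchar(tb$ref) == 1 & nchar(tb$alt) == 1))
        germline_fraction(tb, th$het_threshold, th$hom_threshold)
      else NA_real_, numeric(1))
    gm <- on_target_genotype_matrix(
      cohort$plants, registry, conversion = "C>T",
      het_threshold = th$het_threshold, hom_threshold = th$hom_threshold)
    p <- file.path(outdir, "genotype_matrix.tsv")
    write.table(as.data.frame(gm), p, sep = "\t", quote = FALSE,
                row.names = TRUE, col.names = NA)
    add_out(p)
    all_snvs <- do.call(rbind, lapply(cohort$plants, function(tb)
      tb[tb$type == "SNV", , drop = FALSE]))
    motif <- tryCatch(motif_context(all_snvs, genome, "C>T"),
                      error = function(e) NULL)
    summary <- list(
      germline_fraction = as.list(gf),
      motif = if (is.null(motif)) NULL else list(
        freq = motif$freq, information = motif$information,
        n_used = motif$n_used, n_skipped = motif$n_skipped))
    p <- file.path(outdir, "profile_summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", na = "null")
    add_out(p)
    if (!is.null(motif)) {
      p <- file.path(outdir, "motif_matrix.tsv")
      write.table(cbind(position = 1:3, as.data.frame(motif$freq),
                        information = motif$information),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      add_out(p)
    }
  }

  manifest <- list(
    package = "baseedit",
    version = as.character(utils::packageVersion("baseedit")),
    seed = config$seed,
    stages = stages,
    parameters = config[c("simulate", "thresholds")],
    outputs = lapply(outputs, function(p) list(
      path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
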