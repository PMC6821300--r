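## One-config orchestration: simulate -> cluster -> dstat -> kaks, with a
## machine-readable run report. Configuration is a flat YAML key-value
## document; one master seed derives per-stage substreams, so identical
## (config, seed) reruns give identical result tables.

.configDefaults <- function() {
  list(
    stages = c("simulate", "cluster", "dstat", "kaks"),
    out_dir = "retinet-run",
    taxa = c("sara", "hortense", "erato", "doris", "cydno", "melpomene",
             "hecale", "iulia"),
    outgroup = "iulia",
    quartets = list(c("sara", "hortense", "erato", "iulia")),
    n_loci = 40L,
    sites_per_locus = 900L,
    gamma = 0.1,
    t_internal = log(2),
    mut_rate = 0.02,
    omega_selected = 5,
    frac_selected = 0.05,
    n_chrom_per_pop = 10L,
    window_size = 50000L,
    n_windows = 40L,
    min_score = 30,
    min_fragment = 100L,
    max_ks = 2.0,
    alpha = 0.05,
    q = 0.01,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Reads a flat YAML key-value document (or takes a named list), fills
#' defaults, type-checks every field and rejects unknown keys. The taxa
#' list must contain exactly one outgroup (the `outgroup` entry, present in
#' `taxa`); all quartet labels must be taxa.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return a fully defaulted, validated configuration (class
#'   `"PipelineConfig"`).
#' @examples
#' cfg <- validateConfig(list(n_loci = 10, seed = 42))
#' cfg$window_size
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a named list")
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  if (is.character(cfg$quartets)) cfg$quartets <- list(cfg$quartets)
  cfg$quartets <- lapply(cfg$quartets, function(q) {
    if (length(q) == 1L) strsplit(q, ",")[[1]] else as.character(q)
  })
  if (length(cfg$taxa) != 8L) stop("config error: 'taxa' must list 8 labels")
  if (anyDuplicated(cfg$taxa)) stop("config error: duplicate taxa")
  if (length(cfg$outgroup) != 1L || !cfg$outgroup %in% cfg$taxa)
    stop("config error: exactly one outgroup, present in 'taxa', is required")
  for (q in cfg$quartets) {
    if (length(q) != 4L || !all(q %in% cfg$taxa))
      stop("config error: quartet (", paste(q, collapse = ","),
           ") must name 4 taxa")
  }
  if (cfg$window_size <= 0) stop("config error: nonpositive window_size")
  if (cfg$q <= 0 || cfg$q >= 1) stop("config error: q must be in (0, 1)")
  badStage <- setdiff(cfg$stages, c("simulate", "cluster", "dstat", "kaks"))
  if (length(badStage))
    stop("config error: unknown stage(s): ", paste(badStage, collapse = ", "))
  cfg$n_loci <- as.integer(cfg$n_loci)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "PipelineConfig")
}

# atomic table write: .partial until complete
.writeTable <- function(df, path) {
  tmp <- paste0(path, ".partial")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.simConfigFromPipeline <- function(cfg) {
  simulationConfig(
    nLoci = cfg$n_loci, sitesPerLocus = cfg$sites_per_locus,
    taxa = cfg$taxa, quartet = cfg$quartets[[1]],
    gamma = cfg$gamma, tInternal = cfg$t_internal, mutRate = cfg$mut_rate,
    omegaSelected = cfg$omega_selected, fracSelected = cfg$frac_selected,
    nChromPerPop = cfg$n_chrom_per_pop, windowSize = cfg$window_size,
    seed = cfg$seed)
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes the enabled stages in dependency order: `simulate` (cluster
#' alignments, locus truth, SNP frequency table), `cluster` (RBH clique
#' recovery from the per-species CDS sets), `dstat` (quartet suite over
#' clusters plus the windowed frequency scan) and `kaks` (pairwise screen,
#' candidate filter, branch-site plan). All outputs are tab-separated
#' tables, FASTA or JSON under `config$out_dir`; a failed stage aborts with
#' its name, leaving `.partial` files behind.
#'
#' @param config a `"PipelineConfig"` from [validateConfig()], a named list
#'   of overrides, or a YAML path.
#' @return a run report (list): per-stage row counts, dropped-data
#'   counters, output paths and the config echo. Written to
#'   `out_dir/report.json` as well.
#' @export
runPipeline <- function(config = list()) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), stages = list())
  t0 <- proc.time()[["elapsed"]]
  simCfg <- .simConfigFromPipeline(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  sim <- NULL
  if ("simulate" %in% cfg$stages) {
    sim <- stage("simulate", {
      s <- simulateClusterAlignments(simCfg)
      wf <- simulateWindowFrequencies(simCfg, nWindows = cfg$n_windows)
      writeClusterFasta(s$alignments, file.path(cfg$out_dir, "clusters"))
      writeTruthTable(s$truth, file.path(cfg$out_dir, "locus_truth.tsv"))
      writeSnpTable(wf$snps, file.path(cfg$out_dir, "snp_frequencies.tsv"))
      writeTruthTable(wf$truth, file.path(cfg$out_dir, "window_truth.tsv"))
      list(alignments = s$alignments, truth = s$truth, snps = wf$snps)
    })
    report$stages$simulate <- list(
      n_clusters = length(sim$alignments),
      n_snp_rows = nrow(sim$snps))
  }
  if ("cluster" %in% cfg$stages) {
    membership <- stage("cluster", {
      sets <- lapply(cfg$taxa, function(sp) {
        s <- vapply(sim$alignments, function(a)
          as.character(a[[match(sp, names(a))]]), "")
        names(s) <- sprintf("%s_%s", sp, names(sim$alignments))
        s
      })
      names(sets) <- cfg$taxa
      m <- buildClusters(sets, minScore = cfg$min_score)
      .writeTable(m, file.path(cfg$out_dir, "cluster_membership.tsv"))
      m
    })
    report$stages$cluster <- list(
      n_clusters = length(unique(membership$cluster_id)),
      n_members = nrow(membership))
  }
  if ("dstat" %in% cfg$stages) {
    dres <- stage("dstat", {
      suite <- runDSuite(sim$alignments, cfg$quartets)
      .writeTable(suite, file.path(cfg$out_dir, "d_suite.tsv"))
      wd <- windowedD(sim$snps, cfg$quartets[[1]], cfg$window_size)
      .writeTable(wd$windows, file.path(cfg$out_dir, "d_windows.tsv"))
      chrom <- do.call(rbind, lapply(wd$chromosomes, as.data.frame))
      chrom <- cbind(chrom = names(wd$chromosomes), chrom)
      .writeTable(chrom, file.path(cfg$out_dir, "d_chromosomes.tsv"))
      list(suite = suite, windows = wd$windows)
    })
    report$stages$dstat <- list(
      n_quartets = nrow(dres$suite),
      n_windows = nrow(dres$windows))
  }
  if ("kaks" %in% cfg$stages) {
    sel <- stage("kaks", {
      tab <- do.call(rbind, lapply(names(sim$alignments), function(id)
        clusterKaKs(sim$alignments[[id]], id,
                    minFragment = cfg$min_fragment)))
      scr <- screenCandidates(tab, minFragment = cfg$min_fragment,
                              maxKs = cfg$max_ks)
      .writeTable(scr$table, file.path(cfg$out_dir, "kaks.tsv"))
      .writeTable(scr$candidates, file.path(cfg$out_dir, "candidates.tsv"))
      plan <- enumerateBranchTests(scr$clusters)
      .writeTable(plan, file.path(cfg$out_dir, "branch_site_plan.tsv"))
      list(table = scr$table, candidates = scr$candidates, plan = plan)
    })
    report$stages$kaks <- list(
      n_pairwise = nrow(sel$table),
      n_candidates = nrow(sel$candidates),
      n_candidate_clusters = length(unique(sel$candidates$cluster_id)),
      n_planned_tests = nrow(sel$plan))
  }
  report$elapsed_seconds <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
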