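#' Pipeline configuration
#'
#' Bundles per-stage parameters, the output directory and the single seed
#' that governs every stochastic stage.  Parameter blocks may be given as
#' plain lists (e.g. from YAML); they are passed to the corresponding
#' constructors so invariants are validated once, up front.
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @param sim [sim_config()] or list of its arguments.
#' @param search [search_params()] or list.
#' @param derep [derep_params()] or list.
#' @param rule [rule_thresholds()] or list.
#' @param ml list: `algorithm` (default `"softmax"`), `n_per_group`
#'   (training genomes per group, default 10).
#' @param ordination list: `k`, `n_restarts`.
#' @param permanova list: `n_perm`.
#' @param etfb list: `margin_min`, `n_per_label`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, sim = list(), search = list(),
                            derep = list(), rule = list(), ml = list(),
                            ordination = list(), permanova = list(),
                            etfb = list()) {
  as_block <- function(x, ctor, seed_arg = FALSE) {
    if (inherits(x, "list") || is.null(x)) {
      x <- x %||% list()
      if (seed_arg && is.null(x$seed)) x$seed <- seed
      do.call(ctor, x)
    } else x
  }
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    sim = as_block(sim, sim_config, seed_arg = TRUE),
    search = as_block(search, search_params),
    derep = as_block(derep, derep_params),
    rule = as_block(rule, rule_thresholds),
    ml = utils::modifyList(list(algorithm = "softmax", n_per_group = 10),
                           ml),
    ordination = utils::modifyList(list(k = 2, n_restarts = 10), ordination),
    permanova = utils::modifyList(list(n_perm = 999), permanova),
    etfb = utils::modifyList(list(margin_min = 0.10, n_per_label = 3), etfb)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @param overrides optional named list applied on top (dotted keys, e.g.
#'   `list("sim.n_genomes_per_group" = 4)`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) y[[parts]] <- overrides[[key]]
    else y[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  do.call(pipeline_config, y)
}

.path <- function(cfg, ...) file.path(cfg$outdir, ...)

stage_simulate <- function(cfg) {
  indir <- .path(cfg, "inputs")
  dir.create(file.path(indir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  catalog <- make_pathway_catalog(seed = cfg$seed)
  write_catalog(catalog, file.path(indir, "catalog"))
  cohort <- simulate_cohort(catalog, cfg$sim, seed = cfg$seed)
  write_genomes(cohort$genomes, file.path(indir, "genomes"))
  write_tsv(cohort$quality, file.path(indir, "quality.tsv"))
  truth <- lapply(cohort$truths, function(t)
    list(true_group = t$true_group, embedded_genes = t$embedded_genes))
  write_json(truth, file.path(indir, "truth.json"))
  tab <- simulate_abundance(names(cohort$genomes), cfg$sim,
                            seed = sub_seed(cfg$seed, 1))
  write_abundance(tab, file.path(indir, "abundance.tsv"),
                  file.path(indir, "metadata.tsv"))
  refs <- simulate_etfb_references(catalog, seed = sub_seed(cfg$seed, 2),
                                   n_per_label = cfg$etfb$n_per_label)
  write_etfb_references(refs, file.path(indir, "etfb_references.faa"))
  length(cohort$genomes)
}

stage_dereplicate <- function(cfg) {
  indir <- .path(cfg, "inputs")
  quality <- read_tsv(file.path(indir, "quality.tsv"))
  genomes <- read_genomes(file.path(indir, "genomes"), quality)
  clusters <- dereplicate(genomes, quality, cfg$derep)
  dir.create(.path(cfg, "derep"), showWarnings = FALSE)
  write_tsv(clusters, .path(cfg, "derep", "clusters.tsv"))
  nrow(clusters)
}

stage_search <- function(cfg) {
  indir <- .path(cfg, "inputs")
  catalog <- read_catalog(file.path(indir, "catalog"))
  quality <- read_tsv(file.path(indir, "quality.tsv"))
  genomes <- read_genomes(file.path(indir, "genomes"), quality)
  clusters <- read_tsv(.path(cfg, "derep", "clusters.tsv"))
  reps <- clusters$genome_id[clusters$is_representative]
  hits <- search_cohort(catalog, genomes[reps], cfg$search)
  dir.create(.path(cfg, "search"), showWarnings = FALSE)
  write_tsv(hits, .path(cfg, "search", "hits.tsv"))
  nrow(hits)
}

stage_profile <- function(cfg) {
  indir <- .path(cfg, "inputs")
  catalog <- read_catalog(file.path(indir, "catalog"))
  clusters <- read_tsv(.path(cfg, "derep", "clusters.tsv"))
  reps <- sort(clusters$genome_id[clusters$is_representative])
  hits <- read_tsv(.path(cfg, "search", "hits.tsv"))
  profiles <- build_profiles(hits, catalog, genome_ids = reps)
  m <- profile_matrix(profiles)
  dir.create(.path(cfg, "profile"), showWarnings = FALSE)
  write_tsv(data.frame(genome_id = rownames(m), m, check.names = FALSE),
            .path(cfg, "profile", "profiles.tsv"))
  pct <- m[, startsWith(colnames(m), "pct_"), drop = FALSE]
  cl <- hierarchical_cluster(pct)
  writeLines(cl$newick, .path(cfg, "profile", "dendrogram.nwk"))
  nrow(m)
}

stage_abundance <- function(cfg) {
  indir <- .path(cfg, "inputs")
  tab <- read_abundance(file.path(indir, "abundance.tsv"),
                        file.path(indir, "metadata.tsv"))
  pf <- presence_and_filter(tab)
  dir.create(.path(cfg, "abundance"), showWarnings = FALSE)
  write_tsv(pf$summary, .path(cfg, "abundance", "summary.tsv"))
  writeLines(sort(pf$high_abundance),
             .path(cfg, "abundance", "high_abundance.txt"))
  length(pf$high_abundance)
}

stage_ordinate <- function(cfg) {
  indir <- .path(cfg, "inputs")
  tab <- read_abundance(file.path(indir, "abundance.tsv"),
                        file.path(indir, "metadata.tsv"))
  d <- bray_curtis_dist(tab)
  ord <- nmds(d, k = cfg$ordination$k,
              n_restarts = cfg$ordination$n_restarts,
              seed = sub_seed(cfg$seed, 3))
  dir.create(.path(cfg, "ordination"), showWarnings = FALSE)
  coords <- data.frame(sample_id = rownames(ord$points), ord$points)
  names(coords)[-1] <- paste0("NMDS", seq_len(cfg$ordination$k))
  write_tsv(coords, .path(cfg, "ordination", "nmds_coords.tsv"))
  # the omnibus and pairwise tests run on Euclidean distances of the
  # abundance profiles; the ordination above stays on Bray-Curtis
  de <- dist(t(tab$abund))
  pm <- permanova(de, tab$metadata$experiment,
                  n_perm = cfg$permanova$n_perm,
                  seed = sub_seed(cfg$seed, 4))
  pw <- pairwise_permanova_bh(de, tab$metadata$experiment,
                              n_perm = cfg$permanova$n_perm,
                              seed = sub_seed(cfg$seed, 5))
  write_json(list(stress = ord$stress, pseudo_F = pm$pseudo_F,
                  p_value = pm$p_value, pairwise = pw),
             .path(cfg, "ordination", "stats.json"))
  nrow(coords)
}

.rule_calls_from_matrix <- function(m, thresholds) {
  pct <- m[, startsWith(colnames(m), "pct_"), drop = FALSE]
  colnames(pct) <- sub("^pct_", "", colnames(pct))
  out <- do.call(rbind, lapply(rownames(pct), function(id) {
    v <- pct[id, ]
    attr(v, "genome_id") <- id
    rule_classify(v, thresholds)
  }))
  rownames(out) <- NULL
  out
}

stage_classify <- function(cfg) {
  indir <- .path(cfg, "inputs")
  catalog <- read_catalog(file.path(indir, "catalog"))
  prof_df <- read_tsv(.path(cfg, "profile", "profiles.tsv"))
  m <- as.matrix(prof_df[, -1, drop = FALSE])
  rownames(m) <- prof_df$genome_id
  high <- readLines(.path(cfg, "abundance", "high_abundance.txt"))
  high <- intersect(high, rownames(m))
  tab <- read_abundance(file.path(indir, "abundance.tsv"),
                        file.path(indir, "metadata.tsv"))

  # independent labeled training cohort at the same study conditions
  tr_cfg <- cfg$sim
  tr_cfg$n_genomes_per_group <- cfg$ml$n_per_group
  tr <- simulate_cohort(catalog, tr_cfg, seed = sub_seed(cfg$seed, 6))
  tr_hits <- search_cohort(catalog, tr$genomes, cfg$search)
  tr_prof <- build_profiles(tr_hits, catalog,
                            genome_ids = names(tr$genomes))
  tr_m <- profile_matrix(tr_prof)
  tr_y <- vapply(tr$truths, `[[`, character(1),
                 "true_group")[rownames(tr_m)]
  model <- train_classifier(tr_m, tr_y, algorithm = cfg$ml$algorithm,
                            seed = sub_seed(cfg$seed, 7))

  rule_calls <- .rule_calls_from_matrix(m, cfg$rule)
  ml <- classify_cohort(model, m, high, abundance = tab)
  dir.create(.path(cfg, "classify"), showWarnings = FALSE)
  calls <- rbind(rule_calls,
                 ml$calls[, c("genome_id", "group", "method")])
  write_tsv(calls, .path(cfg, "classify", "calls.tsv"))
  write_tsv(ml$calls, .path(cfg, "classify", "ml_calls.tsv"))
  if (!is.null(ml$by_experiment))
    write_tsv(ml$by_experiment, .path(cfg, "classify", "by_experiment.tsv"))
  venn <- compare_methods(rule_calls[rule_calls$genome_id %in% high, ],
                          ml$calls)
  write_json(list(group_counts = as.list(ml$group_counts),
                  venn = venn,
                  cv_logloss = model$report$cv_logloss,
                  baseline_logloss = model$report$baseline_logloss,
                  improvement_pct = model$report$improvement_pct),
             .path(cfg, "classify", "metrics.json"))
  nrow(calls)
}

stage_etfb <- function(cfg) {
  indir <- .path(cfg, "inputs")
  refs <- read_etfb_references(file.path(indir, "etfb_references.faa"))
  quality <- read_tsv(file.path(indir, "quality.tsv"))
  genomes <- read_genomes(file.path(indir, "genomes"), quality)
  clusters <- read_tsv(.path(cfg, "derep", "clusters.tsv"))
  reps <- clusters$genome_id[clusters$is_representative]
  calls <- etfb_calls(genomes[reps], refs,
                      margin_min = cfg$etfb$margin_min,
                      params = cfg$search)
  fn <- read_tsv(.path(cfg, "classify", "calls.tsv"))
  fn <- fn[fn$method == "rule", ]
  summ <- summarize_etfb(calls, fn)
  dir.create(.path(cfg, "etfb"), showWarnings = FALSE)
  write_tsv(calls, .path(cfg, "etfb", "etfb_calls.tsv"))
  write_tsv(summ$table, .path(cfg, "etfb", "etfb_summary.tsv"))
  write_json(list(n_both = summ$n_both), .path(cfg, "etfb", "etfb_stats.json"))
  nrow(calls)
}

.pipeline_stages <- c("dereplicate", "search", "profile", "abundance",
                      "ordinate", "classify", "etfb")

#' Run the full pipeline
#'
#' Generates the synthetic inputs (unless they already exist and
#' `resimulate = FALSE`), then executes the seven analysis stages in
#' order: dereplicate, search, profile, abundance, ordinate, classify,
#' etfb.  Every stage reads its inputs from and writes its outputs under
#' `config$outdir`, so individual stages can be re-run.  A manifest JSON
#' records the seed, per-stage row counts and MD5 digests of every
#' output; the run is fully deterministic, so re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()] object.
#' @param resimulate regenerate inputs even if present (default TRUE).
#' @return Invisibly, the manifest (also written to
#'   `outdir/manifest.json`).  A stage failure stops with the stage
#'   named.
#' @export
run_all <- function(config, resimulate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  n_genomes <- if (resimulate ||
                   !file.exists(.path(config, "inputs", "quality.tsv"))) {
    message("preparing synthetic inputs")
    stage_simulate(config)
  } else {
    nrow(read_tsv(.path(config, "inputs", "quality.tsv")))
  }

  stage_fns <- list(dereplicate = stage_dereplicate, search = stage_search,
                    profile = stage_profile, abundance = stage_abundance,
                    ordinate = stage_ordinate, classify = stage_classify,
                    etfb = stage_etfb)
  stages <- list()
  for (nm in .pipeline_stages) {
    message("stage ", nm)
    n <- tryCatch(stage_fns[[nm]](config), error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[nm]] <- list(status = "completed", n_rows = n)
  }

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  digests <- as.list(tools::md5sum(files))
  names(digests) <- sub(paste0("^", config$outdir, "/?"), "",
                        names(digests))
  manifest <- list(package = "magce",
                   version = as.character(utils::packageVersion("magce")),
                   seed = config$seed,
                   inputs = list(n_genomes = n_genomes),
                   stages = stages, digests = digests)
  write_json(manifest, .path(config, "manifest.json"))
  invisible(manifest)
}
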