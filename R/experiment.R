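#' Deterministic seed derivation
#'
#' Derives a replicate-level seed from a master seed and a sequence of
#' labels (strings or integers) by a fixed multiplicative hash, so that
#' any replicate can be re-run in isolation and results never depend on
#' execution order. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master Master seed (integer).
#' @param ... Labels: treatment names, replicate indices, stage names.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (tok in list(...)) {
    codes <- if (is.character(tok)) utf8ToInt(tok) else as.numeric(tok)
    for (c in codes) h <- (h * 131 + c + 7) %% m
  }
  as.integer(max(1, h %% (m - 1)))
}

#' Experiment manifest
#'
#' A reproducible description of one experiment: name, landscape config,
#' per-treatment evolution settings, replicate count and master seed.
#' Round-trips through YAML unchanged via [write_manifest()] /
#' [read_manifest()].
#'
#' @param experiment One of `"adaptation"` (small vs large population
#'   sizes), `"no_deleterious"` (small populations with deleterious
#'   mutations reverted), `"drift_test"` (drift-robustness assay of
#'   supplied genotypes), `"markov_sweep"` (critical-size table).
#' @param landscape_config A [landscape_config()] (ignored by
#'   `markov_sweep`).
#' @param n_replicates Replicates per treatment (default 30).
#' @param N_small,N_large Treatment population sizes (defaults 100, 2000).
#' @param generations Adaptation run length (default 20000).
#' @param U Genomic mutation rate (default 0.1).
#' @param drift_replicates,drift_N,drift_generations Drift-test settings
#'   (defaults 10, 50, 1000).
#' @param sweep Named list for `markov_sweep` (arguments to
#'   [ncrit_sweep()]).
#' @param master_seed Master seed for [derive_seed()].
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(experiment = c("adaptation", "no_deleterious",
                                               "drift_test", "markov_sweep"),
                                landscape_config = driftscape::landscape_config(),
                                n_replicates = 30L, N_small = 100L,
                                N_large = 2000L, generations = 20000L,
                                U = 0.1, drift_replicates = 10L, drift_N = 50L,
                                drift_generations = 1000L, sweep = list(),
                                master_seed = 1L) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, landscape_config = landscape_config,
                 n_replicates = as.integer(n_replicates),
                 N_small = as.integer(N_small), N_large = as.integer(N_large),
                 generations = as.integer(generations), U = U,
                 drift_replicates = as.integer(drift_replicates),
                 drift_N = as.integer(drift_N),
                 drift_generations = as.integer(drift_generations),
                 sweep = sweep, master_seed = as.integer(master_seed)),
            class = "experiment_manifest")
}

#' @rdname experiment_manifest
#' @param manifest An `experiment_manifest`.
#' @param file Path of the YAML file.
#' @export
write_manifest <- function(manifest, file) {
  x <- unclass(manifest)
  lc <- unclass(x$landscape_config)
  # named vectors must become maps to keep their names in YAML
  lc$fractions <- as.list(lc$fractions)
  lc$additive_state_counts <- as.list(lc$additive_state_counts)
  x$landscape_config <- lc
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname experiment_manifest
#' @export
read_manifest <- function(file) {
  x <- yaml::read_yaml(file)
  lc <- x$landscape_config
  x$landscape_config <- landscape_config(
    preset = lc$preset, L = lc$L, A = lc$A,
    fractions = unlist(lc$fractions),
    additive_ben_range = as.numeric(lc$additive_ben_range),
    additive_del_range = as.numeric(lc$additive_del_range),
    additive_del_large_range = as.numeric(lc$additive_del_large_range),
    additive_state_counts = unlist(lc$additive_state_counts),
    module_size = lc$module_size,
    module_benefit_range = as.numeric(lc$module_benefit_range),
    member_del_range = as.numeric(lc$member_del_range),
    modifier_benefit = lc$modifier_benefit,
    targets_per_modifier = lc$targets_per_modifier, seed = lc$seed)
  do.call(experiment_manifest, x)
}

#' Stable short hash of a manifest
#'
#' @param manifest An `experiment_manifest`.
#' @return Character hash carried in every output table.
#' @export
manifest_hash <- function(manifest) {
  ser <- paste(utils::capture.output(utils::str(unclass(manifest), digits.d = 15)),
               collapse = "\n")
  sprintf("%08x", derive_seed(0, ser))
}

#' Run an experiment end to end
#'
#' Executes the named experiment across replicates, derives per-replicate
#' seeds from the master seed, runs the analysis stage, and (optionally)
#' writes result tables. Replicate failures are caught and recorded; the
#' run continues.
#'
#' For `"adaptation"` and `"no_deleterious"`: evolves replicate
#' populations on the generated landscape, extracts each population's most
#' abundant genotype and its line of descent, and summarises each
#' genotype's DFE. For `"drift_test"`: runs the drift-robustness assay on
#' supplied genotypes. For `"markov_sweep"`: tabulates critical population
#' sizes.
#'
#' @param manifest An [experiment_manifest()].
#' @param genotypes For `"drift_test"`: a data frame-like list with
#'   elements `genome` (list of genomes), `label` and `replicate`.
#' @param out_dir Optional output directory for TSV tables.
#' @param quiet Suppress progress messages.
#' @return A list of class `experiment_result` with per-experiment tables,
#'   the manifest, its hash, lines of descent (`lods`), and `failures`.
#' @export
run_experiment <- function(manifest, genotypes = NULL, out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  hash <- manifest_hash(manifest)
  res <- switch(manifest$experiment,
    adaptation = run_adaptation(manifest,
      treatments = list(small = list(N = manifest$N_small, revert = FALSE),
                        large = list(N = manifest$N_large, revert = FALSE)),
      quiet = quiet),
    no_deleterious = run_adaptation(manifest,
      treatments = list(no_deleterious = list(N = manifest$N_small, revert = TRUE)),
      quiet = quiet),
    drift_test = run_drift_test(manifest, genotypes, quiet = quiet),
    markov_sweep = list(tables = list(ncrit = do.call(ncrit_sweep, manifest$sweep)),
                        lods = NULL, failures = NULL))
  res$manifest <- manifest
  res$hash <- hash
  class(res) <- "experiment_result"
  if (!is.null(out_dir)) write_experiment_tsv(res, out_dir)
  res
}

run_adaptation <- function(manifest, treatments, quiet = FALSE) {
  landscape <- generate_landscape(manifest$landscape_config)
  ancestor <- landscape$wild
  w_anc <- fitness_of(landscape, ancestor)
  rows <- list(); lods <- list(); genomes <- list(); failures <- list()
  for (tr in names(treatments)) {
    for (r in seq_len(manifest$n_replicates)) {
      key <- paste(tr, r, sep = "_")
      out <- tryCatch({
        cfg <- evolution_config(landscape, N = treatments[[tr]]$N,
                                generations = manifest$generations,
                                U = manifest$U,
                                revert_deleterious = treatments[[tr]]$revert,
                                ancestor = ancestor,
                                seed = derive_seed(manifest$master_seed, tr, r))
        run <- evolve_population(cfg)
        mab <- most_abundant_genotype(run)
        lod <- extract_lod(run, mab)
        sm <- dfe_summary(landscape, mab, label = tr, id = key)
        sm$replicate <- r
        sm$treatment <- tr
        sm$relative_fitness <- mab$fitness / w_anc
        sm$lod_length <- nrow(lod)
        list(sm = sm, lod = lod, genome = mab$genome)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        failures[[key]] <- conditionMessage(out)
        if (!quiet) message("replicate ", key, " failed: ", conditionMessage(out))
      } else {
        rows[[key]] <- out$sm
        lods[[key]] <- out$lod
        genomes[[key]] <- out$genome
      }
      if (!quiet && r %% 10 == 0)
        message(sprintf("[%s] %s replicate %d/%d done", manifest$experiment, tr, r,
                        manifest$n_replicates))
    }
  }
  list(tables = list(genotypes = do.call(rbind, rows)),
       lods = lods, genomes = genomes, landscape = landscape,
       failures = failures)
}

run_drift_test <- function(manifest, genotypes, quiet = FALSE) {
  if (is.null(genotypes))
    stop("drift_test requires 'genotypes' (genome list with labels)")
  landscape <- generate_landscape(manifest$landscape_config)
  rows <- list(); failures <- list()
  for (i in seq_along(genotypes$genome)) {
    key <- if (!is.null(names(genotypes$genome))) names(genotypes$genome)[i] else as.character(i)
    out <- tryCatch({
      rel <- drift_robustness_assay(genotypes$genome[[i]], landscape,
                                    replicates = manifest$drift_replicates,
                                    N_test = manifest$drift_N,
                                    generations_test = manifest$drift_generations,
                                    U = manifest$U,
                                    seed = derive_seed(manifest$master_seed,
                                                       "drift_test", key))
      data.frame(genotype = key,
                 label = genotypes$label[i],
                 replicate = seq_along(rel),
                 relative_fitness = rel)
    }, error = function(e) e)
    if (inherits(out, "error")) failures[[key]] <- conditionMessage(out)
    else rows[[key]] <- out
    if (!quiet && i %% 10 == 0)
      message(sprintf("[drift_test] genotype %d/%d done", i, length(genotypes$genome)))
  }
  list(tables = list(drift = do.call(rbind, rows)), lods = NULL,
       failures = failures)
}

#' Write experiment tables as TSV
#'
#' Every table carries the manifest hash as a comment header, so a table
#' can always be traced to the exact manifest (and hence seeds) that
#' produced it.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_experiment_tsv <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(result$tables)) {
    tab <- result$tables[[nm]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(result$manifest$experiment, "_", nm, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# manifest_hash: ", result$hash), con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment '%s' (manifest %s)\n", x$manifest$experiment, x$hash))
  for (nm in names(x$tables))
    cat(sprintf("  table '%s': %d rows\n", nm, nrow(x$tables[[nm]])))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
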