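# End-to-end orchestration of the synthetic demonstration pipeline:
# simulate -> search/ortholog -> validate -> profile -> enrich -> patterns,
# with a JSON manifest recording inputs, parameters, seeds and output
# digests so a rerun with the same configuration is verifiably identical.

#' Pipeline configuration
#'
#' @param seed Master seed, recorded in the manifest and propagated to
#'   every stage.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param orthology An [orthology_params()]. The default relaxes the
#'   reciprocal cutoff to the forward cutoff because synthetic sequences of
#'   a few hundred residues cannot reach e-values near 1e-200.
#' @param validation A [validation_params()].
#' @param n_organisms,branch_length Shape of the toy taxonomy.
#' @param k Number of profile clusters.
#' @param enrich_fdr FDR cutoff for term retention.
#' @param pattern_fdr,pattern_n_perm Pattern-detection settings.
#' @param stages Character vector of stage toggles, any of
#'   `c("simulate", "ortholog", "profile", "enrich", "patterns")`.
#' @param proteome_dir Optional directory of existing per-organism FASTA
#'   files (used when `"simulate"` is toggled off; file stem = organism).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(),
                            orthology = orthology_params(
                              reciprocal_evalue_max = 1e-5),
                            validation = validation_params(),
                            n_organisms = 8L, branch_length = 0.3,
                            k = 3L, enrich_fdr = 0.01,
                            pattern_fdr = 0.01, pattern_n_perm = 2999L,
                            stages = c("simulate", "ortholog", "profile",
                                       "enrich", "patterns"),
                            proteome_dir = NULL) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, orthology = orthology,
                 validation = validation,
                 n_organisms = as.integer(n_organisms),
                 branch_length = branch_length, k = as.integer(k),
                 enrich_fdr = enrich_fdr, pattern_fdr = pattern_fdr,
                 pattern_n_perm = as.integer(pattern_n_perm),
                 stages = stages, proteome_dir = proteome_dir),
            class = "pipeline_config")
}

.log_stage <- function(...) message(sprintf(...))

#' Run the synthetic demonstration pipeline
#'
#' Executes the toggled stages in order, writing stage outputs (FASTA,
#' TSV, JSON) under `out_dir` and finally a `manifest.json` listing the
#' configuration, the seed, per-stage status, and an md5 digest of every
#' output file. Rerunning with an identical configuration reproduces the
#' digests byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stages_done <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  tax <- toy_taxonomy(config$n_organisms, config$branch_length)
  write_taxonomy(tax, file.path(out_dir, "taxonomy.nwk"))
  emit(file.path(out_dir, "taxonomy.nwk"))

  sim <- NULL
  proteomes <- NULL
  if ("simulate" %in% config$stages) {
    .log_stage("stage simulate: %d families on %d organisms",
               config$sim$n_families, config$n_organisms)
    sim <- simulate_proteomes(tax, config$sim)
    proteomes <- sim$proteomes
    emit(write_proteomes(sim, file.path(out_dir, "proteomes")))
    jsonlite::write_json(sim$truth[c("co_ortholog_events", "pore_regions",
                                     "events")],
                         file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    emit(file.path(out_dir, "truth.json"))
    stages_done <- c(stages_done, "simulate")
  } else {
    if (is.null(config$proteome_dir) || !dir.exists(config$proteome_dir))
      stopf("stage ortholog: proteome directory not found: %s",
            config$proteome_dir %||% "<unset>")
    files <- list.files(config$proteome_dir, pattern = "\\.fasta$",
                        full.names = TRUE)
    proteomes <- lapply(files, Biostrings::readAAStringSet)
    names(proteomes) <- sub("\\.fasta$", "", basename(files))
  }

  pairs <- NULL
  queries <- NULL
  if ("ortholog" %in% config$stages) {
    queries <- proteomes[["human"]]
    if (is.null(queries) || !length(queries))
      stopf("stage ortholog: no 'human' query proteome available")
    targets <- proteomes[names(proteomes) != "human"]
    pr <- if (!is.null(sim)) sim$truth$pore_regions else NULL
    query_domains <- if (!is.null(pr))
      data.frame(accession = names(queries),
                 start = pr$start[match(names(queries), pr$gene)],
                 end = pr$end[match(names(queries), pr$gene)],
                 stringsAsFactors = FALSE)
    else data.frame(accession = names(queries), start = 1L,
                    end = Biostrings::width(queries),
                    stringsAsFactors = FALSE)
    target_ids <- unlist(lapply(targets, names), use.names = FALSE)
    target_seqs <- unlist(lapply(targets, as.character), use.names = FALSE)
    metadata <- make_metadata(target_ids, target_seqs)
    .log_stage("stage ortholog: %d queries vs %d organisms",
               length(queries), length(targets))
    res <- run_orthology(queries, query_domains, targets,
                         params = config$orthology, metadata = metadata,
                         vparams = config$validation)
    pairs <- res$pairs
    emit(write_ortholog_pairs(pairs, file.path(out_dir, "orthologs.tsv")))
    emit(write_ortholog_pairs(res$dropped,
                              file.path(out_dir, "drop_ledger.tsv")))
    stages_done <- c(stages_done, "ortholog")
  }

  profile <- NULL
  clusters <- NULL
  if ("profile" %in% config$stages && !is.null(pairs)) {
    .log_stage("stage profile: clustering into k=%d", config$k)
    orgs <- setdiff(names(tax$lineage), "human")
    sub_lineage <- tax$lineage[orgs]
    profile <- build_profile_matrix(pairs, names(queries),
                                    structure(list(lineage = sub_lineage),
                                              class = "taxonomy"))
    emit(write_profile_matrix(profile, file.path(out_dir, "profile.tsv")))
    cl <- cluster_profiles(profile, k = min(config$k, nrow(profile)))
    clusters <- cl$assignments
    utils::write.table(
      data.frame(query = names(clusters), cluster = clusters),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit(file.path(out_dir, "clusters.tsv"))
    stages_done <- c(stages_done, "profile")
  }

  if ("enrich" %in% config$stages && !is.null(clusters)) {
    .log_stage("stage enrich: planted-term recovery")
    cl_list <- split(names(clusters), unname(clusters))
    terms <- simulate_term_annotations(cl_list, config$sim)
    res <- enrich_terms(cl_list, terms$term_map,
                        universe = names(clusters),
                        fdr_max = config$enrich_fdr)
    utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "enrichment.tsv"))
    stages_done <- c(stages_done, "enrich")
  }

  if ("patterns" %in% config$stages) {
    .log_stage("stage patterns: planted-column recovery")
    msa <- simulate_pattern_msa(config$sim)
    pat <- select_pattern_positions(msa$family, fdr = config$pattern_fdr,
                                    n_perm = config$pattern_n_perm,
                                    seed = stage_seed(config$seed,
                                                      "patterns"))
    utils::write.table(pat, file.path(out_dir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "patterns.tsv"))
    stages_done <- c(stages_done, "patterns")
  }

  outputs <- sort(unique(outputs))
  digests <- as.list(tools::md5sum(outputs))
  names(digests) <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
                        normalizePath(outputs))
  manifest <- list(seed = config$seed, stages = stages_done,
                   parameters = list(
                     n_organisms = config$n_organisms,
                     branch_length = config$branch_length,
                     n_families = config$sim$n_families,
                     forward_evalue_max = config$orthology$forward_evalue_max,
                     reciprocal_evalue_max =
                       config$orthology$reciprocal_evalue_max,
                     inflation = config$orthology$inflation,
                     k = config$k, enrich_fdr = config$enrich_fdr,
                     pattern_fdr = config$pattern_fdr),
                   outputs = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
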