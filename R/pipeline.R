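# End-to-end orchestration: PPI filtering/clustering -> typed-network
# assembly -> motif census and composite-FFL extraction -> drug screen.
# Driven by a single YAML (or plain list) configuration; every intermediate
# artifact is written as a plain-text table and summarised in a JSON
# manifest.

#' Load and validate a pipeline configuration
#'
#' The configuration may be a YAML file path or a list with components:
#' `inputs` (paths `tf_mirna`, `tf_gene`, `mirna_gene`, `mirna_tf`, `ppi`,
#' `drug_targets`, optional `tf_universe` / `gene_universe` /
#' `mirna_universe` files with one id per line), `out_dir`, `seed`, and
#' optional parameter blocks `ppi` (min_combined_score, hub_min_degree,
#' mcode fields), `motif` (z_min, p_max, n_random, swaps_per_edge) and
#' `drugs` (genome_size, min_drug_targets, alpha, tail, approved_only).
#'
#' @param config list or YAML path.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$out_dir))
  needed <- c("tf_mirna", "tf_gene", "mirna_gene", "mirna_tf", "ppi",
              "drug_targets")
  missing <- setdiff(needed, names(config$inputs))
  if (length(missing))
    stop("config inputs missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(names(config$inputs),
                       c(needed, "tf_universe", "gene_universe",
                         "mirna_universe"))) {
    if (!file.exists(config$inputs[[nm]]))
      stop(sprintf("input file for '%s' not found: %s", nm,
                   config$inputs[[nm]]), call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  p <- config$ppi
  config$ppi_config <- ppi_config(
    min_combined_score = p$min_combined_score %||% 0.9,
    hub_min_degree = p$hub_min_degree %||% 30,
    mcode = mcode_config(
      min_cluster_score = p$mcode_min_cluster_score %||% 5,
      node_score_cutoff = p$mcode_node_score_cutoff %||% 0.2,
      max_depth = p$mcode_max_depth %||% 100,
      degree_cutoff = p$mcode_degree_cutoff %||% 2,
      k_core = p$mcode_k_core %||% 3
    )
  )
  m <- config$motif
  config$motif_config <- motif_config(
    z_min = m$z_min %||% 2.0, p_max = m$p_max %||% 0.05,
    n_random = m$n_random %||% 1000,
    swaps_per_edge = m$swaps_per_edge %||% 3,
    seed = config$seed
  )
  d <- config$drugs
  config$drug_params <- list(
    genome_size = d$genome_size %||% 20000,
    min_drug_targets = d$min_drug_targets %||% 2,
    alpha = d$alpha %||% 0.05,
    tail = d$tail %||% "upper",
    approved_only = isTRUE(d$approved_only %||% TRUE)
  )
  class(config) <- "pipeline_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_universe_file <- function(path) {
  x <- readLines(path)
  trimws(x[nzchar(trimws(x))])
}

# Universes either come from explicit files or are inferred from the
# category each identifier appears under in the pair tables.
resolve_universes <- function(config, pair_list) {
  inp <- config$inputs
  infer_tf <- unique(c(pair_list$TF_MIRNA$source, pair_list$TF_GENE$source,
                       pair_list$MIRNA_TF$target))
  infer_gene <- unique(c(pair_list$TF_GENE$target, pair_list$MIRNA_GENE$target))
  infer_mirna <- unique(c(pair_list$TF_MIRNA$target,
                          pair_list$MIRNA_GENE$source,
                          pair_list$MIRNA_TF$source))
  list(
    tf = if (!is.null(inp$tf_universe))
      normalize_gene_id(read_universe_file(inp$tf_universe)) else infer_tf,
    gene = if (!is.null(inp$gene_universe))
      normalize_gene_id(read_universe_file(inp$gene_universe)) else infer_gene,
    mirna = if (!is.null(inp$mirna_universe))
      normalize_mirna_id(read_universe_file(inp$mirna_universe)) else infer_mirna
  )
}

write_table_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence PPI -> network build -> motif analysis ->
#' drug screen from a single configuration, writing every intermediate
#' artifact under `out_dir` and a `manifest.json` recording the package
#' version, seed, input file hashes, per-stage row counts and stage
#' timings. Any stage failure aborts with the stage name; artifacts written
#' before the failure are retained.
#'
#' @param config a [pipeline_config()], or a list / YAML path accepted by
#'   it.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  counts <- list()
  timings <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # stage 1: PPI
  ppi_res <- stage("ppi", function() {
    edges <- read_ppi_table(config$inputs$ppi)
    g <- filter_ppi(edges, config$ppi_config$min_combined_score)
    fedges <- igraph::as_data_frame(g, what = "edges")
    names(fedges) <- c("protein_a", "protein_b", "combined_score")
    artifacts$filtered_ppi <<- write_table_artifact(
      fedges, file.path(out_dir, "filtered_ppi.tsv"))
    hubs <- hub_genes(g, config$ppi_config$hub_min_degree)
    artifacts$hubs <<- write_table_artifact(
      data.frame(gene = hubs,
                 degree = as.integer(igraph::degree(g)[hubs])),
      file.path(out_dir, "hubs.tsv"))
    cl <- mcode_clusters(g, config$ppi_config$mcode)
    cl_flat <- if (nrow(cl)) do.call(rbind, lapply(seq_len(nrow(cl)),
      function(i) data.frame(cluster = cl$cluster[i],
                             member = cl$members[[i]],
                             n_nodes = cl$n_nodes[i], n_edges = cl$n_edges[i],
                             score = cl$score[i], stringsAsFactors = FALSE)))
      else data.frame(cluster = integer(), member = character(),
                      n_nodes = integer(), n_edges = integer(),
                      score = numeric())
    artifacts$clusters <<- write_table_artifact(
      cl_flat, file.path(out_dir, "mcode_clusters.tsv"))
    counts$ppi <<- list(edges_in = nrow(edges), edges_filtered = nrow(fedges),
                        hubs = length(hubs), clusters = nrow(cl))
    list(graph = g, hubs = hubs, clusters = cl)
  })

  # stage 2: typed network
  net_res <- stage("build", function() {
    pair_list <- list(
      TF_MIRNA = read_pair_table(config$inputs$tf_mirna, "TF_MIRNA"),
      TF_GENE = read_pair_table(config$inputs$tf_gene, "TF_GENE"),
      MIRNA_GENE = read_pair_table(config$inputs$mirna_gene, "MIRNA_GENE"),
      MIRNA_TF = read_pair_table(config$inputs$mirna_tf, "MIRNA_TF"))
    uni <- resolve_universes(config, pair_list)
    net <- build_network(do.call(rbind, pair_list), uni$tf, uni$gene,
                         uni$mirna)
    artifacts$tmign <<- file.path(out_dir, "tmign.sif")
    write_sif(net, artifacts$tmign)
    topo <- topology_profile(net)
    artifacts$topology <<- write_table_artifact(
      topo, file.path(out_dir, "topology.tsv"))
    fit <- tryCatch(fit_power_law(topo$degree), error = function(e) NULL)
    artifacts$power_law <<- file.path(out_dir, "power_law.json")
    jsonlite::write_json(
      if (is.null(fit)) list(error = "degree distribution too degenerate")
      else fit,
      artifacts$power_law, auto_unbox = TRUE, digits = NA)
    counts$build <<- c(node_census(net), list(edges = n_edges(net)))
    list(network = net, universes = uni, pairs = pair_list)
  })

  # stage 3: motifs
  motif_res <- stage("motifs", function() {
    census <- enumerate_triads(net_res$network)
    stats <- motif_zscores(net_res$network, config$motif_config,
                           census = census)
    artifacts$motif_stats <<- write_table_artifact(
      stats, file.path(out_dir, "motif_stats.tsv"))
    merged <- select_and_merge(stats, census, config$motif_config)
    artifacts$iacfmsn <<- file.path(out_dir, "iacfmsn.sif")
    write_sif(merged$network, artifacts$iacfmsn)
    artifacts$ffl_triples <<- write_table_artifact(
      merged$triples, file.path(out_dir, "ffl_triples.tsv"))
    counts$motifs <<- list(classes_observed = nrow(stats),
                           classes_selected = nrow(merged$classes),
                           ffl_triples = nrow(merged$triples),
                           subnetwork_nodes = n_nodes(merged$network),
                           subnetwork_edges = n_edges(merged$network))
    merged
  })

  # stage 4: drug screen
  stage("drugs", function() {
    drugs <- read_drug_target_table(config$inputs$drug_targets)
    sub <- motif_res$network
    sub_genes <- sub$nodes$node[sub$nodes$role %in% c("GENE", "TF_AND_GENE")]
    mapped <- map_drugs_to_genes(sub_genes, drugs,
                                 config$drug_params$approved_only)
    artifacts$drug_map <<- write_table_artifact(
      mapped, file.path(out_dir, "drug_gene_map.tsv"))
    # miRNA target sets: genes (and TFs, which are genes too) each
    # sub-network miRNA regulates anywhere in the full network
    full <- net_res$network
    mirnas <- sub$nodes$node[sub$nodes$role == "MIRNA"]
    e <- full$edges[full$edges$category %in% c("MIRNA_GENE", "MIRNA_TF") &
                      full$edges$source %in% mirnas, , drop = FALSE]
    mirna_targets <- split(e$target, e$source)
    pool <- if (config$drug_params$approved_only)
      drugs[drugs$approved, , drop = FALSE] else drugs
    drug_targets <- split(pool$target_gene, pool$drug_id)
    assoc <- mirna_drug_association(
      mirna_targets, drug_targets, M = config$drug_params$genome_size,
      min_drug_targets = config$drug_params$min_drug_targets,
      alpha = config$drug_params$alpha, tail = config$drug_params$tail)
    artifacts$drug_associations <<- write_table_artifact(
      assoc, file.path(out_dir, "drug_associations.tsv"))
    counts$drugs <<- list(drug_gene_pairs = nrow(mapped),
                          tested_pairs = nrow(assoc),
                          significant_pairs = sum(assoc$significant))
    assoc
  })

  input_files <- unlist(config$inputs)
  manifest <- list(
    package = "fflregnet",
    version = as.character(utils::packageVersion("fflregnet")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(input_files)),
    artifacts = artifacts,
    row_counts = counts,
    stage_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
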