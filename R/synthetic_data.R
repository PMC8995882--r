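# Synthetic generators for every pipeline input, with planted ground truth:
# regulatory pair tables with a controlled number of complete composite
# FFLs, PPI graphs with planted dense modules, and drug-target tables with
# one planted target-enriched drug. All generators are deterministic
# functions of their config (seed included).

#' Configuration for the synthetic regulatory network generator
#'
#' @param n_tf,n_mirna,n_gene sizes of the pure-role universes.
#' @param n_dual number of nodes listed in both the TF and gene universes.
#' @param n_planted_ffl number of complete composite FFLs to plant.
#' @param background_edges_per_category random background edges added per
#'   category (rejected when they would complete an extra composite FFL).
#' @param seed integer seed.
#' @return list of class `synth_regnet_config`.
#' @export
synth_regnet_config <- function(n_tf = 20, n_mirna = 30, n_gene = 50,
                                n_dual = 2, n_planted_ffl = 30,
                                background_edges_per_category = 40,
                                seed = 1L) {
  stopifnot(n_tf >= 0, n_mirna >= 0, n_gene >= 0, n_dual >= 0,
            n_planted_ffl >= 0, background_edges_per_category >= 0,
            n_planted_ffl <= n_tf * n_mirna * n_gene || n_planted_ffl == 0)
  structure(list(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
                 n_dual = n_dual, n_planted_ffl = n_planted_ffl,
                 background_edges_per_category = background_edges_per_category,
                 seed = as.integer(seed)),
            class = "synth_regnet_config")
}

synth_universes <- function(config) {
  tf <- sprintf("TF%03d", seq_len(config$n_tf))
  mirna <- sprintf("hsa-mir-%04d", seq_len(config$n_mirna))
  gene <- sprintf("GENE%03d", seq_len(config$n_gene))
  dual <- sprintf("DUAL%03d", seq_len(config$n_dual))
  list(tf = c(tf, dual), mirna = mirna, gene = c(gene, dual))
}

#' Generate regulatory pair tables with planted composite FFLs
#'
#' Plants `n_planted_ffl` distinct (TF, miRNA, gene) triples, each
#' contributing exactly the four edges TF->miRNA, miRNA->TF, TF->gene and
#' miRNA->gene, then adds uniform background edges per category. A
#' background edge that would complete an additional composite FFL is
#' rejected and redrawn (bounded retries), so the number of complete
#' composite FFLs in the output is exactly the planted count.
#'
#' @param config a [synth_regnet_config()].
#' @return list with `pairs` (data.frame of all categorised pairs),
#'   `universes` (list tf / mirna / gene) and `ground_truth` (list with
#'   `planted_ffl_triples` data.frame).
#' @export
generate_regulatory_pairs <- function(config) {
  stopifnot(inherits(config, "synth_regnet_config"))
  set.seed(config$seed)
  uni <- synth_universes(config)

  # edge lookup keyed source\rtarget per category
  sets <- lapply(EDGE_CATEGORIES, function(x)
    new.env(hash = TRUE, parent = emptyenv()))
  names(sets) <- EDGE_CATEGORIES
  has <- function(cat, s, t)
    exists(paste(s, t, sep = "\r"), envir = sets[[cat]], inherits = FALSE)
  put <- function(cat, s, t)
    assign(paste(s, t, sep = "\r"), TRUE, envir = sets[[cat]])

  # would adding (s, t, cat) complete a composite FFL not yet complete?
  completes_ffl <- function(cat, s, t) {
    if (cat == "TF_MIRNA") {
      for (g in uni$gene)
        if (g != s && has("MIRNA_TF", t, s) && has("TF_GENE", s, g) &&
            has("MIRNA_GENE", t, g)) return(TRUE)
    } else if (cat == "MIRNA_TF") {
      for (g in uni$gene)
        if (g != t && has("TF_MIRNA", t, s) && has("TF_GENE", t, g) &&
            has("MIRNA_GENE", s, g)) return(TRUE)
    } else if (cat == "TF_GENE") {
      for (m in uni$mirna)
        if (has("TF_MIRNA", s, m) && has("MIRNA_TF", m, s) &&
            has("MIRNA_GENE", m, t)) return(TRUE)
    } else if (cat == "MIRNA_GENE") {
      for (tf in uni$tf)
        if (tf != t && has("TF_MIRNA", tf, s) && has("MIRNA_TF", s, tf) &&
            has("TF_GENE", tf, t)) return(TRUE)
    }
    FALSE
  }

  pairs <- list()
  add_pair <- function(cat, s, t) {
    put(cat, s, t)
    pairs[[length(pairs) + 1L]] <<- data.frame(
      source = s, target = t, category = cat, mode = "unspecified",
      stringsAsFactors = FALSE)
  }

  # every (tf, mirna, gene) triple whose four edges are all present
  all_complete_ffls <- function() {
    out <- character()
    for (key in ls(sets[["TF_MIRNA"]])) {
      st <- strsplit(key, "\r", fixed = TRUE)[[1]]
      tf <- st[1]; m <- st[2]
      if (!has("MIRNA_TF", m, tf)) next
      for (g in uni$gene)
        if (g != tf && has("TF_GENE", tf, g) && has("MIRNA_GENE", m, g))
          out <- c(out, paste(tf, m, g, sep = "\r"))
    }
    out
  }

  # plant distinct triples; planted edge sets can in principle combine into
  # an unplanned complete FFL, so the whole planting is redrawn until the
  # set of complete FFLs equals the planted set exactly
  planted <- data.frame(tf = character(), mirna = character(),
                        gene = character(), stringsAsFactors = FALSE)
  if (config$n_planted_ffl > 0) {
    for (attempt in 1:50) {
      for (cat in EDGE_CATEGORIES)
        rm(list = ls(sets[[cat]]), envir = sets[[cat]])
      pairs <- list()
      seen <- new.env(hash = TRUE, parent = emptyenv())
      planted <- data.frame(tf = character(), mirna = character(),
                            gene = character(), stringsAsFactors = FALSE)
      tries <- 0L
      while (nrow(planted) < config$n_planted_ffl) {
        tries <- tries + 1L
        if (tries > 1000L * config$n_planted_ffl)
          stop("could not plant the requested number of distinct FFL triples",
               call. = FALSE)
        tf <- sample(uni$tf, 1)
        m <- sample(uni$mirna, 1)
        g <- sample(uni$gene, 1)
        if (tf == g) next
        key <- paste(tf, m, g, sep = "\r")
        if (exists(key, envir = seen, inherits = FALSE)) next
        assign(key, TRUE, envir = seen)
        planted <- rbind(planted, data.frame(tf = tf, mirna = m, gene = g,
                                             stringsAsFactors = FALSE))
      }
      for (i in seq_len(nrow(planted))) {
        tf <- planted$tf[i]; m <- planted$mirna[i]; g <- planted$gene[i]
        if (!has("TF_MIRNA", tf, m)) add_pair("TF_MIRNA", tf, m)
        if (!has("MIRNA_TF", m, tf)) add_pair("MIRNA_TF", m, tf)
        if (!has("TF_GENE", tf, g)) add_pair("TF_GENE", tf, g)
        if (!has("MIRNA_GENE", m, g)) add_pair("MIRNA_GENE", m, g)
      }
      complete <- sort(all_complete_ffls())
      if (identical(complete,
                    sort(paste(planted$tf, planted$mirna, planted$gene,
                               sep = "\r"))))
        break
      if (attempt == 50)
        stop("planting repeatedly produced unplanned composite FFLs",
             call. = FALSE)
    }
  }

  # background edges with composite-FFL rejection
  draw_endpoint <- function(side) {
    switch(side, tf = sample(uni$tf, 1), mirna = sample(uni$mirna, 1),
           gene = sample(uni$gene, 1))
  }
  cat_ends <- list(TF_MIRNA = c("tf", "mirna"), TF_GENE = c("tf", "gene"),
                   MIRNA_GENE = c("mirna", "gene"), MIRNA_TF = c("mirna", "tf"))
  for (cat in EDGE_CATEGORIES) {
    ends <- cat_ends[[cat]]
    added <- 0L
    tries <- 0L
    while (added < config$background_edges_per_category) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, config$background_edges_per_category))
        stop(sprintf(
          "background generation for %s exhausted its retry budget", cat),
          call. = FALSE)
      s <- draw_endpoint(ends[1])
      t <- draw_endpoint(ends[2])
      if (s == t) next
      if (has(cat, s, t)) next
      if (completes_ffl(cat, s, t)) next
      add_pair(cat, s, t)
      added <- added + 1L
    }
  }

  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$category, pairs$source, pairs$target), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  planted <- planted[order(planted$tf, planted$mirna, planted$gene), ,
                     drop = FALSE]
  rownames(planted) <- NULL
  list(pairs = pairs, universes = uni,
       ground_truth = list(planted_ffl_triples = planted))
}

#' Configuration for the synthetic PPI generator
#'
#' @param n_proteins total protein universe size.
#' @param n_modules number of planted dense modules.
#' @param module_size nodes per module (>= 4).
#' @param p_within edge probability inside a module.
#' @param p_background edge probability between all other pairs
#'   (must be < `p_within`).
#' @param score_range_signal combined-score interval for module edges.
#' @param score_range_noise combined-score interval for background edges.
#' @param seed integer seed.
#' @return list of class `synth_ppi_config`.
#' @export
synth_ppi_config <- function(n_proteins = 100, n_modules = 2, module_size = 8,
                             p_within = 0.9, p_background = 0.02,
                             score_range_signal = c(0.905, 0.999),
                             score_range_noise = c(0.15, 0.999),
                             seed = 1L) {
  stopifnot(module_size >= 4, p_within > p_background,
            p_within >= 0, p_within <= 1, p_background >= 0,
            n_modules * module_size <= n_proteins,
            length(score_range_signal) == 2, length(score_range_noise) == 2,
            all(score_range_signal >= 0), all(score_range_signal <= 1),
            all(score_range_noise >= 0), all(score_range_noise <= 1))
  structure(list(n_proteins = n_proteins, n_modules = n_modules,
                 module_size = module_size, p_within = p_within,
                 p_background = p_background,
                 score_range_signal = score_range_signal,
                 score_range_noise = score_range_noise,
                 seed = as.integer(seed)),
            class = "synth_ppi_config")
}

#' Generate a STRING-like PPI edge table with planted modules
#'
#' Plants `n_modules` disjoint Erdos-Renyi blocks at `p_within` whose edges
#' draw combined scores from the signal range; every remaining protein pair
#' gets an edge at `p_background` with a noise-range score.
#'
#' @param config a [synth_ppi_config()].
#' @return list with `edges` (data.frame protein_a / protein_b /
#'   combined_score) and `ground_truth` (list with
#'   `planted_module_members`, a list of character vectors).
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "synth_ppi_config"))
  set.seed(config$seed)
  proteins <- sprintf("PROT%04d", seq_len(config$n_proteins))
  member_of <- integer(config$n_proteins)  # 0 = background
  modules <- list()
  nxt <- 1L
  for (m in seq_len(config$n_modules)) {
    idx <- nxt:(nxt + config$module_size - 1L)
    member_of[idx] <- m
    modules[[m]] <- proteins[idx]
    nxt <- nxt + config$module_size
  }
  pairs <- utils::combn(config$n_proteins, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  within <- member_of[i] != 0L & member_of[i] == member_of[j]
  p <- ifelse(within, config$p_within, config$p_background)
  keep <- stats::runif(length(p)) < p
  i <- i[keep]; j <- j[keep]; within <- within[keep]
  lo <- config$score_range_noise[1] +
    (config$score_range_noise[2] - config$score_range_noise[1]) *
    stats::runif(length(i))
  hi <- config$score_range_signal[1] +
    (config$score_range_signal[2] - config$score_range_signal[1]) *
    stats::runif(length(i))
  score <- ifelse(within, hi, lo)
  edges <- data.frame(protein_a = proteins[i], protein_b = proteins[j],
                      combined_score = round(score, 6),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       ground_truth = list(planted_module_members = modules))
}

#' Configuration for the synthetic drug-target generator
#'
#' @param n_drugs number of drugs.
#' @param n_genes_universe size of the target-gene universe.
#' @param targets_per_drug targets drawn per drug.
#' @param planted_drug_overlap how many of the planted drug's targets fall
#'   inside the query gene set (<= `targets_per_drug`).
#' @param seed integer seed.
#' @return list of class `synth_drug_config`.
#' @export
synth_drug_config <- function(n_drugs = 50, n_genes_universe = 500,
                              targets_per_drug = 8, planted_drug_overlap = 6,
                              seed = 1L) {
  stopifnot(planted_drug_overlap <= targets_per_drug, n_drugs >= 1,
            targets_per_drug >= 1,
            n_genes_universe >= targets_per_drug)
  structure(list(n_drugs = n_drugs, n_genes_universe = n_genes_universe,
                 targets_per_drug = targets_per_drug,
                 planted_drug_overlap = planted_drug_overlap,
                 seed = as.integer(seed)),
            class = "synth_drug_config")
}

#' Generate a drug-target table with one planted target-enriched drug
#'
#' The first drug is planted: `planted_drug_overlap` of its targets are
#' drawn from `query_gene_set` and the rest from outside it. Every other
#' drug draws its targets uniformly from the whole universe (which contains
#' the query set).
#'
#' @param config a [synth_drug_config()].
#' @param query_gene_set character vector of genes the screen will query
#'   (must contain at least `planted_drug_overlap` genes).
#' @return list with `pairs` (drug-target data.frame) and `ground_truth`
#'   (list with `planted_drug_id`).
#' @export
generate_drug_targets <- function(config, query_gene_set) {
  stopifnot(inherits(config, "synth_drug_config"))
  query_gene_set <- unique(normalize_gene_id(query_gene_set))
  stopifnot(config$planted_drug_overlap <= length(query_gene_set))
  set.seed(config$seed)
  universe <- unique(c(sprintf("TGT%04d", seq_len(config$n_genes_universe)),
                       query_gene_set))
  outside <- setdiff(universe, query_gene_set)
  stopifnot(length(outside) >=
              config$targets_per_drug - config$planted_drug_overlap)
  drug_ids <- sprintf("DB%05d", seq_len(config$n_drugs))
  planted_id <- drug_ids[1]
  rows <- list()
  for (d in seq_len(config$n_drugs)) {
    if (d == 1L) {
      targets <- c(sample(query_gene_set, config$planted_drug_overlap),
                   sample(outside,
                          config$targets_per_drug - config$planted_drug_overlap))
    } else {
      targets <- sample(universe, config$targets_per_drug)
    }
    rows[[d]] <- data.frame(drug_id = drug_ids[d],
                            drug_name = sprintf("drug-%s", drug_ids[d]),
                            approved = TRUE, target_gene = targets,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(pairs$drug_id, pairs$target_gene), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       ground_truth = list(planted_drug_id = planted_id,
                           universe = universe))
}

#' Write a full synthetic input set to a directory
#'
#' Materialises one synthetic study — the four regulatory pair tables, a
#' PPI table, a drug-target table — in the TSV dialects the readers expect,
#' plus a `ground_truth.json` sidecar.
#'
#' @param dir output directory (created if needed).
#' @param regnet_config a [synth_regnet_config()].
#' @param ppi_config a [synth_ppi_config()].
#' @param drug_config a [synth_drug_config()].
#' @return invisibly, a named list of the written file paths.
#' @export
write_synthetic_inputs <- function(dir,
                                   regnet_config = synth_regnet_config(),
                                   ppi_config = synth_ppi_config(),
                                   drug_config = synth_drug_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- generate_regulatory_pairs(regnet_config)
  ppi <- generate_ppi(ppi_config)
  # the drug screen queries the genes regulated by the planted miRNAs
  query <- unique(reg$ground_truth$planted_ffl_triples$gene)
  if (length(query) < drug_config$planted_drug_overlap)
    query <- unique(c(query, reg$universes$gene))
  drugs <- generate_drug_targets(drug_config, query)

  paths <- list()
  for (cat in EDGE_CATEGORIES) {
    p <- file.path(dir, paste0(tolower(cat), ".tsv"))
    write_pair_table(reg$pairs[reg$pairs$category == cat, , drop = FALSE], p)
    paths[[tolower(cat)]] <- p
  }
  paths$ppi <- file.path(dir, "ppi.tsv")
  write_ppi_table(ppi$edges, paths$ppi)
  paths$drug_targets <- file.path(dir, "drug_targets.tsv")
  write_drug_target_table(drugs$pairs, paths$drug_targets)
  for (u in c("tf", "mirna", "gene")) {
    p <- file.path(dir, paste0(u, "_universe.txt"))
    writeLines(reg$universes[[u]], p)
    paths[[paste0(u, "_universe")]] <- p
  }
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(planted_ffl_triples = reg$ground_truth$planted_ffl_triples,
         planted_module_members = ppi$ground_truth$planted_module_members,
         planted_drug_id = drugs$ground_truth$planted_drug_id),
    paths$ground_truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
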