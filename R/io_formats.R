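# Readers and writers for every external table the pipeline touches.
# All tables are plain TSV with a header; identifiers are normalised on the
# way in (gene/TF symbols upper-cased, miRNA names lower-cased) so that the
# same molecule named with different capitalisation collapses to one node.

normalize_gene_id <- function(x) toupper(trimws(x))

normalize_mirna_id <- function(x) tolower(trimws(x))

# Which side of each edge category carries a miRNA identifier.
category_sides <- function(category) {
  switch(category,
    TF_MIRNA   = list(source = "gene", target = "mirna"),
    TF_GENE    = list(source = "gene", target = "gene"),
    MIRNA_GENE = list(source = "mirna", target = "gene"),
    MIRNA_TF   = list(source = "mirna", target = "gene"),
    stop("unknown edge category: ", category)
  )
}

normalize_by_side <- function(x, side) {
  if (side == "mirna") normalize_mirna_id(x) else normalize_gene_id(x)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  require_columns(df, required, path)
  df
}

#' Read a regulatory pair table
#'
#' Reads one of the four categories of regulation pairs (TF->miRNA, TF->gene,
#' miRNA->gene, miRNA->TF) from a TSV file with columns `source`, `target`
#' and an optional `mode` column (activation / repression / unspecified).
#' Identifiers are normalised, self-loops are rejected with a warning, and
#' exact duplicates of (source, target) within the category are collapsed
#' to a single pair (the number collapsed is reported via `message()`).
#' miRNA-side identifiers that do not match the "hsa-..." naming pattern are
#' accepted verbatim with a warning.
#'
#' @param path TSV file path.
#' @param category one of [EDGE_CATEGORIES].
#' @return data.frame with columns `source`, `target`, `category`, `mode`.
#' @export
read_pair_table <- function(path, category) {
  category <- match.arg(category, EDGE_CATEGORIES)
  df <- read_tsv_checked(path, c("source", "target"))
  if (!"mode" %in% names(df)) df$mode <- rep("unspecified", nrow(df))
  df$mode[is.na(df$mode) | df$mode == ""] <- "unspecified"
  bad_mode <- setdiff(unique(df$mode), REGULATION_MODES)
  if (length(bad_mode))
    stop(sprintf("file '%s' has unknown regulation mode(s): %s",
                 path, paste(bad_mode, collapse = ", ")), call. = FALSE)
  sides <- category_sides(category)
  df$source <- normalize_by_side(df$source, sides$source)
  df$target <- normalize_by_side(df$target, sides$target)

  mirna_ids <- character()
  if (sides$source == "mirna") mirna_ids <- c(mirna_ids, df$source)
  if (sides$target == "mirna") mirna_ids <- c(mirna_ids, df$target)
  odd <- unique(mirna_ids[!grepl("^hsa-", mirna_ids) & nzchar(mirna_ids)])
  if (length(odd))
    warning(sprintf("%d miRNA identifier(s) do not match the 'hsa-' pattern (kept verbatim): %s",
                    length(odd), paste(utils::head(odd, 3), collapse = ", ")),
            call. = FALSE)

  self <- df$source == df$target
  if (any(self)) {
    warning(sprintf("rejected %d self-loop row(s) in '%s'", sum(self), path),
            call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  key <- paste(df$source, df$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("collapsed %d duplicate pair(s) in '%s'", sum(dup), path))
  df <- df[!dup, , drop = FALSE]
  out <- data.frame(source = df$source, target = df$target,
                    category = rep(category, nrow(df)), mode = df$mode,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a regulatory pair table
#'
#' Inverse of [read_pair_table()]: writes `source`, `target`, `mode` as TSV.
#'
#' @param pairs data.frame as returned by [read_pair_table()].
#' @param path output path.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs[, c("source", "target", "mode")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted protein-protein interaction table
#'
#' Expects TSV columns `protein_a`, `protein_b`, `combined_score`. Scores on
#' the STRING-style 0-1000 integer scale (detected when any score exceeds 1)
#' are divided by 1000; scores already in [0, 1] pass through. The edge list
#' is undirected: each edge is stored with `protein_a <= protein_b`
#' lexicographically and symmetric duplicates are collapsed keeping the
#' maximum score.
#'
#' @param path TSV file path.
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (in [0, 1]).
#' @export
read_ppi_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_a", "protein_b", "combined_score"))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score))
    stop(sprintf("file '%s' has non-numeric combined_score value(s)", path),
         call. = FALSE)
  if (any(score < 0) || any(score > 1000))
    stop(sprintf("file '%s' has combined_score outside [0, 1000]", path),
         call. = FALSE)
  if (length(score) && max(score) > 1) score <- score / 1000
  a <- normalize_gene_id(df$protein_a)
  b <- normalize_gene_id(df$protein_b)
  if (any(a == b)) {
    warning(sprintf("rejected %d self-interaction row(s) in '%s'",
                    sum(a == b), path), call. = FALSE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- data.frame(protein_a = lo, protein_b = hi, combined_score = score,
                    stringsAsFactors = FALSE)
  key <- paste(out$protein_a, out$protein_b, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("collapsed %d symmetric duplicate edge(s) in '%s'",
                    sum(duplicated(key)), path))
    mx <- tapply(out$combined_score, key, max)
    out <- out[!duplicated(key), , drop = FALSE]
    out$combined_score <- as.numeric(mx[paste(out$protein_a, out$protein_b,
                                              sep = "\r")])
  }
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a protein-protein interaction table
#' @param edges data.frame as returned by [read_ppi_table()].
#' @param path output path.
#' @export
write_ppi_table <- function(edges, path) {
  utils::write.table(edges[, c("protein_a", "protein_b", "combined_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_approved_flag <- function(x, path) {
  lx <- tolower(trimws(x))
  yes <- c("true", "t", "yes", "y", "1", "approved")
  no  <- c("false", "f", "no", "n", "0", "investigational", "experimental",
           "withdrawn", "unapproved")
  out <- rep(NA, length(lx))
  out[lx %in% yes] <- TRUE
  out[lx %in% no] <- FALSE
  if (anyNA(out))
    stop(sprintf("file '%s' has unparseable approval flag(s): %s", path,
                 paste(utils::head(unique(x[is.na(out)]), 3), collapse = ", ")),
         call. = FALSE)
  out
}

#' Read a drug-target table
#'
#' Expects TSV columns `drug_id`, `drug_name`, `approved`, `target_gene`.
#' The approval flag is parsed case-insensitively from true/false, yes/no,
#' 1/0 or approved/investigational-style vocabularies. Duplicate
#' (drug_id, target_gene) rows are collapsed to one.
#'
#' @param path TSV file path.
#' @return data.frame with columns `drug_id`, `drug_name`, `approved`
#'   (logical), `target_gene`.
#' @export
read_drug_target_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "drug_name", "approved",
                                 "target_gene"))
  if (any(!nzchar(trimws(df$drug_id))))
    stop(sprintf("file '%s' has empty drug_id value(s)", path), call. = FALSE)
  out <- data.frame(
    drug_id = trimws(df$drug_id),
    drug_name = trimws(df$drug_name),
    approved = parse_approved_flag(df$approved, path),
    target_gene = normalize_gene_id(df$target_gene),
    stringsAsFactors = FALSE
  )
  key <- paste(out$drug_id, out$target_gene, sep = "\r")
  if (anyDuplicated(key))
    message(sprintf("collapsed %d duplicate (drug, gene) row(s) in '%s'",
                    sum(duplicated(key)), path))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$drug_id, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a drug-target table
#' @param pairs data.frame as returned by [read_drug_target_table()].
#' @param path output path.
#' @export
write_drug_target_table <- function(pairs, path) {
  df <- pairs[, c("drug_id", "drug_name", "approved", "target_gene")]
  df$approved <- ifelse(df$approved, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sif_nodes_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
}

#' Export a typed network as a SIF file
#'
#' Writes Cytoscape-compatible SIF lines `source<TAB>category<TAB>target`,
#' one per directed edge, in a deterministic (category, source, target)
#' order, plus a companion node-attribute TSV (`<stem>_nodes.tsv` with
#' columns `node`, `role`).
#'
#' @param network a `typed_network`.
#' @param path output SIF path.
#' @return the SIF path, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "typed_network"))
  e <- network$edges
  lines <- if (nrow(e)) sprintf("%s\t%s\t%s", e$source, e$category, e$target)
           else character()
  writeLines(lines, path)
  utils::write.table(network$nodes[, c("node", "role")], sif_nodes_path(path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed network from a SIF file
#'
#' Inverse of [write_sif()]. Node roles are taken from the companion
#' node-attribute TSV written next to the SIF file.
#'
#' @param path SIF path (the `<stem>_nodes.tsv` companion must exist).
#' @return a `typed_network`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  npath <- sif_nodes_path(path)
  if (!file.exists(npath))
    stop("node-attribute file not found: ", npath, call. = FALSE)
  nodes <- utils::read.delim(npath, colClasses = "character",
                             stringsAsFactors = FALSE)
  require_columns(nodes, c("node", "role"), npath)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("malformed SIF line (expected 3 tab-separated fields) in ", path,
           call. = FALSE)
    m <- do.call(rbind, parts)
    edges <- data.frame(source = m[, 1], target = m[, 3], category = m[, 2],
                        mode = "unspecified", stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  typed_network(nodes, edges)
}
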