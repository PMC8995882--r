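# Drug-target mapping and miRNA-drug association by the cumulative
# hypergeometric distribution. Both tails are always reported: the lower
# tail is the cumulative sum from 0 to x (the probability of at most x
# shared genes); the upper tail P(X >= x) is the one under which an
# unusually large overlap yields a small p, and is the default used for
# significance calls.

#' Cumulative hypergeometric distribution
#'
#' P(X <= x) where X counts the overlap between a size-N draw and a marked
#' subset of size K inside a universe of size M:
#' sum over i = 0..x of choose(K, i) * choose(M - K, N - i) / choose(M, N).
#' Terms are accumulated in log space for numerical stability.
#'
#' @param x maximum overlap summed to (0 <= x <= min(K, N)).
#' @param M universe size (e.g. number of genes in the genome).
#' @param K size of the marked subset (e.g. a miRNA's target genes).
#' @param N draw size (e.g. a drug's target genes).
#' @return numeric probability in [0, 1].
#' @export
hypergeom_cdf <- function(x, M, K, N) {
  stopifnot(length(x) == 1, length(M) == 1, length(K) == 1, length(N) == 1)
  if (K > M || N > M || x < 0 || x > min(K, N) || K < 0 || N < 0)
    stop("invalid hypergeometric query: need 0 <= x <= min(K, N) and K, N <= M",
         call. = FALSE)
  i <- 0:x
  logterms <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  logterms <- logterms[is.finite(logterms)]
  if (!length(logterms)) return(0)
  mx <- max(logterms)
  min(1, exp(mx) * sum(exp(logterms - mx)))
}

# Upper tail P(X >= x); shares the P(X = x) term with the lower tail.
hypergeom_upper <- function(x, M, K, N) {
  if (x <= 0) return(1)
  min(1, max(0, 1 - hypergeom_cdf(x - 1, M, K, N)))
}

#' Restrict a drug-target table to a gene set
#'
#' Keeps the pairs whose target gene lies in `genes`; with
#' `approved_only`, non-approved drugs are removed first.
#'
#' @param genes character vector of gene identifiers.
#' @param drugs drug-target data.frame (see [read_drug_target_table()]).
#' @param approved_only drop non-approved drugs (default TRUE).
#' @return filtered drug-target data.frame.
#' @export
map_drugs_to_genes <- function(genes, drugs, approved_only = TRUE) {
  stopifnot(is.data.frame(drugs),
            all(c("drug_id", "approved", "target_gene") %in% names(drugs)))
  genes <- unique(normalize_gene_id(genes))
  if (approved_only) drugs <- drugs[drugs$approved, , drop = FALSE]
  out <- drugs[drugs$target_gene %in% genes, , drop = FALSE]
  out <- out[order(out$drug_id, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-drug association by cumulative hypergeometric test
#'
#' For every (miRNA, drug) combination, computes the overlap x between the
#' miRNA's target genes (size K) and the drug's target genes (size N) in a
#' genome universe of size M, and reports both hypergeometric tails:
#' `p_lower` = P(X <= x) and `p_upper` = P(X >= x). Drugs with fewer than
#' `min_drug_targets` targets are discarded before testing. Significance is
#' called on the selected tail at level `alpha`; a Benjamini-Hochberg
#' adjusted column on that tail is added for information only.
#'
#' @param mirna_targets named list: miRNA id -> character vector of target
#'   genes.
#' @param drug_targets named list: drug id -> character vector of target
#'   genes.
#' @param M genome universe size (must be >= every set size).
#' @param min_drug_targets minimum drug target count (default 2).
#' @param alpha significance level (default 0.05).
#' @param tail which tail drives the significance call (default "upper").
#' @return data.frame with one row per tested (miRNA, drug) pair:
#'   `mirna_id`, `drug_id`, `x`, `K`, `N`, `shared_genes`
#'   (comma-separated), `p_lower`, `p_upper`, `p_adjusted`, `significant`,
#'   sorted by the selected tail.
#' @export
mirna_drug_association <- function(mirna_targets, drug_targets, M,
                                   min_drug_targets = 2, alpha = 0.05,
                                   tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(is.list(mirna_targets), is.list(drug_targets), M >= 1)
  mirna_targets <- lapply(mirna_targets, function(x) unique(as.character(x)))
  drug_targets <- lapply(drug_targets, function(x) unique(as.character(x)))
  drug_targets <- drug_targets[lengths(drug_targets) >= min_drug_targets]
  empty <- data.frame(mirna_id = character(), drug_id = character(),
                      x = integer(), K = integer(), N = integer(),
                      shared_genes = character(), p_lower = numeric(),
                      p_upper = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(mirna_targets) || !length(drug_targets)) return(empty)
  sizes <- c(lengths(mirna_targets), lengths(drug_targets))
  if (any(sizes > M))
    stop("genome size M is smaller than a target set", call. = FALSE)

  rows <- list()
  for (m in sort(names(mirna_targets))) {
    K <- length(mirna_targets[[m]])
    for (d in sort(names(drug_targets))) {
      N <- length(drug_targets[[d]])
      shared <- intersect(mirna_targets[[m]], drug_targets[[d]])
      x <- length(shared)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, drug_id = d, x = x, K = K, N = N,
        shared_genes = paste(sort(shared), collapse = ","),
        p_lower = hypergeom_cdf(x, M, K, N),
        p_upper = hypergeom_upper(x, M, K, N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  psel <- if (tail == "upper") out$p_upper else out$p_lower
  out$p_adjusted <- stats::p.adjust(psel, method = "BH")
  out$significant <- psel < alpha
  out <- out[order(psel, out$mirna_id, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-gene-pathway report
#'
#' Expands drug-target pairs with a user-supplied gene -> pathway map into
#' one row per (drug, gene, pathway) triple; genes without pathway
#' annotation keep an empty pathway field.
#'
#' @param pairs drug-target data.frame.
#' @param gene_pathways named list: gene -> character vector of pathway ids
#'   (may be empty or missing genes).
#' @return data.frame with columns `drug_id`, `drug_name`, `target_gene`,
#'   `pathway`.
#' @export
drug_gene_report <- function(pairs, gene_pathways = list()) {
  stopifnot(is.data.frame(pairs),
            all(c("drug_id", "drug_name", "target_gene") %in% names(pairs)))
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    g <- pairs$target_gene[r]
    pw <- gene_pathways[[g]]
    if (is.null(pw) || !length(pw)) pw <- ""
    rows[[length(rows) + 1L]] <- data.frame(
      drug_id = pairs$drug_id[r], drug_name = pairs$drug_name[r],
      target_gene = g, pathway = pw, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(drug_id = character(), drug_name = character(),
                      target_gene = character(), pathway = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
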