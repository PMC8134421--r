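#' Map SNVs to their genes
#'
#' Many variants map to the same gene; the result is the deduplicated,
#' sorted gene list. Variants absent from the map are dropped with a
#' warning reporting how many.
#'
#' @param snvs character vector of locus ids.
#' @param snv_gene_map data.frame with columns `locus_id` and `gene`.
#' @return sorted character vector of unique genes (non-empty, else error).
#' @export
snvs_to_genes <- function(snvs, snv_gene_map) {
  if (length(snvs) == 0L) stop("empty SNV list", call. = FALSE)
  stopifnot(all(c("locus_id", "gene") %in% names(snv_gene_map)))
  hit <- snv_gene_map$locus_id %in% snvs
  n_unmapped <- length(setdiff(snvs, snv_gene_map$locus_id))
  if (n_unmapped > 0) {
    warning(n_unmapped, " SNV(s) not present in the gene map were dropped")
  }
  genes <- sort(unique(snv_gene_map$gene[hit]))
  if (length(genes) == 0L) stop("no SNV could be mapped to a gene", call. = FALSE)
  genes
}

#' Gene-set over-representation profile
#'
#' For every term, the overlap between the query genes and the term's
#' genes (both restricted to the background universe) is scored with the
#' hypergeometric upper-tail p-value. Terms are ranked ascending by
#' p-value, ties broken by larger overlap and then term id, giving the
#' enrichment profile: the rank-1 term is the most over-represented.
#'
#' @param query character vector of genes; must be a subset of
#'   `background`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); must be non-empty.
#' @param background character vector: the gene universe.
#' @return data.frame of class `enrichment_profile`: `term`, `overlap`,
#'   `term_size`, `p_value`, `rank`.
#' @export
enrich_profile <- function(query, gene_sets, background) {
  if (inherits(gene_sets, "gene_annotation")) gene_sets <- gene_sets$gene_sets
  if (length(gene_sets) == 0L) stop("gene-set collection is empty", call. = FALSE)
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop("query genes outside the background: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  query <- unique(query)
  background <- unique(background)
  N <- length(background)
  q <- length(query)
  term_genes <- lapply(gene_sets, intersect, y = background)
  m <- lengths(term_genes)
  x <- vapply(term_genes, function(g) length(intersect(g, query)), integer(1))
  p <- stats::phyper(x - 1, m, N - m, q, lower.tail = FALSE)
  out <- data.frame(term = names(gene_sets), overlap = x, term_size = m,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$overlap, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Rank-resampling bias test for a prediction model
#'
#' Tests whether the ASE variants a model recovers are functionally biased.
#' The observed enrichment profile comes from the genes of the correctly
#' predicted ASE-SNVs; the expected rank distribution comes from repeatedly
#' drawing the same number of SNVs at random (without replacement) from the
#' full ASE-SNV set and profiling those draws identically. For each of the
#' observed profile's `top_k` terms, the observed rank and its rank in
#' every resample profile are reported; large, consistent deviations of the
#' observed rank from the resampled ranks indicate bias. A term absent from
#' a resample profile receives rank T+1 (T = number of terms) and is
#' flagged.
#'
#' @param predicted_snvs locus ids of predicted ASE-SNVs; must be a subset
#'   of `full_ase_snvs`.
#' @param full_ase_snvs locus ids of all ASE-SNVs in the cohort.
#' @param snv_gene_map data.frame `locus_id`, `gene`.
#' @param gene_sets named list of gene sets (or a `gene_annotation`).
#' @param background gene universe; default: all genes of
#'   `full_ase_snvs`.
#' @param n_resamples number of random draws (default 10).
#' @param top_k number of observed top terms reported (default 10).
#' @param seed integer seed.
#' @return object of class `bias_report`: `observed` (top-k slice of the
#'   observed profile), `ranks` (long data.frame `term`, `source`, `rank`,
#'   `p_value`, `absent`), `n_resamples`, `subset_size`, `seed`.
#' @export
rank_resampling_test <- function(predicted_snvs, full_ase_snvs, snv_gene_map,
                                 gene_sets, background = NULL,
                                 n_resamples = 10L, top_k = 10L, seed = 1L) {
  if (inherits(gene_sets, "gene_annotation")) gene_sets <- gene_sets$gene_sets
  if (length(gene_sets) == 0L) stop("gene-set collection is empty", call. = FALSE)
  predicted_snvs <- unique(predicted_snvs)
  full_ase_snvs <- unique(full_ase_snvs)
  if (length(predicted_snvs) > length(full_ase_snvs)) {
    stop("more predicted SNVs than SNVs in the full ASE set", call. = FALSE)
  }
  if (length(setdiff(predicted_snvs, full_ase_snvs))) {
    stop("predicted SNVs must be a subset of the full ASE-SNV set", call. = FALSE)
  }
  if (is.null(background)) background <- snvs_to_genes(full_ase_snvs, snv_gene_map)
  n_terms <- length(gene_sets)

  profile_of <- function(snvs) {
    enrich_profile(snvs_to_genes(snvs, snv_gene_map), gene_sets, background)
  }
  obs <- profile_of(predicted_snvs)
  top <- utils::head(obs, top_k)

  rank_in <- function(profile, term) {
    i <- match(term, profile$term)
    if (is.na(i)) c(rank = n_terms + 1, p = NA_real_, absent = 1) else
      c(rank = profile$rank[i], p = profile$p_value[i], absent = 0)
  }

  rows <- list(data.frame(term = top$term, source = "observed",
                          rank = top$rank, p_value = top$p_value,
                          absent = FALSE, stringsAsFactors = FALSE))
  withr_seed(seed, {
    for (r in seq_len(n_resamples)) {
      draw <- sample(full_ase_snvs, length(predicted_snvs))
      prof <- profile_of(draw)
      got <- t(vapply(top$term, rank_in, numeric(3), profile = prof))
      rows[[r + 1L]] <- data.frame(term = top$term,
                                   source = sprintf("resample_%d", r),
                                   rank = got[, "rank"], p_value = got[, "p"],
                                   absent = got[, "absent"] > 0,
                                   stringsAsFactors = FALSE)
    }
  })
  ranks <- do.call(rbind, rows)
  rownames(ranks) <- NULL
  structure(list(observed = top, ranks = ranks, n_resamples = n_resamples,
                 subset_size = length(predicted_snvs), seed = seed),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("bias test: %d predicted ASE-SNVs, %d resamples\n",
              x$subset_size, x$n_resamples))
  res <- x$ranks[x$ranks$source != "observed", , drop = FALSE]
  for (tm in x$observed$term) {
    rr <- res$rank[res$term == tm]
    cat(sprintf("  %-14s observed rank %2d, expected ranks %s\n", tm,
                x$observed$rank[x$observed$term == tm],
                paste(range(rr), collapse = "-")))
  }
  invisible(x)
}

#' Write a bias report in long tabular form
#'
#' Tab-separated columns `term`, `source` (observed or resample_i),
#' `rank`, `p_value` — suitable for violin-style plotting.
#'
#' @param report a `bias_report`.
#' @param path file path.
#' @export
write_bias_report <- function(report, path) {
  utils::write.table(report$ranks[, c("term", "source", "rank", "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
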