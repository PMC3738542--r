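#' Pairwise strain contrasts of reference log-ratios
#'
#' In a common-reference design every strain's expression is a log2 ratio M
#' versus the pooled reference; the contrast between two strains is the
#' difference of their reference ratios, `M_X - M_Y`. Differences satisfy
#' the cycle identity `(X-Y) = (X-Z) - (Y-Z)` exactly.
#'
#' @param M data.frame or matrix of per-strain M values (rows = genes,
#'   columns = strains; rownames or a `gene_id` column give the ids).
#' @param pairs optional character matrix/list of pairs; default all
#'   ordered pairs `combn(strains, 2)` in column order.
#' @return data.frame `gene_id`, `pair` (e.g. `"BL21-HMS174"`),
#'   `gene_diff` (log2). Missing M in either strain yields `NA`.
#' @examples
#' m <- data.frame(BL21 = -1, HMS174 = 2.96, RV308 = -1.08,
#'                 row.names = "aceA")
#' pairwise_gene_contrast(m)
#' @export
pairwise_gene_contrast <- function(M, pairs = NULL) {
  if (is.data.frame(M) && "gene_id" %in% names(M)) {
    rownames(M) <- M$gene_id
    M$gene_id <- NULL
  }
  M <- as.matrix(M)
  strains <- colnames(M)
  stopifnot(!is.null(strains), length(strains) >= 2L)
  if (is.null(pairs)) pairs <- utils::combn(strains, 2L)
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    data.frame(gene_id = rownames(M) %||% seq_len(nrow(M)),
               pair = paste0(a, "-", b),
               gene_diff = M[, a] - M[, b],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcript-protein concordance call
#'
#' Classifies agreement between a gene-level log2 contrast and a
#' protein-level signed fold change for the same strain pair:
#' \itemize{
#'   \item `gene-NA` / `protein-NA` when the respective value is missing;
#'   \item `concordant` when `|gene_diff| >= sign_threshold` and the signs
#'     agree, or when both levels are flat (`|gene_diff| <
#'     sign_threshold` and `|protein_fold| <= flat_fold`);
#'   \item `discordant` otherwise (sign disagreement, or a large protein
#'     fold with a flat gene contrast).
#' }
#' The call is invariant under simultaneous reversal of the pair (which
#' negates the gene difference and maps the protein fold to its negative).
#'
#' @param gene_diff log2 gene contrast(s).
#' @param protein_fold signed protein fold change(s) (|fold| >= 1).
#' @param sign_threshold minimum |gene_diff| for a sign-based call
#'   (default 1.0 log2 units, matching the |M| > 1 convention of the DE
#'   filter: a gene contrast below one log2 unit is treated as flat).
#' @param flat_fold protein fold magnitude at or below which the protein is
#'   considered unchanged (default 2.0, the DIGE alteration threshold).
#' @return character vector of calls.
#' @examples
#' concordance_call(3.56, 9.69)   # concordant (GatD-like)
#' concordance_call(0.97, 15.60)  # discordant (CysP-like)
#' @export
concordance_call <- function(gene_diff, protein_fold, sign_threshold = 1.0,
                             flat_fold = 2.0) {
  n <- max(length(gene_diff), length(protein_fold))
  gene_diff <- rep_len(gene_diff, n)
  protein_fold <- rep_len(protein_fold, n)
  out <- character(n)
  for (i in seq_len(n)) {
    g <- gene_diff[i]; p <- protein_fold[i]
    out[i] <- if (is.na(g) && is.na(p)) "NA"
      else if (is.na(g)) "gene-NA"
      else if (is.na(p)) "protein-NA"
      else if (abs(g) >= sign_threshold) {
        if (sign(g) == sign(p)) "concordant" else "discordant"
      } else if (abs(p) > flat_fold) "discordant" else "concordant"
  }
  out
}

#' Build a contrast table across molecular levels
#'
#' Joins per-spot protein contrasts with per-gene transcript contrasts via
#' a spot -> gene map and adds a concordance call per row. Spots mapping to
#' several proteins (co-migrating spots) produce one row per constituent
#' gene.
#'
#' @param protein a `protein_contrast` data.frame (columns `spot_id`,
#'   `pair`, `ratio`, see [protein_contrasts()]).
#' @param gene output of [pairwise_gene_contrast()].
#' @param spot_map data.frame `spot_id`, `gene_id` (a spot id may repeat
#'   for multi-protein spots).
#' @param ... thresholds passed to [concordance_call()].
#' @return data.frame `spot_id`, `gene_id`, `pair`, `protein_fold`,
#'   `gene_diff`, `call`.
#' @export
contrast_table <- function(protein, gene, spot_map, ...) {
  stopifnot(all(c("spot_id", "gene_id") %in% names(spot_map)))
  out <- merge(protein[c("spot_id", "pair", "ratio")], spot_map,
               by = "spot_id")
  names(out)[names(out) == "ratio"] <- "protein_fold"
  out <- merge(out, gene, by = c("gene_id", "pair"), all.x = TRUE)
  out$call <- concordance_call(out$gene_diff, out$protein_fold, ...)
  out[order(out$gene_id, out$pair),
      c("spot_id", "gene_id", "pair", "protein_fold", "gene_diff", "call")]
}
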