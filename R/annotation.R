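#' Tally genes into functional categories
#'
#' Counts, for every category term, how many genes of a gene set are
#' annotated with it (a gene annotated with several terms contributes to
#' each). Genes without any annotation are counted under the pseudo-term
#' `"unannotated"`. Terms are ranked by descending count, ties broken by
#' lexicographic term id.
#'
#' @param genes character vector of gene ids (the set to characterize,
#'   e.g. a strain-specific DE set).
#' @param map annotation map: a data.frame with columns `gene` and `term`
#'   (optionally `label`), or a named list gene -> character vector of
#'   terms.
#' @param k return only the top `k` terms (default all).
#' @return data.frame `term`, `count` (plus `label` if supplied), sorted;
#'   attribute `unannotated` holds the count of unannotated genes. Empty
#'   gene set gives an empty tally.
#' @examples
#' m <- data.frame(gene = c("a", "b", "c"), term = "GO:0006810")
#' category_tally(c("a", "b", "c"), m)
#' @export
category_tally <- function(genes, map, k = Inf) {
  genes <- unique(genes)
  if (is.list(map) && !is.data.frame(map)) {
    map <- data.frame(gene = rep(names(map), lengths(map)),
                      term = unlist(map, use.names = FALSE),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "term") %in% names(map)))
  if (any(!nzchar(map$term)) || any(is.na(map$term)))
    stop("terms must be non-empty strings")
  if (length(genes) == 0L) {
    out <- data.frame(term = character(), count = integer())
    attr(out, "unannotated") <- 0L
    return(out)
  }
  hits <- unique(map[map$gene %in% genes, c("gene", "term")])
  counts <- table(hits$term)
  out <- data.frame(term = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), ]
  if (is.finite(k)) out <- utils::head(out, k)
  if ("label" %in% names(map))
    out$label <- map$label[match(out$term, map$term)]
  rownames(out) <- NULL
  attr(out, "unannotated") <- sum(!genes %in% map$gene)
  out
}
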