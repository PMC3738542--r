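#' MA transform of a two-colour spot table
#'
#' Computes the log-ratio M and average log-intensity A for every spot,
#' oriented sample-over-reference: `M = log2(sample / reference)`,
#' `A = 0.5 * log2(sample * reference)`. Only foreground intensities are
#' used; no background correction is applied. Spots with a non-positive
#' intensity in either channel are flagged unusable and excluded from M/A
#' (set to `NA`).
#'
#' @param spots a `spot_table` as produced by [simulate_microarray()] or
#'   [read_spot_table()]: columns `block`, `probe_id`, `F_ch1`, `F_ch2`,
#'   `sample_ch1`, `sample_ch2`.
#' @param ref label identifying the reference channel content
#'   (default `"pool"`).
#' @return the spot table with added columns `M`, `A` (sample over
#'   reference) and logical `usable`.
#' @export
ma_transform <- function(spots, ref = "pool") {
  need <- c("block", "probe_id", "F_ch1", "F_ch2", "sample_ch1",
            "sample_ch2")
  if (!all(need %in% names(spots)))
    stop("spot table must have columns ", paste(need, collapse = ", "))
  ch1_is_sample <- spots$sample_ch1 != ref
  if (!all(xor(spots$sample_ch1 == ref, spots$sample_ch2 == ref)))
    stop("each spot must have exactly one reference channel")
  smp <- ifelse(ch1_is_sample, spots$F_ch1, spots$F_ch2)
  rf <- ifelse(ch1_is_sample, spots$F_ch2, spots$F_ch1)
  usable <- is.finite(smp) & is.finite(rf) & smp > 0 & rf > 0
  spots$M <- spots$A <- NA_real_
  spots$M[usable] <- log2(smp[usable] / rf[usable])
  spots$A[usable] <- 0.5 * log2(smp[usable] * rf[usable])
  spots$usable <- usable
  spots
}

#' Print-tip loess normalization
#'
#' Removes intensity-dependent dye bias separately within every print-tip
#' group by local linear regression of M on A with tricube weights
#' (robustified loess), subtracting the fitted trend from M. Tip groups
#' with fewer than 10 usable spots are median-centred instead, with a
#' warning.
#'
#' @param spots a spot table with `M`, `A`, `usable` columns (see
#'   [ma_transform()]) and a `block` column identifying the print-tip
#'   group.
#' @param span loess span (fraction of spots in the local window).
#' @param iterations number of robustifying iterations (0 = plain
#'   least-squares loess).
#' @return the spot table with `M` replaced by the normalized value (raw
#'   values retained in `M_raw`).
#' @export
printtip_loess_normalize <- function(spots, span = 0.4, iterations = 3) {
  stopifnot(all(c("M", "A", "block") %in% names(spots)), span > 0)
  if (!"usable" %in% names(spots)) spots$usable <- is.finite(spots$M)
  spots$M_raw <- spots$M
  fam <- if (iterations > 0) "symmetric" else "gaussian"
  ctl <- stats::loess.control(iterations = iterations + 1L,
                              surface = "direct")
  for (tip in unique(spots$block)) {
    sel <- spots$block == tip & spots$usable
    n <- sum(sel)
    if (n == 0L) next
    if (n < 10L) {
      warning("print-tip group ", tip, " has ", n,
              " usable spots; falling back to median-centering")
      spots$M[sel] <- spots$M[sel] - stats::median(spots$M[sel])
      next
    }
    d <- data.frame(M = spots$M[sel], A = spots$A[sel])
    trend <- tryCatch(
      stats::predict(stats::loess(M ~ A, data = d, span = span,
                                  degree = 1, family = fam,
                                  control = ctl), newdata = d),
      error = function(e) NULL)
    if (is.null(trend) || any(!is.finite(trend)))
      # sparse tips can defeat the robustified local fit; fall back to a
      # plain least-squares loess, then to median-centering
      trend <- tryCatch(
        stats::predict(stats::loess(M ~ A, data = d, span = span,
                                    degree = 1, family = "gaussian",
                                    control = ctl), newdata = d),
        error = function(e) {
          warning("loess failed in print-tip group ", tip,
                  "; median-centering instead")
          rep(stats::median(d$M), nrow(d))
        })
    spots$M[sel] <- spots$M[sel] - trend
  }
  spots
}

#' Consolidate a dye-swap pair (or any replicate arrays of one sample)
#'
#' Because [ma_transform()] orients every M sample-over-reference, the
#' swapped member needs no extra negation here; consolidation averages
#' replicate spots of a probe within each array first, maps probes to
#' genes, and then averages per gene across the arrays of the sample.
#'
#' @param arrays list of normalized spot tables for one sample (both
#'   dye-swap members).
#' @param probe_map optional data.frame `probe_id`, `gene_id`; by default
#'   probes are gene ids.
#' @return data.frame `gene_id`, `M` (mean over arrays), `A` (mean over
#'   arrays), `n_arrays` (arrays contributing; genes missing from some
#'   arrays are kept and flagged by a lower `n_arrays`).
#' @export
consolidate_dye_swap <- function(arrays, probe_map = NULL) {
  stopifnot(is.list(arrays), length(arrays) >= 1L)
  per_array <- lapply(arrays, function(st) {
    st <- st[st$usable & is.finite(st$M), ]
    gene <- if (is.null(probe_map)) st$probe_id else {
      idx <- match(st$probe_id, probe_map$probe_id)
      probe_map$gene_id[idx]
    }
    keep <- !is.na(gene)
    m <- tapply(st$M[keep], gene[keep], mean)
    a <- tapply(st$A[keep], gene[keep], mean)
    data.frame(gene_id = names(m), M = as.numeric(m), A = as.numeric(a),
               stringsAsFactors = FALSE)
  })
  all_g <- sort(unique(unlist(lapply(per_array, `[[`, "gene_id"))))
  Ms <- sapply(per_array, function(d) d$M[match(all_g, d$gene_id)])
  As <- sapply(per_array, function(d) d$A[match(all_g, d$gene_id)])
  Ms <- matrix(Ms, nrow = length(all_g))
  As <- matrix(As, nrow = length(all_g))
  data.frame(gene_id = all_g,
             M = rowMeans(Ms, na.rm = TRUE),
             A = rowMeans(As, na.rm = TRUE),
             n_arrays = rowSums(!is.na(Ms)),
             stringsAsFactors = FALSE)
}

#' Per-gene log-ratio matrix for one strain
#'
#' Normalizes every array of a strain, orients M sample-over-reference and
#' returns a genes x arrays matrix of M values plus the matching A matrix.
#' Each array is one replicate column; a dye-swap pair contributes two
#' columns.
#'
#' @param scans list of spot tables (all arrays of one strain).
#' @param probe_map optional probe -> gene map (see
#'   [consolidate_dye_swap()]).
#' @param span,iterations loess settings, see
#'   [printtip_loess_normalize()].
#' @param normalize set `FALSE` to skip normalization.
#' @return list with matrices `M` and `A` (genes x arrays).
#' @export
gene_ratio_matrix <- function(scans, probe_map = NULL, span = 0.4,
                              iterations = 3, normalize = TRUE) {
  cons <- lapply(scans, function(st) {
    st <- ma_transform(st)
    if (normalize) st <- printtip_loess_normalize(st, span, iterations)
    consolidate_dye_swap(list(st), probe_map)
  })
  genes <- sort(unique(unlist(lapply(cons, `[[`, "gene_id"))))
  M <- sapply(cons, function(d) d$M[match(genes, d$gene_id)])
  A <- sapply(cons, function(d) d$A[match(genes, d$gene_id)])
  M <- matrix(M, nrow = length(genes), dimnames = list(genes, NULL))
  A <- matrix(A, nrow = length(genes), dimnames = list(genes, NULL))
  list(M = M, A = A)
}

# Newton solve of trigamma(x) = y, vectorized (monotone decreasing).
.trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & !is.na(y) & y <= 0] <- Inf
  x <- 0.5 + 1 / y[ok]
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[ok] <- x
  out
}

#' Empirical-Bayes moderated one-sample t statistics
#'
#' For each gene, tests whether the mean log-ratio across replicate arrays
#' differs from zero, shrinking the per-gene sample variance towards a
#' common prior: the posterior variance is
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} with
#' residual df \eqn{d_g = n_g - 1}. The prior df \eqn{d_0} and scale
#' \eqn{s_0^2} are estimated from the observed variance distribution by
#' moment matching on the log variances (matching the mean and variance of
#' \eqn{\log s_g^2} to the scaled-F sampling theory). The moderated
#' statistic \eqn{t_g = \bar{M}_g / (\tilde{s}_g / \sqrt{n_g})} is referred
#' to a t distribution on \eqn{d_0 + d_g} df, two-sided.
#'
#' @param M numeric matrix genes x arrays of log-ratios for one strain
#'   (NAs allowed; genes need at least 2 finite values).
#' @param prior_df override the estimated prior df: `0` gives the ordinary
#'   one-sample t, `Inf` fully pools the variances; `NULL` (default)
#'   estimates it from the data.
#' @return data.frame `gene_id`, `mean_M`, `s2`, `s2_post`, `t`, `df`,
#'   `p` (moderated), `t_ordinary`, `p_ordinary`. Attributes `d0` and
#'   `s02` carry the estimated prior.
#' @export
moderated_t <- function(M, prior_df = NULL) {
  M <- as.matrix(M)
  n <- unname(rowSums(is.finite(M)))
  if (all(n < 2L)) stop("need at least 2 arrays per gene")
  mean_m <- unname(rowMeans(M, na.rm = TRUE))
  s2 <- unname(apply(M, 1L, stats::var, na.rm = TRUE))
  dg <- n - 1L
  est <- n >= 2L & is.finite(s2) & s2 > 0
  if (is.null(prior_df)) {
    z <- log(s2[est])
    e <- z - digamma(dg[est] / 2) + log(dg[est] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(dg[est] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2[est]) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * ifelse(is.finite(s2), s2, 0)) / (d0 + dg)
  df_tot <- pmin(d0 + dg, .Machine$double.xmax)
  tmod <- mean_m / sqrt(s2_post / n)
  p <- 2 * stats::pt(-abs(tmod), df = df_tot)
  t_ord <- mean_m / sqrt(s2 / n)
  p_ord <- 2 * stats::pt(-abs(t_ord), df = dg)
  bad <- n < 2L
  p[bad] <- NA; tmod[bad] <- NA; p_ord[bad] <- NA; t_ord[bad] <- NA
  out <- data.frame(gene_id = rownames(M) %||% seq_len(nrow(M)),
                    mean_M = mean_m, s2 = s2, s2_post = s2_post,
                    t = tmod, df = d0 + dg, p = p,
                    t_ordinary = t_ord, p_ordinary = p_ord,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-strain expression results
#'
#' Runs [gene_ratio_matrix()] and [moderated_t()] for every strain and
#' stacks the per-gene results with the average A per gene per strain, in
#' the long format consumed by [filter_de()].
#'
#' @param scans_by_strain named list (strain -> list of spot tables).
#' @param probe_map,span,iterations see [gene_ratio_matrix()].
#' @param prior_df see [moderated_t()].
#' @return data.frame `gene_id`, `strain`, `M`, `A`, `t`, `p`, `p_adj`
#'   (Benjamini-Hochberg within strain, informational), `p_ordinary`,
#'   `n_arrays`.
#' @export
expression_results <- function(scans_by_strain, probe_map = NULL,
                               span = 0.4, iterations = 3,
                               prior_df = NULL) {
  stopifnot(is.list(scans_by_strain), !is.null(names(scans_by_strain)))
  res <- lapply(names(scans_by_strain), function(s) {
    gm <- gene_ratio_matrix(scans_by_strain[[s]], probe_map, span,
                            iterations)
    mt <- moderated_t(gm$M, prior_df = prior_df)
    data.frame(gene_id = mt$gene_id, strain = s, M = mt$mean_M,
               A = rowMeans(gm$A, na.rm = TRUE), t = mt$t, p = mt$p,
               p_adj = stats::p.adjust(mt$p, "BH"),
               p_ordinary = mt$p_ordinary,
               n_arrays = rowSums(is.finite(gm$M)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Differential-expression filter
#'
#' A gene is called differentially expressed (DE) in a strain iff all of
#' `A > a_min`, `|M| > m_min` and `p < p_max` hold there (strict
#' inequalities; defaults A > 7.5, |M| > 1, p < 0.05). The DE union
#' contains every gene DE in at least one strain.
#'
#' @param results long data.frame from [expression_results()] (columns
#'   `gene_id`, `strain`, `M`, `A`, `p`).
#' @param a_min,m_min,p_max filter thresholds.
#' @return list of class `de_filter`: `flags` (logical genes x strains
#'   matrix; genes with missing M/A/p in a strain are `FALSE` there, with a
#'   warning), `union` (character vector of DE gene ids), and the
#'   thresholds.
#' @export
filter_de <- function(results, a_min = 7.5, m_min = 1.0, p_max = 0.05) {
  need <- c("gene_id", "strain", "M", "A", "p")
  stopifnot(all(need %in% names(results)))
  genes <- sort(unique(results$gene_id))
  strains <- unique(results$strain)
  flags <- matrix(FALSE, length(genes), length(strains),
                  dimnames = list(genes, strains))
  incomplete <- !stats::complete.cases(results[c("M", "A", "p")])
  if (any(incomplete))
    warning(sum(incomplete), " gene/strain records with missing M, A or p",
            " excluded from the DE filter")
  ok <- results[!incomplete, ]
  de <- ok$A > a_min & abs(ok$M) > m_min & ok$p < p_max
  flags[cbind(match(ok$gene_id, genes), match(ok$strain, strains))] <- de
  structure(list(flags = flags, union = genes[rowSums(flags) > 0],
                 a_min = a_min, m_min = m_min, p_max = p_max),
            class = "de_filter")
}

#' Venn partition of per-strain DE sets
#'
#' Partitions a gene universe into the 7 disjoint regions of a three-set
#' Venn diagram (or \eqn{2^k - 1} regions for k strains) plus the
#' complement of genes DE in no strain. Region counts always sum to the
#' universe size.
#'
#' @param flags logical genes x strains matrix (rownames = gene ids), as in
#'   [filter_de()]`$flags`.
#' @param universe character vector of universe gene ids (e.g. the
#'   commonset). Flags for genes outside the universe are an error;
#'   universe genes without flags count as not DE.
#' @return list of class `venn_partition`: `regions` (named counts, names
#'   like `"HMS174"`, `"HMS174+BL21"`, ...), `complement`, `union_size`,
#'   `universe_size`, `members` (gene ids per region).
#' @export
venn_partition <- function(flags, universe = rownames(flags)) {
  stopifnot(is.matrix(flags), is.logical(flags), !is.null(rownames(flags)))
  outside <- setdiff(rownames(flags), universe)
  if (length(outside))
    stop("flags present for genes outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  full <- matrix(FALSE, length(universe), ncol(flags),
                 dimnames = list(universe, colnames(flags)))
  full[rownames(flags), ] <- flags
  k <- ncol(full)
  strains <- colnames(full)
  key <- apply(full, 1L, function(r) paste(strains[r], collapse = "+"))
  region_names <- unlist(lapply(seq_len(k), function(m)
    utils::combn(strains, m, paste, collapse = "+")))
  counts <- stats::setNames(integer(length(region_names)), region_names)
  tab <- table(key[key != ""])
  counts[names(tab)] <- as.integer(tab)
  members <- split(universe, factor(key, levels = c("", region_names)))
  structure(list(regions = counts,
                 complement = sum(key == ""),
                 union_size = sum(key != ""),
                 universe_size = length(universe),
                 members = members[region_names]),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", x$universe_size, "genes\n")
  for (nm in names(x$regions))
    cat(sprintf("  %-28s %d\n", nm, x$regions[[nm]]))
  cat(sprintf("  %-28s %d\n", "none (complement)", x$complement))
  cat("union:", x$union_size, "\n")
  invisible(x)
}

#' Intersect gene lists of two array platforms
#'
#' The cross-platform "commonset": case-normalized, deduplicated, sorted
#' intersection of the gene identifier lists of two platforms.
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @return sorted character vector of shared (lower-cased) gene ids.
#' @export
intersect_platforms <- function(genes_a, genes_b) {
  if (!length(genes_a) || !length(genes_b))
    stop("empty platform gene list")
  sort(intersect(unique(tolower(genes_a)), unique(tolower(genes_b))))
}
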