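#' Ground truth for a simulated two-colour array experiment
#'
#' Defines per-gene baseline intensities, planted log2 fold changes per
#' strain relative to the common reference pool, two overlapping platforms,
#' and an intensity-dependent dye bias per print-tip group.
#'
#' Two platforms (one per genome) share a common gene set ("commonset");
#' each may carry platform-specific extra genes. The planted `lfc` matrix is
#' the expected log2 ratio of a strain sample over the pooled reference.
#'
#' @param gene_ids character vector of commonset gene ids (present on both
#'   platforms).
#' @param lfc numeric matrix, genes x strains, planted log2 fold change vs
#'   the reference pool (rownames = `gene_ids`, colnames = strain names).
#' @param base_log2 per-gene baseline log2 intensity (recycled; default
#'   drawn N(10, 1) at `seed`).
#' @param extra_a,extra_b character vectors of platform-specific gene ids
#'   (absent from the other platform; default none).
#' @param n_printtips number of print-tip groups per array.
#' @param tip_bias matrix `n_printtips` x 2 (intercept, slope of the linear
#'   intensity-dependent dye bias, in log2 units per unit A); default zeros.
#' @param spot_sd additive Gaussian noise sd of the raw log-ratio, log2
#'   units.
#' @param n_duplicates replicate spots per probe.
#' @param seed integer seed used when baselines are drawn.
#' @return object of class `array_truth`.
#' @export
array_truth <- function(gene_ids, lfc, base_log2 = NULL,
                        extra_a = character(), extra_b = character(),
                        n_printtips = 16L, tip_bias = NULL,
                        spot_sd = 0, n_duplicates = 1L, seed = 1L) {
  stopifnot(is.character(gene_ids), length(gene_ids) > 0,
            !anyDuplicated(gene_ids))
  lfc <- as.matrix(lfc)
  if (nrow(lfc) != length(gene_ids))
    stop("lfc must have one row per commonset gene")
  if (any(!is.finite(lfc))) stop("planted lfc must be finite")
  if (is.null(rownames(lfc))) rownames(lfc) <- gene_ids
  if (is.null(colnames(lfc)))
    colnames(lfc) <- paste0("strain", seq_len(ncol(lfc)))
  if (is.null(base_log2)) {
    set.seed(seed)
    base_log2 <- stats::rnorm(length(gene_ids), 10, 1)
  }
  base_log2 <- rep_len(base_log2, length(gene_ids))
  names(base_log2) <- gene_ids
  if (is.null(tip_bias)) tip_bias <- matrix(0, n_printtips, 2L)
  tip_bias <- as.matrix(tip_bias)
  stopifnot(nrow(tip_bias) == n_printtips, ncol(tip_bias) == 2L,
            spot_sd >= 0, n_duplicates >= 1L)
  structure(list(gene_ids = gene_ids, lfc = lfc, base_log2 = base_log2,
                 extra_a = extra_a, extra_b = extra_b,
                 n_printtips = as.integer(n_printtips),
                 tip_bias = tip_bias, spot_sd = spot_sd,
                 n_duplicates = as.integer(n_duplicates),
                 seed = as.integer(seed)),
            class = "array_truth")
}

#' Default synthetic array truth with planted differential expression
#'
#' Convenience constructor: `n_de` genes per strain get a planted log2 fold
#' change of +/-`lfc_size` (alternating sign), a configurable number of
#' genes are shared across all strains, the rest are null.
#'
#' @param n_genes commonset size.
#' @param strains strain names.
#' @param n_de planted differentially expressed genes per strain
#'   (strain-unique).
#' @param n_de_shared genes planted in all strains.
#' @param lfc_size absolute planted log2 fold change.
#' @param spot_sd log2 noise sd per spot.
#' @param n_printtips,seed see [array_truth()].
#' @param tip_bias_range intercepts drawn uniformly in +/- this range, with
#'   matched intensity-dependent slopes (set 0 for no dye bias).
#' @return an `array_truth` whose `lfc` matrix carries the planted effects;
#'   attribute `de_genes` lists the planted gene ids per strain.
#' @export
default_array_truth <- function(n_genes = 1000L,
                                strains = c("HMS174", "RV308", "BL21"),
                                n_de = 30L, n_de_shared = 10L, lfc_size = 2,
                                spot_sd = 0.3, n_printtips = 16L,
                                tip_bias_range = 0.3, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("gene%05d", seq_len(n_genes))
  lfc <- matrix(0, n_genes, length(strains),
                dimnames = list(ids, strains))
  total_de <- n_de * length(strains) + n_de_shared
  stopifnot(total_de <= n_genes)
  slots <- sample(n_genes, total_de)
  de <- list()
  offset <- 0L
  for (s in strains) {
    idx <- slots[offset + seq_len(n_de)]
    lfc[idx, s] <- lfc_size * rep_len(c(1, -1), n_de)
    de[[s]] <- ids[idx]
    offset <- offset + n_de
  }
  shared <- slots[offset + seq_len(n_de_shared)]
  lfc[shared, ] <- lfc_size * rep_len(c(1, -1), n_de_shared)
  for (s in strains) de[[s]] <- c(de[[s]], ids[shared])
  bias <- cbind(stats::runif(n_printtips, -tip_bias_range, tip_bias_range),
                stats::runif(n_printtips, -tip_bias_range / 10,
                             tip_bias_range / 10))
  if (tip_bias_range == 0) bias[] <- 0
  tr <- array_truth(ids, lfc, n_printtips = n_printtips, tip_bias = bias,
                    spot_sd = spot_sd, seed = seed)
  attr(tr, "de_genes") <- de
  tr
}

#' Dye-swap hybridization design against a common reference
#'
#' Each biological sample (strain x replicate) is hybridized twice against
#' the pooled reference, once with the sample in Cy5 and once in Cy3
#' (a dye-swap pair).
#'
#' @param strains strain names.
#' @param n_reps biological replicates per strain.
#' @param platform_of optional named vector strain -> platform
#'   (`"A"`/`"B"`); default `"A"` for all.
#' @return data.frame with columns `array_id`, `sample`, `strain`,
#'   `replicate`, `sample_dye` (`Cy5`/`Cy3`), `platform`.
#' @export
dye_swap_design <- function(strains = c("HMS174", "RV308", "BL21"),
                            n_reps = 3L, platform_of = NULL) {
  samples <- expand.grid(replicate = seq_len(n_reps), strain = strains,
                         stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$strain, "_r", samples$replicate)
  des <- samples[rep(seq_len(nrow(samples)), each = 2L), ]
  des$sample_dye <- rep(c("Cy5", "Cy3"), nrow(samples))
  des$array_id <- sprintf("array%03d", seq_len(nrow(des)))
  des$platform <- if (is.null(platform_of)) "A" else
    unname(platform_of[des$strain])
  rownames(des) <- NULL
  des[c("array_id", "sample", "strain", "replicate", "sample_dye",
        "platform")]
}

#' Simulate two-colour reference-design hybridizations
#'
#' Generates one GenePix-like spot table per array. The reference channel
#' measures the per-gene baseline intensity of the pooled reference; the
#' sample channel additionally carries the planted log2 fold change. The
#' observed raw log-ratio of the Cy5 over the Cy3 channel is
#' `orient * lfc + a_tip + b_tip * A + noise`, where `orient` is +1 when the
#' sample sits in Cy5 and -1 in the swapped pair member, and `(a, b)` is the
#' linear intensity-dependent dye bias of the spot's print-tip group (the
#' bias does *not* flip with the swap, which is what dye-swap designs
#' cancel).
#'
#' @param truth an [array_truth()].
#' @param design a design data.frame as from [dye_swap_design()].
#' @param seed integer seed for spot noise.
#' @return a list of spot tables (class `spot_table`), one per array, each a
#'   data.frame with columns `block`, `row`, `column`, `probe_id`,
#'   `F_ch1`, `F_ch2`, `dye_ch1`, `dye_ch2`, `sample_ch1`, `sample_ch2`
#'   (ch1 = Cy5 scan channel, ch2 = Cy3). Attribute `design` carries the
#'   design row.
#' @export
simulate_microarray <- function(truth, design, seed = truth$seed) {
  stopifnot(inherits(truth, "array_truth"))
  need <- c("array_id", "sample", "strain", "sample_dye", "platform")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(design$strain), colnames(truth$lfc))
  if (length(unknown))
    stop("design error: strain(s) absent from truth: ",
         paste(unknown, collapse = ", "))
  # sample_dye pairing sanity: each sample needs both orientations
  tab <- table(design$sample, design$sample_dye)
  if (!all(tab >= 1L))
    warning("not every sample is hybridized in both dye orientations")
  set.seed(seed)
  out <- vector("list", nrow(design))
  names(out) <- design$array_id
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    genes <- switch(row$platform,
                    A = c(truth$gene_ids, truth$extra_a),
                    B = c(truth$gene_ids, truth$extra_b),
                    c(truth$gene_ids))
    probes <- rep(genes, each = truth$n_duplicates)
    n <- length(probes)
    tip <- ((seq_len(n) - 1L) %% truth$n_printtips) + 1L
    idx <- match(probes, names(truth$base_log2))
    base <- rep(10, n)
    base[!is.na(idx)] <- truth$base_log2[idx[!is.na(idx)]]
    lidx <- match(probes, rownames(truth$lfc))
    lfc <- numeric(n)
    lfc[!is.na(lidx)] <- truth$lfc[lidx[!is.na(lidx)], row$strain]
    orient <- if (row$sample_dye == "Cy5") 1 else -1
    bias <- truth$tip_bias[tip, 1L] + truth$tip_bias[tip, 2L] * base
    m_raw <- orient * lfc + bias +
      if (truth$spot_sd > 0) stats::rnorm(n, 0, truth$spot_sd) else 0
    a <- base
    f_cy5 <- 2^(a + m_raw / 2)
    f_cy3 <- 2^(a - m_raw / 2)
    st <- data.frame(block = tip,
                     row = ((seq_len(n) - 1L) %/% truth$n_printtips) + 1L,
                     column = 1L,
                     probe_id = probes,
                     F_ch1 = f_cy5, F_ch2 = f_cy3,
                     dye_ch1 = "Cy5", dye_ch2 = "Cy3",
                     sample_ch1 = if (orient == 1) row$sample else "pool",
                     sample_ch2 = if (orient == 1) "pool" else row$sample,
                     stringsAsFactors = FALSE)
    attr(st, "design") <- row
    class(st) <- c("spot_table", "data.frame")
    out[[i]] <- st
  }
  out
}
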