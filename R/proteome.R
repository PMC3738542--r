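#' Internal-standard standardized abundances
#'
#' Divides every sample channel volume by the Cy2 internal-standard volume
#' of the same spot on the same gel, yielding cross-gel comparable
#' standardized abundances.
#'
#' @param gels a `dige_spot_table` or list of them (see [simulate_dige()]
#'   or [read_dige_table()]).
#' @return long data.frame `spot_id`, `gel_id`, `sample`, `ph_range`,
#'   `abundance` (volume / Cy2 volume). Spots with non-positive Cy2 volume
#'   are dropped with a warning; a sample channel missing on a gel yields
#'   no row (missing, not zero).
#' @export
standardize_abundance <- function(gels) {
  if (is.data.frame(gels)) gels <- list(gels)
  rows <- lapply(gels, function(g) {
    need <- c("spot_id", "gel_id", "cy2_vol", "cy3_vol", "cy5_vol",
              "sample_cy3", "sample_cy5", "ph_range")
    stopifnot(all(need %in% names(g)))
    bad <- !is.finite(g$cy2_vol) | g$cy2_vol <= 0
    if (any(bad))
      warning(sum(bad), " spot(s) with non-positive Cy2 volume dropped on ",
              g$gel_id[1L])
    g <- g[!bad, ]
    out <- list()
    for (ch in c("cy3", "cy5")) {
      vol <- g[[paste0(ch, "_vol")]]
      smp <- g[[paste0("sample_", ch)]]
      keep <- !is.na(smp) & is.finite(vol) & vol > 0
      if (any(keep))
        out[[ch]] <- data.frame(spot_id = g$spot_id[keep],
                                gel_id = g$gel_id[keep],
                                sample = smp[keep],
                                ph_range = g$ph_range[keep],
                                abundance = vol[keep] / g$cy2_vol[keep],
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed fold change (DeCyder convention)
#'
#' Ratios at or above 1 are reported as-is; ratios below 1 as the negative
#' reciprocal, so magnitudes are symmetric about +/-1 and
#' `signed_fold_change(a, b) == -signed_fold_change(b, a)` whenever the
#' ratio differs from 1.
#'
#' @param mean_a,mean_b positive group mean abundances (vectorized).
#' @return signed fold change(s) with `|f| >= 1`.
#' @examples
#' signed_fold_change(2, 1)  # +2
#' signed_fold_change(1, 2)  # -2
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a) | !is.finite(mean_b) |
            mean_a <= 0 | mean_b <= 0, na.rm = TRUE))
    stop("domain error: means must be positive")
  r <- mean_a / mean_b
  ifelse(r >= 1, r, -1 / r)
}

#' Per-spot strain-pair protein contrasts
#'
#' For one pair of strains, computes per spot the signed fold change of the
#' group means of standardized abundance (`strain_a` over `strain_b`) and a
#' two-sample Student's t-test (equal variance by default) on the
#' standardized abundances.
#'
#' @param abund long standardized-abundance data.frame (see
#'   [standardize_abundance()]).
#' @param groups named character vector sample -> strain.
#' @param strain_a,strain_b the two strains to contrast (ratio is a over
#'   b).
#' @param var_equal `TRUE` for the classical Student's t (default),
#'   `FALSE` for Welch.
#' @param paired pair observations by gel (requires both strains on each
#'   gel); default unpaired.
#' @return data.frame of class `protein_contrast`: `spot_id`, `pair`,
#'   `ph_range`, `ratio` (signed fold), `p`, `n_a`, `n_b`. Spots with
#'   fewer than 2 replicates in either group are skipped with a warning.
#' @export
protein_contrasts <- function(abund, groups, strain_a, strain_b,
                              var_equal = TRUE, paired = FALSE) {
  stopifnot(all(c("spot_id", "sample", "abundance") %in% names(abund)))
  abund$strain <- unname(groups[abund$sample])
  ab <- abund[abund$strain %in% c(strain_a, strain_b), ]
  res <- lapply(split(ab, ab$spot_id), function(d) {
    xa <- d$abundance[d$strain == strain_a]
    xb <- d$abundance[d$strain == strain_b]
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    p <- tryCatch({
      if (paired) {
        da <- d[d$strain == strain_a, ]
        db <- d[d$strain == strain_b, ]
        common <- intersect(da$gel_id, db$gel_id)
        if (length(common) < 2L) return(NULL)
        stats::t.test(da$abundance[match(common, da$gel_id)],
                      db$abundance[match(common, db$gel_id)],
                      paired = TRUE)$p.value
      } else {
        stats::t.test(xa, xb, var.equal = var_equal)$p.value
      }
    }, error = function(e) NA_real_)
    data.frame(spot_id = d$spot_id[1L],
               pair = paste0(strain_a, "-", strain_b),
               ph_range = d$ph_range[1L],
               ratio = signed_fold_change(mean(xa), mean(xb)),
               p = p, n_a = length(xa), n_b = length(xb),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0)
    warning(skipped, " spot(s) skipped: fewer than 2 replicates per group")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("protein_contrast", "data.frame")
  out
}

#' Filter significantly altered protein spots
#'
#' A spot is altered iff its absolute signed average ratio exceeds
#' `ratio_min` *and* its Student's t-test p-value is below `p_max`
#' (strict inequalities; defaults |ratio| > 2.0 and p < 0.01, so a spot at
#' exactly 2.0-fold is not altered).
#'
#' @param contrasts a `protein_contrast` data.frame
#'   ([protein_contrasts()]).
#' @param ratio_min,p_max thresholds.
#' @return the altered subset, with an `altered` logical column added to
#'   the full table in attribute `full`.
#' @export
dige_filter <- function(contrasts, ratio_min = 2.0, p_max = 0.01) {
  stopifnot(all(c("ratio", "p") %in% names(contrasts)))
  altered <- !is.na(contrasts$p) & abs(contrasts$ratio) > ratio_min &
    contrasts$p < p_max
  contrasts$altered <- altered
  out <- contrasts[altered, ]
  attr(out, "full") <- contrasts
  out
}

#' Count altered spots by pI range
#'
#' Tabulates altered spots into acidic (pI 4-7), basic (pI 6-11) and total
#' counts, per strain pair if several are present.
#'
#' @param altered data.frame of altered spots with `ph_range` and
#'   optionally `pair` columns (see [dige_filter()]).
#' @return data.frame `pair`, `acidic`, `basic`, `total`.
#' @export
count_by_range <- function(altered) {
  stopifnot("ph_range" %in% names(altered))
  if (nrow(altered) > 0 &&
      any(is.na(altered$ph_range) |
            !altered$ph_range %in% c("acidic", "basic")))
    stop("untagged spot: ph_range must be 'acidic' or 'basic'")
  pairs <- if ("pair" %in% names(altered) && nrow(altered) > 0)
    unique(altered$pair) else "all"
  rows <- lapply(pairs, function(p) {
    d <- if ("pair" %in% names(altered))
      altered[altered$pair == p, ] else altered
    data.frame(pair = p,
               acidic = sum(d$ph_range == "acidic"),
               basic = sum(d$ph_range == "basic"),
               total = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pair = "all", acidic = 0L, basic = 0L, total = 0L)
  out
}
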