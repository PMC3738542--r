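#' Ground truth for a simulated DIGE experiment
#'
#' Per-spot protein abundance levels per strain (linear scale, relative to
#' an arbitrary unit); the internal standard on every gel is the pooled
#' mean of all samples. Planted abundance ratios between strains are the
#' ratios of these levels.
#'
#' @param spot_ids character vector of spot ids.
#' @param abundance numeric matrix spots x strains of positive abundance
#'   levels (rownames = spot ids).
#' @param ph_range character vector per spot: `"acidic"` (pI 4-7) or
#'   `"basic"` (pI 6-11); recycled.
#' @param base_volume per-spot base spot volume scale (recycled; default
#'   drawn lognormal at `seed`).
#' @param noise_sdlog sd of the multiplicative lognormal volume noise (in
#'   natural-log units; 0 = noiseless).
#' @param seed integer seed.
#' @return object of class `dige_truth`.
#' @export
dige_truth <- function(spot_ids, abundance, ph_range = "acidic",
                       base_volume = NULL, noise_sdlog = 0, seed = 1L) {
  stopifnot(is.character(spot_ids), !anyDuplicated(spot_ids))
  abundance <- as.matrix(abundance)
  stopifnot(nrow(abundance) == length(spot_ids), all(abundance > 0))
  if (is.null(rownames(abundance))) rownames(abundance) <- spot_ids
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("strain", seq_len(ncol(abundance)))
  ph_range <- rep_len(ph_range, length(spot_ids))
  stopifnot(all(ph_range %in% c("acidic", "basic")))
  if (is.null(base_volume)) {
    set.seed(seed)
    base_volume <- stats::rlnorm(length(spot_ids), log(1000), 0.5)
  }
  base_volume <- rep_len(base_volume, length(spot_ids))
  stopifnot(noise_sdlog >= 0)
  structure(list(spot_ids = spot_ids, abundance = abundance,
                 ph_range = ph_range, base_volume = base_volume,
                 noise_sdlog = noise_sdlog, seed = as.integer(seed)),
            class = "dige_truth")
}

#' Simulate DIGE gels with a Cy2 internal standard
#'
#' Each gel carries two samples (Cy3 and Cy5) plus the pooled internal
#' standard in Cy2. Spot volumes are the per-spot base volume times the
#' strain abundance (or the pooled mean for the standard), a gel-specific
#' multiplicative effect, and lognormal noise. Standardizing against Cy2
#' (see [standardize_abundance()]) cancels the gel effect, so
#' standardized-abundance ratios recover the planted ratios in expectation.
#'
#' @param truth a [dige_truth()].
#' @param samples data.frame with columns `sample`, `strain` (one row per
#'   biological sample to run).
#' @param n_gels number of gels (must satisfy `2 * n_gels >=
#'   nrow(samples)`).
#' @param seed integer seed.
#' @return list of data.frames (class `dige_spot_table`), one per gel, with
#'   columns `spot_id`, `gel_id`, `cy2_vol`, `cy3_vol`, `cy5_vol`,
#'   `sample_cy3`, `sample_cy5`, `ph_range`.
#' @export
simulate_dige <- function(truth, samples, n_gels = ceiling(nrow(samples) / 2),
                          seed = truth$seed) {
  stopifnot(inherits(truth, "dige_truth"),
            all(c("sample", "strain") %in% names(samples)))
  unknown <- setdiff(unique(samples$strain), colnames(truth$abundance))
  if (length(unknown))
    stop("design error: strain(s) absent from truth: ",
         paste(unknown, collapse = ", "))
  if (2L * n_gels < nrow(samples))
    stop("design error: ", n_gels, " gels cannot carry ",
         nrow(samples), " samples (2 per gel)")
  set.seed(seed)
  pool <- rowMeans(truth$abundance[, unique(samples$strain), drop = FALSE])
  n_spots <- length(truth$spot_ids)
  sdl <- truth$noise_sdlog
  noise <- function() if (sdl > 0) stats::rlnorm(n_spots, 0, sdl) else 1
  gels <- vector("list", n_gels)
  for (g in seq_len(n_gels)) {
    i3 <- 2L * g - 1L
    i5 <- 2L * g
    s3 <- samples$sample[i3]
    s5 <- if (i5 <= nrow(samples)) samples$sample[i5] else NA_character_
    gel_eff <- stats::rlnorm(1, 0, if (sdl > 0) 0.2 else 0)
    cy2 <- truth$base_volume * pool * gel_eff * noise()
    cy3 <- truth$base_volume *
      truth$abundance[, samples$strain[i3]] * gel_eff * noise()
    cy5 <- if (is.na(s5)) rep(NA_real_, n_spots) else
      truth$base_volume * truth$abundance[, samples$strain[i5]] *
        gel_eff * noise()
    tab <- data.frame(spot_id = truth$spot_ids,
                      gel_id = sprintf("gel%02d", g),
                      cy2_vol = cy2, cy3_vol = cy3, cy5_vol = cy5,
                      sample_cy3 = s3, sample_cy5 = s5,
                      ph_range = truth$ph_range,
                      stringsAsFactors = FALSE)
    class(tab) <- c("dige_spot_table", "data.frame")
    gels[[g]] <- tab
  }
  gels
}
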