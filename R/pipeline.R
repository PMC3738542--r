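#' Pipeline configuration
#'
#' Bundles strain presets, design sizes, filter thresholds and seeds for an
#' end-to-end synthetic run: batch simulation, process metrics,
#' transcriptome differential expression, DIGE proteome contrasts,
#' transcript-protein integration and category tallies.
#'
#' @param strains named list strain -> [strain_kinetics()]; default the
#'   three built-in presets named HMS174, RV308, BL21.
#' @param n_replicates replicate cultivations / biological samples per
#'   strain.
#' @param n_genes commonset size of the synthetic arrays.
#' @param n_de,n_de_shared,lfc_size,spot_sd,tip_bias_range see
#'   [default_array_truth()].
#' @param n_spots number of DIGE spots.
#' @param a_min,m_min,p_max DE filter thresholds ([filter_de()]).
#' @param ratio_min,p_max_dige DIGE filter thresholds ([dige_filter()]).
#' @param loess_span,loess_iterations normalization settings.
#' @param noise_cv process measurement noise CV.
#' @param report_digits rounding used in rendered reports.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(strains = list(HMS174 = strain_preset("K12_HMS_like"),
                                           RV308 = strain_preset("K12_RV_like"),
                                           BL21 = strain_preset("B_like")),
                            n_replicates = 3L, n_genes = 600L, n_de = 25L,
                            n_de_shared = 10L, lfc_size = 2, spot_sd = 0.3,
                            tip_bias_range = 0.3, n_spots = 120L,
                            a_min = 7.5, m_min = 1.0, p_max = 0.05,
                            ratio_min = 2.0, p_max_dige = 0.01,
                            loess_span = 0.4, loess_iterations = 3L,
                            noise_cv = 0.02, report_digits = 2L,
                            seed = 1L) {
  stopifnot(length(strains) >= 2L, !is.null(names(strains)),
            all(vapply(strains, inherits, logical(1), "strain_kinetics")),
            a_min > 0, m_min > 0, p_max > 0, ratio_min > 0, p_max_dige > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed derivation, kept within 32-bit range
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 9973L) %% 2147483587L
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> process -> transcriptome -> proteome -> integrate
#' -> annotate on synthetic data with known ground truth and writes all
#' artifacts plus a manifest (with md5 hashes of every output) to
#' `out_dir`. The run is fully reproducible from the config alone.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return invisible list with the in-memory results of every stage
#'   (`process`, `expression`, `de`, `venn`, `proteome`, `integration`,
#'   `annotation`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  artifacts <- character()
  emit <- function(obj, name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
  }
  strains <- names(config$strains)

  ## 1. batch simulations + process metrics -------------------------------
  sims <- list()
  proc_rows <- list()
  for (s in strains) {
    for (r in seq_len(config$n_replicates)) {
      sc <- batch_scenario(config$strains[[s]], noise_cv = config$noise_cv,
                           seed = .stage_seed(config$seed,
                                              match(s, strains) * 10L + r))
      sim <- simulate_batch(sc)
      key <- paste0(s, "_r", r)
      sims[[key]] <- sim
      emit(sim$measured, paste0("series_", key, ".tsv"),
           write_process_series)
      k <- config$strains[[s]]
      st <- sim$state
      expo <- st$time_h >= k$lag_duration + 0.2 &
        st$glucose_g_per_L > 0.25 * sc$S0
      gr <- fit_growth_rate(process_series(st, volume = sc$volume),
                            window = range(st$time_h[expo]))
      last <- nrow(st)
      proc_rows[[key]] <- data.frame(
        strain = s, replicate = r,
        mu_fit = gr$rate, mu_average = gr$average_rate,
        final_cdm = st$cdm_g_per_L[last],
        max_acetate = max(st$acetate_g_per_L),
        stringsAsFactors = FALSE)
    }
  }
  proc <- do.call(rbind, proc_rows)
  rownames(proc) <- NULL

  summaries <- do.call(rbind, lapply(strains, function(s) {
    d <- proc[proc$strain == s, ]
    f <- function(v) {
      z <- summarize_replicates(v)
      c(z$mean, z$sem)
    }
    cdm <- f(d$final_cdm); ac <- f(d$max_acetate); mu <- f(d$mu_fit)
    data.frame(strain = s, final_cdm_mean = cdm[1], final_cdm_sem = cdm[2],
               acetate_mean = ac[1], acetate_sem = ac[2],
               mu_mean = mu[1], mu_sem = mu[2], n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  balances <- lapply(strains, function(s) {
    sim <- sims[[paste0(s, "_r1")]]
    sc <- sim$scenario
    st <- sim$state
    consumed <- (sc$S0 - st$glucose_g_per_L[nrow(st)]) * sc$volume
    total_c <- consumed * carbon_fraction(composition_glucose()) +
      sc$X0 * sc$volume * carbon_fraction(composition_biomass())
    carbon_balance(process_series(st, volume = sc$volume), total_c)
  })
  names(balances) <- strains
  yields <- do.call(rbind, lapply(strains, function(s) {
    d <- summaries[summaries$strain == s, ]
    sc0 <- sims[[paste0(s, "_r1")]]$scenario
    y <- yield_coefficients(d$final_cdm_mean, sc0$S0, d$acetate_mean)
    data.frame(strain = s, yxs_raw = y$yxs_raw,
               yxs_corrected = y$yxs_corrected,
               glucose_equivalent = y$glucose_equivalent_of_byproduct,
               stringsAsFactors = FALSE)
  }))
  process_out <- list(per_run = proc, summaries = summaries,
                      yields = yields, balances = balances)
  emit(proc, "process_per_run.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(summaries, "process_summaries.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(yields, "process_yields.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## 2. transcriptome ------------------------------------------------------
  truth <- default_array_truth(
    n_genes = config$n_genes, strains = strains, n_de = config$n_de,
    n_de_shared = config$n_de_shared, lfc_size = config$lfc_size,
    spot_sd = config$spot_sd, tip_bias_range = config$tip_bias_range,
    seed = .stage_seed(config$seed, 101L))
  design <- dye_swap_design(strains, config$n_replicates)
  scans <- simulate_microarray(truth, design,
                               seed = .stage_seed(config$seed, 102L))
  scans_by_strain <- lapply(strains, function(s)
    scans[design$array_id[design$strain == s]])
  names(scans_by_strain) <- strains
  expr <- expression_results(scans_by_strain, span = config$loess_span,
                             iterations = config$loess_iterations)
  de <- filter_de(expr, config$a_min, config$m_min, config$p_max)
  venn <- venn_partition(de$flags, universe = truth$gene_ids)
  emit(expr, "expression_results.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(venn, "venn.json", function(o, p)
    jsonlite::write_json(list(regions = as.list(o$regions),
                              complement = o$complement,
                              union = o$union_size,
                              universe = o$universe_size),
                         p, auto_unbox = TRUE))

  ## 3. proteome -----------------------------------------------------------
  set.seed(.stage_seed(config$seed, 201L))
  spot_ids <- sprintf("spot%04d", seq_len(config$n_spots))
  ab <- matrix(1, config$n_spots, length(strains),
               dimnames = list(spot_ids, strains))
  n_alt <- max(4L, config$n_spots %/% 10L)
  alt_idx <- sample(config$n_spots, n_alt)
  for (j in seq_along(alt_idx))
    ab[alt_idx[j], sample(strains, 1L)] <- sample(c(4, 0.25), 1L)
  dtruth <- dige_truth(spot_ids, ab,
                       ph_range = sample(c("acidic", "basic"),
                                         config$n_spots, TRUE,
                                         prob = c(0.8, 0.2)),
                       noise_sdlog = 0.1,
                       seed = .stage_seed(config$seed, 202L))
  samples <- expand.grid(replicate = seq_len(config$n_replicates * 2L),
                         strain = strains, stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$strain, "_s", samples$replicate)
  gels <- simulate_dige(dtruth, samples,
                        seed = .stage_seed(config$seed, 203L))
  abund <- standardize_abundance(gels)
  groups <- stats::setNames(samples$strain, samples$sample)
  pairs <- utils::combn(strains, 2L)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
    protein_contrasts(abund, groups, pairs[2L, j], pairs[1L, j])))
  altered <- dige_filter(contrasts, config$ratio_min, config$p_max_dige)
  range_counts <- count_by_range(altered)
  emit(contrasts, "protein_contrasts.tsv", function(o, p)
    utils::write.table(as.data.frame(o), p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit(range_counts, "altered_by_range.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))
  for (g in gels)
    emit(g, paste0("dige_", g$gel_id[1L], ".tsv"), write_dige_table)

  ## 4. integration --------------------------------------------------------
  m_wide <- do.call(cbind, lapply(strains, function(s) {
    d <- expr[expr$strain == s, ]
    stats::setNames(d$M, d$gene_id)[truth$gene_ids]
  }))
  colnames(m_wide) <- strains
  rownames(m_wide) <- truth$gene_ids
  gene_contr <- pairwise_gene_contrast(m_wide)
  # synthetic spot->gene map: altered spots mapped onto the planted genes
  de_truth <- attr(truth, "de_genes")
  mapped_genes <- unique(unlist(de_truth))
  n_map <- min(length(alt_idx), length(mapped_genes))
  spot_map <- data.frame(spot_id = spot_ids[alt_idx][seq_len(n_map)],
                         gene_id = mapped_genes[seq_len(n_map)],
                         stringsAsFactors = FALSE)
  integ <- contrast_table(contrasts, gene_contr, spot_map)
  emit(integ, "integration_table.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## 5. annotation ---------------------------------------------------------
  set.seed(.stage_seed(config$seed, 301L))
  terms <- c("transport", "iron-acquisition", "motility", "regulation",
             "metabolism")
  ann_map <- data.frame(
    gene = truth$gene_ids,
    term = sample(terms, config$n_genes, TRUE),
    stringsAsFactors = FALSE)
  tallies <- lapply(strains, function(s)
    category_tally(rownames(de$flags)[de$flags[, s]], ann_map, k = 5L))
  names(tallies) <- strains
  ann_out <- do.call(rbind, lapply(strains, function(s) {
    t <- tallies[[s]]
    if (nrow(t) == 0L) return(NULL)
    cbind(strain = s, t)
  }))
  emit(ann_out, "annotation_tallies.tsv", function(o, p)
    utils::write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## manifest --------------------------------------------------------------
  manifest <- NULL
  if (!is.null(out_dir)) {
    hashes <- tools::md5sum(artifacts)
    manifest <- list(seed = config$seed,
                     strains = strains,
                     thresholds = list(A = config$a_min, M = config$m_min,
                                       p = config$p_max,
                                       ratio = config$ratio_min,
                                       p_dige = config$p_max_dige),
                     files = as.list(stats::setNames(unname(hashes),
                                                     basename(artifacts))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(process = process_out, expression = expr, de = de,
                 venn = venn, proteome = list(contrasts = contrasts,
                                              altered = altered,
                                              by_range = range_counts,
                                              truth = dtruth),
                 integration = integ, annotation = tallies,
                 array_truth = truth, manifest = manifest))
}
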