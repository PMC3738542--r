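#' Read and write the process time-series TSV dialect
#'
#' Tab-separated, UTF-8, decimal point, header row with columns `time_h`,
#' `cdm_g_per_L`, `glucose_g_per_L`, `acetate_g_per_L`, `formate_g_per_L`,
#' `pyruvate_g_per_L`, `lactate_g_per_L`, `co2_rate_gC_per_L_h`.
#'
#' @param path file path.
#' @param volume,co2_cumulative see [process_series()].
#' @return a [process_series()].
#' @export
read_process_series <- function(path, volume = 4, co2_cumulative = FALSE) {
  d <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  process_series(d, volume = volume, co2_cumulative = co2_cumulative)
}

#' @rdname read_process_series
#' @param series a [process_series()].
#' @export
write_process_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write GenePix-like spot tables
#'
#' Tab-separated with columns `block`, `row`, `column`, `probe_id`,
#' `F_ch1`, `F_ch2`, `dye_ch1`, `dye_ch2`, `sample_ch1`, `sample_ch2`.
#'
#' @param path file path.
#' @return a `spot_table` data.frame.
#' @export
read_spot_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  need <- c("block", "probe_id", "F_ch1", "F_ch2", "sample_ch1",
            "sample_ch2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(d) <- c("spot_table", "data.frame")
  d
}

#' @rdname read_spot_table
#' @param spots a `spot_table`.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(as.data.frame(spots), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write DIGE spot tables
#'
#' Tab-separated with columns `spot_id`, `gel_id`, `cy2_vol`, `cy3_vol`,
#' `cy5_vol`, `sample_cy3`, `sample_cy5`, `ph_range`.
#'
#' @param path file path.
#' @return a `dige_spot_table` data.frame.
#' @export
read_dige_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  need <- c("spot_id", "gel_id", "cy2_vol", "cy3_vol", "cy5_vol",
            "sample_cy3", "sample_cy5", "ph_range")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(d) <- c("dige_spot_table", "data.frame")
  d
}

#' @rdname read_dige_table
#' @param gel a `dige_spot_table`.
#' @export
write_dige_table <- function(gel, path) {
  utils::write.table(as.data.frame(gel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column annotation map (gene, term)
#' @param path TSV file with columns `gene`, `term` (header required).
#' @return data.frame usable by [category_tally()].
#' @export
read_annotation_map <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(d)))
    stop("annotation map needs columns 'gene' and 'term'")
  d
}
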