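#' Read a biomass ensemble from CSV or single-band TIFF
#'
#' CSV files must carry a `biomass_gC_m2` column (one value per pixel).
#' TIFF files are read as a single-band image via the `tiff` package
#' (installed separately); non-finite pixels (NaN nodata) are excluded
#' from the ensemble and georeferencing metadata is ignored.
#'
#' @param path File path ending in `.csv`, `.tif` or `.tiff`.
#' @param pixel_edge Pixel edge length in metres.
#' @param nodata Optional sentinel value to exclude (in addition to
#'   non-finite pixels) when reading TIFF.
#' @return A [biomass_ensemble()].
#' @export
read_biomass <- function(path, pixel_edge = 25, nodata = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!"biomass_gC_m2" %in% names(df))
      .stopf("CSV %s must have a `biomass_gC_m2` column", path)
    return(biomass_ensemble(df$biomass_gC_m2, pixel_edge = pixel_edge))
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      .stopf("reading TIFF requires the `tiff` package")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) > 2L) .stopf("TIFF %s must be single-band", path)
    v <- as.vector(img)
    v <- v[is.finite(v)]
    if (!is.null(nodata)) v <- v[v != nodata]
    if (length(v) == 0L) .stopf("TIFF %s holds no valid pixels", path)
    return(biomass_ensemble(v, pixel_edge = pixel_edge))
  }
  .stopf("unsupported biomass file format: .%s (use .csv or .tif)", ext)
}

#' Write a biomass ensemble to CSV
#'
#' Single column `biomass_gC_m2`, one row per pixel.
#'
#' @param ensemble A [biomass_ensemble()] (or bare numeric vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biomass_csv <- function(ensemble, path) {
  v <- if (inherits(ensemble, "biomass_ensemble")) ensemble$values
       else ensemble
  utils::write.csv(data.frame(biomass_gC_m2 = v), path, row.names = FALSE)
  invisible(path)
}

#' Write an observation pair as two CSVs plus a metadata sidecar
#'
#' Produces `<prefix>_t1.csv`, `<prefix>_t2.csv` and `<prefix>_meta.json`
#' (separation years, pixel edge, and the generating regime and seed when
#' the pair is synthetic).
#'
#' @param pair An [observation_pair()].
#' @param prefix Output path prefix.
#' @param seed Optional seed recorded in the sidecar.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_pair <- function(pair, prefix, seed = NULL) {
  if (!inherits(pair, "observation_pair"))
    .stopf("`pair` must be an observation_pair object")
  p1 <- paste0(prefix, "_t1.csv")
  p2 <- paste0(prefix, "_t2.csv")
  pm <- paste0(prefix, "_meta.json")
  write_biomass_csv(pair$obs_t1, p1)
  write_biomass_csv(pair$obs_t2, p2)
  meta <- list(separation_years = pair$separation_years,
               pixel_edge = pair$obs_t1$pixel_edge,
               n = length(pair$obs_t1$values))
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(pair$truth))
    meta$regime <- regime_to_list(pair$truth$regime)
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA)
  invisible(c(t1 = p1, t2 = p2, meta = pm))
}

#' Read an observation pair written by [write_pair()]
#'
#' @param prefix The path prefix used when writing.
#' @return An [observation_pair()] (truth regime, if recorded, is kept in
#'   the `truth` slot).
#' @export
read_pair <- function(prefix) {
  pm <- paste0(prefix, "_meta.json")
  if (!file.exists(pm)) .stopf("sidecar not found: %s", pm)
  meta <- jsonlite::read_json(pm, simplifyVector = TRUE)
  edge <- if (is.null(meta$pixel_edge)) 25 else meta$pixel_edge
  o1 <- read_biomass(paste0(prefix, "_t1.csv"), pixel_edge = edge)
  o2 <- read_biomass(paste0(prefix, "_t2.csv"), pixel_edge = edge)
  truth <- if (!is.null(meta$regime))
    list(regime = regime_from_list(meta$regime)) else NULL
  observation_pair(o1, o2, meta$separation_years, truth = truth)
}

#' Write or read an experiment results table
#'
#' Plain CSV serialisation of the per-case results data frame produced by
#' [run_test1()] and friends; reading reproduces the frame losslessly.
#'
#' @param results A results data frame.
#' @param path CSV path.
#' @return `write_results_csv()` returns `path` invisibly;
#'   `read_results_csv()` returns the data frame.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a fit's likelihood surface to JSON
#'
#' @param fit A `regime_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_surface_json <- function(fit, path) {
  if (!inherits(fit, "regime_fit")) .stopf("`fit` must be a regime_fit object")
  s <- fit$surface
  out <- list(e_p_axis = s$e_p_axis, e_i_axis = s$e_i_axis,
              log_lik = apply(s$log_lik, 1, identity, simplify = FALSE),
              lik_norm = apply(s$lik_norm, 1, identity, simplify = FALSE),
              argmax = regime_to_list(fit$argmax),
              level = fit$region$level,
              summaries = as.list(as.data.frame(t(fit$summaries))))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
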