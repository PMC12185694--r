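#' Mean ROI time series from a 4D volume
#'
#' @param volume4d 4D numeric array `(x, y, z, t)` or an `RNifti` image.
#' @param mask 3D logical/0-1 array on the same grid.
#' @param dt Seconds per frame (TR).
#' @return A time-series tibble (per-frame mean over mask voxels).
#' @export
extract_roi_series <- function(volume4d, mask, dt) {
  vol <- unclass(volume4d)
  dims <- dim(vol)
  stopifnot(length(dims) == 4, all(dim(mask) == dims[1:3]))
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("Empty ROI mask.", call. = FALSE)
  mat <- matrix(vol, nrow = prod(dims[1:3]), ncol = dims[4])
  ts_tibble(colMeans(mat[idx, , drop = FALSE]), dt)
}

# 1D Gaussian kernel, normalized; sigma in voxels.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with reflective boundary.
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1) return(arr)
  half <- (length(k) - 1) / 2
  apply_fun <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(pmax(half:1, 1), n)], v, v[pmin(pmax(n - (1:half) + 1, 1), n)])
    stats::convolve(pad, rev(k), type = "filter")
  }
  margins <- setdiff(1:3, axis)
  out <- apply(arr, margins, apply_fun)
  # apply() puts the processed axis first; restore the original order
  aperm(out, order(c(axis, margins)))
}

#' Spatial Gaussian smoothing of a volume
#'
#' Separable Gaussian with `sigma = fwhm / 2.3548` per axis, specified in
#' mm and converted by the voxel size; applied frame-wise to 4D input.
#' Boundaries are reflected so the total image sum is preserved.
#'
#' @param vol 3D or 4D numeric array.
#' @param fwhm Full width at half maximum in mm (0 = identity).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return Smoothed array, same shape.
#' @export
gaussian_smooth <- function(vol, fwhm, voxel_size = 1) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(vol)
  voxel_size <- rep(voxel_size, length.out = 3)
  sigmas <- (fwhm / 2.3548) / voxel_size
  smooth3 <- function(a) {
    for (ax in 1:3) a <- conv_axis(a, gauss_kernel(sigmas[ax]), ax)
    a
  }
  dims <- dim(vol)
  if (length(dims) == 3) return(smooth3(vol))
  stopifnot(length(dims) == 4)
  out <- vol
  for (f in seq_len(dims[4])) out[, , , f] <- smooth3(vol[, , , f])
  out
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti keeping the package's single volumetric
#' format in one place. `write_volume_nifti()` stores the TR (seconds) in
#' the 4th pixdim slot for 4D data.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti()` returns the image as a plain array with a
#'   `pixdim` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @param vol Numeric array (3D or 4D).
#' @param voxel_size Voxel edge lengths in mm.
#' @param tr Repetition time in seconds (4D only).
#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(vol, path, voxel_size = 1, tr = NULL) {
  voxel_size <- rep(voxel_size, length.out = 3)
  pd <- if (length(dim(vol)) == 4) c(voxel_size, tr %||% 1) else voxel_size
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- pd
  tmp <- file.path(dirname(path), paste0(".tmp-", basename(path)))
  RNifti::writeNifti(img, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a six-column rigid-body motion table
#'
#' Whitespace- or tab-delimited, one row per frame, columns ordered
#' x, y, z (mm), pitch, roll, yaw (radians); a header row is detected and
#' skipped.
#'
#' @param path File path.
#' @return A tibble with columns `x`, `y`, `z`, `pitch`, `roll`, `yaw`.
#' @export
read_motion_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- suppressWarnings(any(is.na(as.numeric(strsplit(trimws(first), "\\s+")[[1]]))))
  x <- utils::read.table(path, header = has_header)
  if (ncol(x) < 6) stop("Motion table needs 6 columns.", call. = FALSE)
  names(x)[1:6] <- c("x", "y", "z", "pitch", "roll", "yaw")
  tibble::as_tibble(x[, 1:6])
}

#' Run the simulate-and-analyse pipeline from a config
#'
#' Executes the requested stages in order on synthetic data and writes each
#' stage's result plus a manifest (parameters, seed, package version) under
#' `out_dir`. Stages: `"coupling"` (simulate coupled BOLD/CSF subjects,
#' preprocess, cross-correlate), `"kinetics"` (simulate Gd curves, extract
#' kinetic parameters), `"pulsation"` (simulate the pulsatile signal,
#' detect the cardiac peak, compute pulsation power) and `"cbf"` (simulate
#' an ASL dataset and quantify CBF).
#'
#' @param config A list (or path to a JSON file) with elements `seed`,
#'   `stages` (character vector), and optionally any [sim_config()]
#'   argument under `sim`.
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, a named list of per-stage result tibbles.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$stages)) stop("Config must name `stages`.", call. = FALSE)
  if (is.null(config$seed)) stop("Config must name `seed`.", call. = FALSE)
  sim_args <- config$sim %||% list()
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (stage in config$stages) {
    results[[stage]] <- switch(
      stage,
      coupling = purrr::map_dfr(seq_len(cfg$n_subjects), function(s) {
        sim <- gen_coupled_bold_csf(cfg, subject = s)
        bold <- preprocess(sim$bold, band = cfg$band)
        csf <- preprocess(sim$csf, band = cfg$band)
        dplyr::mutate(bold_csf_coupling(bold, csf), subject = s,
                      true_lag = cfg$true_lag)
      }),
      kinetics = purrr::map_dfr(seq_len(cfg$n_subjects), function(s) {
        sim <- gen_gd_curve(cfg, subject = s,
                            noise_sd = cfg$kinetics$peak_amp / 20)
        dplyr::mutate(gd_kinetics(sim$curve), subject = s,
                      true_decay = sim$truth$Decay, true_ttp = sim$truth$ttp)
      }),
      pulsation = {
        sim <- gen_pulsatile_signal(cfg)
        spec <- normalize_and_spectrum(sim$ts)
        peak <- detect_cardiac_peak(spec)
        pulsation_power(sim$ts, cardiac = peak)
      },
      cbf = {
        sim <- gen_asl_dataset(cfg)
        cbf <- quantify_cbf(sim$control, sim$label, sim$t1_map, sim$params)
        tibble::tibble(cbf_mean = mean(cbf), cbf_true = sim$truth$cbf_true)
      },
      stop(sprintf("Unknown stage '%s'.", stage), call. = FALSE)
    )
    out_path <- file.path(out_dir, paste0(stage, ".tsv"))
    res <- results[[stage]]
    utils::write.table(res[, !vapply(res, is.list, logical(1))],
                       paste0(out_path, ".tmp"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    file.rename(paste0(out_path, ".tmp"), out_path)
  }
  manifest <- list(seed = config$seed, stages = config$stages,
                   sim = sim_args,
                   package_version = as.character(utils::packageVersion("neurofluidr")))
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(results)
}
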