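#' Write a gradient waveform as a TSV table
#'
#' Two tab-separated columns with header `time_s` and `grad_mT_per_m`.
#' Metadata (axis, amplitude, label, raster) goes in a JSON sidecar
#' manifest when writing a library.
#'
#' @param w a `gradient_waveform`.
#' @param path output file path.
#' @export
write_waveform_tsv <- function(w, path) {
  utils::write.table(
    data.frame(time_s = waveform_times(w), grad_mT_per_m = w$samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gradient waveform from a TSV table
#'
#' Expects the [write_waveform_tsv()] format; the raster time is
#' inferred from the time column, whose uniformity is checked to 1e-9
#' relative.
#'
#' @param path TSV file path.
#' @param axis,label,amp_scale metadata not stored in the table.
#' @return a `gradient_waveform`.
#' @export
read_waveform_tsv <- function(path, axis = "x", label = "",
                              amp_scale = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "grad_mT_per_m") %in% names(d)))
    stop("waveform table must have columns time_s and grad_mT_per_m")
  tt <- d$time_s
  if (length(tt) < 2) stop("waveform table too short")
  dts <- diff(tt)
  if (any(dts <= 0)) stop("time column must be strictly increasing")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-9 * dt)
    stop("time column is not a uniform grid (to 1e-9 relative)")
  gradient_waveform(d$grad_mT_per_m, dt, axis = axis,
                    amp_scale = amp_scale, label = label)
}

#' Write a waveform library to a directory
#'
#' One TSV per waveform (`<label>_<axis>_<amplitude>.tsv`, plus
#' `_meas` companions when the library is paired) and a JSON
#' `manifest.json` listing file, label, axis, amplitude and split.
#'
#' @param lib a `waveform_library`.
#' @param dir output directory (created if needed).
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  for (i in seq_along(lib$records)) {
    r <- lib$records[[i]]
    base <- sprintf("%s_%s_%+05.0f", r$label, r$axis, r$amplitude)
    write_waveform_tsv(r$waveform, file.path(dir, paste0(base, ".tsv")))
    entry <- list(file = paste0(base, ".tsv"), label = r$label,
                  axis = r$axis, amplitude = r$amplitude,
                  split = r$split)
    if (!is.null(r$measured)) {
      write_waveform_tsv(r$measured,
                         file.path(dir, paste0(base, "_meas.tsv")))
      entry$measured_file <- paste0(base, "_meas.tsv")
    }
    man[[i]] <- entry
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a waveform library written by [write_library()]
#'
#' @param dir library directory containing `manifest.json`.
#' @return a `waveform_library`.
#' @export
read_library <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir)
  man <- jsonlite::read_json(mf)
  recs <- lapply(man, function(e) {
    for (f in c("file", "label", "axis", "amplitude", "split"))
      if (is.null(e[[f]]))
        stop("manifest entry missing field '", f, "'")
    r <- list(
      waveform = read_waveform_tsv(file.path(dir, e$file),
                                   axis = e$axis, label = e$label,
                                   amp_scale = e$amplitude),
      label = e$label, axis = e$axis, amplitude = e$amplitude,
      split = e$split)
    if (!is.null(e$measured_file))
      r$measured <- read_waveform_tsv(file.path(dir, e$measured_file),
                                      axis = e$axis, label = e$label)
    r
  })
  structure(list(records = recs, config = NULL),
            class = "waveform_library")
}

#' Write a GIRF as TSV plus JSON metadata
#'
#' Columns `freq_Hz`, `Re`, `Im`; metadata (axis, raster, lambda, FFT
#' length) in a `.json` sidecar.
#' @param girf a `girf_model`.
#' @param path TSV path (sidecar gets `.json` appended).
#' @export
write_girf_tsv <- function(girf, path) {
  utils::write.table(
    data.frame(freq_Hz = girf$freq, Re = Re(girf$transfer_function),
               Im = Im(girf$transfer_function)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(axis = girf$axis, dt = girf$dt,
                            lambda = girf$lambda,
                            fft_length = girf$fft_length),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a GIRF written by [write_girf_tsv()]
#' @param path TSV path.
#' @return a `girf_model`.
#' @export
read_girf_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(axis = meta$axis, transfer_function = complex(
    real = d$Re, imaginary = d$Im), freq = d$freq_Hz,
    fft_length = meta$fft_length, lambda = meta$lambda, dt = meta$dt),
    class = "girf_model")
}

#' Write a k-space trajectory as TSV
#' @param tr a `ktrajectory`.
#' @param path output path.
#' @export
write_trajectory_tsv <- function(tr, path) {
  utils::write.table(
    data.frame(t_s = tr$times, kx_per_m = tr$kx, ky_per_m = tr$ky),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reconstructed image (magnitude) or parameter map as NIfTI
#'
#' @param x a `recon_image`, `parameter_maps` component, or numeric
#'   matrix.
#' @param path output `.nii`/`.nii.gz` path.
#' @param what for `recon_image`: `"magnitude"` or `"phase"`.
#' @export
write_nifti_map <- function(x, path, what = c("magnitude", "phase")) {
  what <- match.arg(what)
  m <- if (inherits(x, "recon_image")) {
    if (what == "magnitude") abs(x$image) else Arg(x$image)
  } else as.matrix(x)
  vox <- if (!is.null(attr(x, "fov"))) attr(x, "fov") / nrow(m) * 1000
         else if (inherits(x, "recon_image")) x$fov / nrow(m) * 1000
         else 1
  img <- RNifti::asNifti(array(m, c(dim(m), 1)),
                         pixdim = c(vox, vox, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
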