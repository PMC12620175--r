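#' Default characterization-library configuration
#'
#' Eighteen waveform shapes: eleven system-characterization-heavy shapes
#' assigned to training and seven imaging-heavy shapes withheld for
#' validation. Training shapes are replicated at 15 amplitudes uniformly
#' spaced over \[70, 700\] mT/m (45 mT/m spacing); validation shapes at 7
#' amplitudes over the same range. Each shape is defined at the top
#' amplitude (so scaling down never increases slew demand) and replicated
#' on the requested axes.
#'
#' @param dt raster time (s).
#' @param amp_range amplitude range (mT/m).
#' @param n_train_amps,n_val_amps amplitude-grid sizes.
#' @param axes axes to replicate the library on.
#' @param max_grad,slew_limit system limits used in shape design.
#' @return a config list consumed by [build_characterization_library()].
#' @export
library_config <- function(dt = 4e-6, amp_range = c(70, 700),
                           n_train_amps = 15, n_val_amps = 7,
                           axes = c("x", "y", "z"),
                           max_grad = 770, slew_limit = 5274) {
  list(dt = dt, amp_range = amp_range, n_train_amps = n_train_amps,
       n_val_amps = n_val_amps, axes = axes, max_grad = max_grad,
       slew_limit = slew_limit)
}

# the 18 default shape prototypes, built at peak amplitude `top`
.library_shapes <- function(cfg) {
  dt <- cfg$dt
  top <- max(cfg$amp_range)
  sl <- 0.92 * cfg$slew_limit
  ramp_min <- top * 1e-3 / sl           # shortest in-limit ramp at `top`
  r <- function(mult) max(ramp_min * mult, 4 * dt)
  # characterization spiral/rosette: single-turn spiral and 5-petal
  # rosette designed so the peak gradient sits just under `top`; scaling
  # the shape to the top of the amplitude grid then leaves the slew
  # demand within the system limit
  sp <- make_spiral_inout(135, fov = 0.03, resolution = 1.11e-4,
                          max_grad = 0.99 * top, slew_limit = 0.9 * sl,
                          dt = dt, prephaser = TRUE)
  # rosette peak gradient is k_max*w1/gamma_bar; derate the ramp slew by
  # the upscale factor to the top of the amplitude grid
  ro_w1 <- pi * 5 / 4.5e-3
  ro_peak <- 1 / (2 * 1.07e-4) * ro_w1 / .GAMMA_BAR * 1e3
  ro <- make_rosette(8, 5, fov = 0.03, resolution = 1.07e-4,
                     readout_duration = 4.5e-3, dt = dt,
                     max_grad = cfg$max_grad, slew_limit = sl,
                     ramp_slew = sl * ro_peak / top)
  relabel <- function(w, lab) { w$label <- lab; w }
  chirp <- function(f1, dur, lab)
    relabel(make_chirp(700, f1, dur, top, sl, dt = dt), lab)
  msine <- function(f, a, dur, lab)
    relabel(make_multisine(f, a * top, dur, dt = dt), lab)
  train <- list(
    relabel(make_trapezoid(top, 6e-4, r(1.2), dt), "trap_long"),
    relabel(make_trapezoid(top, 2.4e-4, r(1.5), dt), "trap_short"),
    relabel(make_triangle_train(top, 4, r(1.2), dt), "tri4"),
    relabel(make_triangle_train(top, 2, r(1.8), dt), "tri2"),
    chirp(3e3, 2e-3, "chirp3k"),
    chirp(8e3, 5.6e-3, "chirp8k"),
    relabel(make_triangle_train(top, 1, r(1.3), dt), "blip"),
    msine(c(0.3e3, 0.7e3, 1.1e3), c(1, 0.6, 0.4), 2e-3, "msine3a"),
    msine(c(0.2e3, 0.5e3, 0.9e3, 1.4e3), c(1, 0.5, 0.35, 0.2), 2.4e-3,
          "msine4"),
    msine(c(0.35e3, 0.9e3), c(1, 0.45), 2e-3, "msine2a"),
    relabel(sp$shots[[1]]$gx, "spiral_char")
  )
  val <- list(
    relabel(sp$shots[[35]]$gy, "spiral_val_gy"),
    relabel(sp$shots[[68]]$gx, "spiral_val_gx"),
    relabel(ro$shots[[1]]$gx, "rosette_val_gx"),
    relabel(ro$shots[[2]]$gy, "rosette_val_gy"),
    relabel(make_trapezoid(top, 3e-4, r(2.2), dt), "trap_val"),
    msine(c(0.6e3, 1.05e3), c(1, 0.5), 2e-3, "msine_val"),
    chirp(5e3, 3.3e-3, "chirp_val")
  )
  list(train = train, val = val)
}

#' Build the nominal characterization library
#'
#' Generates the train/validation split of nominal waveforms: the default
#' configuration yields 18 distinct shapes (11 train, 7 validation),
#' train shapes at 15 amplitudes and validation shapes at 7 amplitudes in
#' \[70, 700\] mT/m, replicated on each axis (214 waveforms per axis).
#' Construction is deterministic.
#'
#' @param config a [library_config()] list.
#' @return an object of class `waveform_library`: a list of records, each
#'   `list(waveform, label, axis, amplitude, split)`.
#' @export
build_characterization_library <- function(config = library_config()) {
  shapes <- .library_shapes(config)
  labs <- vapply(c(shapes$train, shapes$val), function(w) w$label, "")
  if (anyDuplicated(labs)) stop("duplicate waveform labels in library")
  amps_tr <- seq(config$amp_range[1], config$amp_range[2],
                 length.out = config$n_train_amps)
  amps_va <- seq(config$amp_range[1], config$amp_range[2],
                 length.out = config$n_val_amps)
  recs <- list()
  for (ax in config$axes) {
    for (split in c("train", "validation")) {
      ss <- if (split == "train") shapes$train else shapes$val
      amps <- if (split == "train") amps_tr else amps_va
      for (w in ss) {
        w$axis <- ax
        for (wa in scale_to_amplitudes(w, amps, config$max_grad)) {
          wa$axis <- ax
          recs[[length(recs) + 1L]] <-
            list(waveform = wa, label = wa$label, axis = ax,
                 amplitude = wa$amp_scale, split = split)
        }
      }
    }
  }
  structure(list(records = recs, config = config),
            class = "waveform_library")
}

#' @export
print.waveform_library <- function(x, ...) {
  ax <- vapply(x$records, function(r) r$axis, "")
  sp <- vapply(x$records, function(r) r$split, "")
  cat(sprintf("<waveform_library> %d waveforms (%d train / %d validation) on %d axes\n",
              length(x$records), sum(sp == "train"),
              sum(sp == "validation"), length(unique(ax))))
  if (!is.null(x$records[[1]]$measured)) cat("  paired (nominal + measured)\n")
  invisible(x)
}

#' Subset a library by axis and/or split
#' @param lib a `waveform_library`.
#' @param axis,split optional filters.
#' @return a `waveform_library`.
#' @export
library_subset <- function(lib, axis = NULL, split = NULL) {
  keep <- vapply(lib$records, function(r) {
    (is.null(axis) || r$axis %in% axis) &&
      (is.null(split) || r$split %in% split)
  }, TRUE)
  structure(list(records = lib$records[keep], config = lib$config),
            class = "waveform_library")
}

#' Simulate measurement of every waveform in a library
#'
#' Runs [simulate_measurement()] on each nominal waveform, attaching the
#' result as `measured` in each record; split labels and ordering are
#' preserved. Noise substreams are indexed by record position, so the
#' result is deterministic given the model's `rng_seed`.
#'
#' @param model a [gradient_system()].
#' @param lib a `waveform_library` of nominal waveforms.
#' @param add_noise add measurement noise?
#' @param settle_pad post-waveform settling window (s) per measurement;
#'   see [simulate_measurement()].
#' @return the paired `waveform_library`.
#' @export
simulate_library <- function(model, lib, add_noise = TRUE,
                             settle_pad = 0) {
  if (!length(lib$records)) stop("library is empty")
  for (i in seq_along(lib$records)) {
    r <- lib$records[[i]]
    lib$records[[i]]$measured <-
      simulate_measurement(model, r$waveform, add_noise = add_noise,
                           noise_stream = i, settle_pad = settle_pad)
  }
  lib
}

# list of (nominal, measured) pairs for one axis/split
.library_pairs <- function(lib, axis, split = "train") {
  sub <- library_subset(lib, axis = axis, split = split)
  lapply(sub$records, function(r) {
    if (is.null(r$measured)) stop("library has no measured waveforms")
    list(nominal = r$waveform, measured = r$measured)
  })
}
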