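# lazily built shared fixtures; heavy objects are constructed once per
# test run and reused across files
.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) assign(name, force(expr), envir = .fix)
  .fix[[name]]
}

# a small nominal library: 4 shapes x 3 amplitudes on one axis
tiny_library <- function(axis = "x") {
  memo(paste0("tinylib_", axis), {
    cfg <- library_config(axes = axis, n_train_amps = 3, n_val_amps = 2)
    shapes <- list(
      make_trapezoid(700, 4e-4, 1.8e-4, axis = axis),
      make_triangle_train(700, 2, 2.4e-4, axis = axis),
      make_chirp(700, 3e3, 1.6e-3, 700, 4500, axis = axis),
      make_multisine(c(300, 900), c(700, 300), 1.6e-3, axis = axis))
    amps <- list(train = seq(70, 700, length.out = 3),
                 val = c(200, 550))
    recs <- list()
    for (i in seq_along(shapes)) {
      split <- if (i <= 3) "train" else "validation"
      a <- if (split == "train") amps$train else amps$val
      for (w in scale_to_amplitudes(shapes[[i]], a)) {
        w$axis <- axis
        w$label <- paste0("shape", i)
        recs[[length(recs) + 1]] <- list(waveform = w, label = w$label,
                                         axis = axis,
                                         amplitude = w$amp_scale,
                                         split = split)
      }
    }
    structure(list(records = recs, config = cfg),
              class = "waveform_library")
  })
}

# identity-system pairs (measured == nominal) for estimator oracles
identity_pairs <- function(axis = "x") {
  lapply(library_subset(tiny_library(axis), split = "train")$records,
         function(r) list(nominal = r$waveform, measured = r$waveform))
}

# full default characterization library (all axes)
full_library <- function() memo("fulllib", build_characterization_library())

# default nonlinear simulator + simulated full library
nonlinear_sim <- function() {
  memo("nonlinsim",
       simulate_library(gradient_system(), full_library()))
}

mean_val_nrmse <- function(sim, axis, pred_fun) {
  pv <- gradnet:::.library_pairs(sim, axis, "validation")
  mean(vapply(pv, function(p)
    waveform_nrmse(pred_fun(p$nominal), p$measured,
                   amp = abs(p$nominal$amp_scale)), 0))
}
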