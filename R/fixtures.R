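#' Generate a named, seeded fixture bundle
#'
#' Produces a self-contained bundle used by the test-suite and by the worked
#' examples: a phantom layout, a scripted raster session driven by the
#' calibrated encoder and the virtual subject, and the analysis snapshot of
#' that session. Bundles are a pure function of `(name, seed)`: the same
#' pair regenerates an identical bundle.
#'
#' Known names:
#' * `"default"`: the full apparatus phantom (12 inclusions) with a 60 s
#'   raster session.
#' * `"uniform"`: an inclusion-free control phantom with the same session
#'   script.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param dir optional directory; when given, the bundle is written there
#'   (`phantom.json`, `session/`, `analysis.json`).
#' @return a list with `phantom`, `session` (a `telepalp_session`), and for
#'   the default fixture `analysis`.
#' @export
generate_fixtures <- function(name = "default", seed = 1L, dir = NULL) {
  if (!name %in% c("default", "uniform"))
    abort("unknown fixture name: %s", name)
  ph_cfg <- if (name == "uniform") phantom_config(replicas = 0L)
            else phantom_config()
  phantom <- generate_phantom(ph_cfg, seed = seed)
  cal <- calibrate_gain()
  ses_cfg <- session_config(duration = 60, seed = seed)
  ctl <- control_config()
  log <- run_session(phantom, subject_model(), ctl,
                     izhikevich_params(), cal, ses_cfg,
                     make_trajectory("raster", list(speed = 15),
                                     control_cfg = ctl))
  out <- list(phantom = phantom, session = log)
  if (name == "default" && nrow(log$responses))
    out$analysis <- analyze_sessions(log$responses, phantom)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_phantom(phantom, file.path(dir, "phantom.json"))
    write_session_log(log, file.path(dir, "session"))
    if (!is.null(out$analysis))
      jsonlite::write_json(out$analysis, file.path(dir, "analysis.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
  }
  out
}
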