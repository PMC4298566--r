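# One-shot reproducible pipeline: (optional) synthesize -> track ->
# beatfreq -> envelope, with a manifest recording versions, parameters,
# seed and per-stage status.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param video,meta paths to an input TIFF stack and its sidecar metadata;
#'   leave `NULL` to synthesize a recording instead.
#' @param synthesize list of [beat_protocol()] / [render_params()] arguments
#'   used when no input video is given (split into `protocol` and `render`).
#' @param window_s analysis half-window (s).
#' @param annulus_um annulus `c(inner, outer)` diameters (µm).
#' @param prune_len skeleton spur-pruning length (px).
#' @param projection envelope projection, `"max"` or `"mean"`.
#' @param roi optional head region of interest `list(center = c(x, y),
#'   radius)`; derived from frame 1 when absent.
#' @param seed integer seed for all stochastic draws.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, video = NULL, meta = NULL, synthesize = NULL,
                       window_s = 0.5, annulus_um = c(16, 20), prune_len = 5,
                       projection = "max", roi = NULL, seed = 1L) {
  if (is.null(video) && is.null(synthesize)) synthesize <- list()
  if (!is.null(video) && !file.exists(video))
    stop("config error: video path does not exist: ", video)
  if (!is.null(video) && (is.null(meta) || !file.exists(meta)))
    stop("config error: metadata path missing for video: ", meta)
  stopifnot(window_s > 0, length(annulus_um) == 2,
            annulus_um[2] > annulus_um[1], projection %in% c("max", "mean"))
  structure(list(out_dir = out_dir, video = video, meta = meta,
                 synthesize = synthesize, window_s = window_s,
                 annulus_um = annulus_um, prune_len = prune_len,
                 projection = projection, roi = roi,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$roi))
    cfg$roi <- list(center = as.numeric(cfg$roi$center),
                    radius = cfg$roi$radius)
  if (!is.null(cfg$annulus_um)) cfg$annulus_um <- as.numeric(cfg$annulus_um)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes synthesize (when no input video is given), track, beatfreq and
#' envelope, writing per-stage outputs and a manifest to `out_dir`.
#' Identical configuration and seed produce identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list; its `ok` element is `FALSE` when a
#'   stage failed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(
    package = "flagellabeat",
    version = as.character(utils::packageVersion("flagellabeat")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("window_s", "annulus_um", "prune_len",
                          "projection")],
    stages = list(), outputs = character(), ok = TRUE)
  set.seed(config$seed)

  run_stage <- function(name, fn) {
    if (!manifest$ok) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res))
      manifest$ok <<- FALSE
      return(NULL)
    }
    manifest$stages[[name]] <<- list(status = "completed")
    res
  }

  video <- NULL
  if (is.null(config$video)) {
    video <- run_stage("synthesize", function() {
      args <- config$synthesize
      pargs <- args$protocol %||% list()
      rargs <- args$render %||% list()
      if (is.null(pargs$seed)) pargs$seed <- config$seed
      sv <- generate_video(do.call(beat_protocol, pargs),
                           do.call(render_params, rargs))
      write_video(sv$video, out("video.tiff"), out("video.yaml"))
      write_ground_truth(sv$truth, out("ground_truth.csv"),
                         out("ground_truth.json"))
      manifest$outputs <<- c(manifest$outputs, "video.tiff", "video.yaml",
                             "ground_truth.csv", "ground_truth.json")
      sv$video
    })
  } else {
    video <- run_stage("load", function()
      read_video(config$video, config$meta))
  }

  angles <- run_stage("track", function() {
    a <- angle_series(video, window_s = config$window_s,
                      head_prior = config$roi$center,
                      prune_len = config$prune_len, keep_traces = TRUE)
    utils::write.csv(as.data.frame(a), out("angles.csv"), row.names = FALSE)
    tr <- attr(a, "traces")
    rows <- do.call(rbind, lapply(which(!vapply(tr, is.null, logical(1))),
      function(k) data.frame(frame = k,
                             point_index = seq_len(nrow(tr[[k]]$points)),
                             x = tr[[k]]$points[, 1],
                             y = tr[[k]]$points[, 2])))
    utils::write.csv(rows, out("traces.csv"), row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, "angles.csv", "traces.csv")
    a
  })

  freq <- run_stage("beatfreq", function() {
    fs <- frequency_series(angles, window_s = config$window_s)
    utils::write.csv(as.data.frame(fs), out("frequency.csv"),
                     row.names = FALSE)
    s <- summary(fs)
    jsonlite::write_json(unclass(s)[!vapply(unclass(s), is.null, logical(1))],
                         out("frequency_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <<- c(manifest$outputs, "frequency.csv",
                           "frequency_summary.json")
    fs
  })

  run_stage("envelope", function() {
    roi <- config$roi
    if (is.null(roi)) {
      p1 <- locate_head(binarize(video$frames[[1]]),
                        intensity = video$frames[[1]])
      roi <- list(center = p1$center,
                  radius = ceiling(config$annulus_um[1] / 2 / video$um_per_px))
    }
    heads <- register_head(video, roi)
    ann <- annulus(config$annulus_um[1], config$annulus_um[2])
    az <- vapply(seq_len(length(video$frames)), function(k) {
      tryCatch(neck_azimuth(binarize(video$frames[[k]], frame_index = k),
                            c(heads$x[k], heads$y[k]), ann, video$um_per_px,
                            intensity = video$frames[[k]], frame_index = k),
               error = function(e) NA_real_)
    }, numeric(1))
    env <- align_and_superimpose(video, heads, az,
                                 projection = config$projection)
    tiff::writeTIFF(env$image, out("envelope.tiff"), bits.per.sample = 16L)
    jsonlite::write_json(list(n_frames_used = env$n_frames_used,
                              reference_azimuth = env$reference_azimuth,
                              projection = env$projection),
                         out("envelope.json"), auto_unbox = TRUE, digits = NA)
    manifest$outputs <<- c(manifest$outputs, "envelope.tiff", "envelope.json")
    env
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
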