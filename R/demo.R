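#' Run the full synthetic case-study pipeline
#'
#' End-to-end demonstration mirroring a language-mapping analysis on
#' synthetic data: build a brain-like mesh, place the four-strip 64-channel
#' montage, simulate an ERP task recording with phase-coupled strips,
#' zero-phase band-pass filter (0.5-250 Hz), epoch (-800 to +3500 ms),
#' reject artifact epochs, average the ERP, compute phase-locking-value
#' networks for the six canonical bands, and export one surface-map image
#' per ERP time stage plus one ball-and-stick network image per band at the
#' display threshold. All outputs land in \code{out_dir}: data files in the
#' package's five formats, plus the rendered images.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed controlling every random element.
#' @param subdivisions mesh resolution (see \code{\link{make_brain_mesh}}).
#' @param n_trials number of simulated trials.
#' @param fs sampling rate, Hz.
#' @param erp_times_ms post-stimulus time points (ms) mapped as ERP rows.
#' @param display_threshold connection display threshold (default 0.6).
#' @param reject_sd epoch-rejection threshold in robust-SD units.
#' @param width,height image size in pixels.
#' @param format image format, "png" or "bmp".
#' @return invisible list with the intermediate objects (\code{mesh},
#'   \code{montage}, \code{epochs}, \code{erp}, \code{erp_rows},
#'   \code{plv} (per band), \code{files}).
#' @export
demo_case_study <- function(out_dir, seed = 1, subdivisions = 3L,
                            n_trials = 40, fs = 600,
                            erp_times_ms = seq(0, 3000, by = 500),
                            display_threshold = 0.6, reject_sd = 15,
                            width = 640, height = 480,
                            format = c("png", "bmp")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strips <- list(1:16, 17:32, 33:48, 49:64)

  mesh <- make_brain_mesh(subdivisions)
  montage <- make_case_study_montage(mesh)
  rec <- make_erp_dataset(n_trials = n_trials, n_channels = 64, fs = fs,
                          snr = 1, seed = seed, coupled_groups = strips,
                          artifact_trials = 2)

  filtered <- bandpass_zero_phase(rec, 0.5, 250)
  epochs <- segment_epochs(filtered, -800, 3500)
  epochs <- reject_epochs(epochs, reject_sd)
  erp <- average_erp(epochs)

  # one parameter row per requested post-stimulus time point
  samp <- round((erp_times_ms - epochs$window[1]) * fs / 1000) + 1L
  erp_rows <- t(erp[, samp, drop = FALSE])
  rownames(erp_rows) <- NULL

  files <- character(0)
  p <- function(...) file.path(out_dir, paste0(...))
  write_mof(mesh, p("brain.mof"))
  write_epf(montage, p("montage.epf"))
  cam <- camera_preset(mesh, "left")
  write_cpf(cam, p("view.cpf"))
  write_table_file(erp_rows, p("erp_rows.txt"), "params")
  files <- c(files, p("brain.mof"), p("montage.epf"), p("view.cpf"),
             p("erp_rows.txt"))

  plv <- list()
  for (band in names(ieeg_bands())) {
    M <- plv_matrix(epochs, band = band)
    plv[[band]] <- M
    write_table_file(M, p("plv_", band, ".txt"), "matrix")
    files <- c(files, p("plv_", band, ".txt"))
  }

  base_scene <- scene_spec(mesh = mesh, electrodes = montage, camera = cam,
                           mapping = list(method = "gauss", sigma = 10,
                                          radius = 15,
                                          range = scale_range(erp_rows)))
  map_files <- export_images(base_scene, erp_rows, p("erp_map"),
                             format = format, width = width,
                             height = height)
  files <- c(files, map_files)

  net_files <- character(0)
  for (band in names(ieeg_bands())) {
    es <- threshold_edges(plv[[band]], display_threshold)
    es <- edge_styles(es, "scaled",
                      scale_mode = "manual", lo = display_threshold, hi = 1,
                      colormap = "jet")
    nodes <- replot_nodes(montage, node_strength(es),
                          colormap = "bluered")
    sc <- scene_spec(mesh = mesh, electrodes = nodes, edges = es,
                     camera = cam, opacity = 1, colormap = "jet")
    img <- render_scene(sc, width, height)
    fn <- p("network_", band, ".", format)
    write_image(img, fn, format)
    net_files <- c(net_files, fn)
  }
  files <- c(files, net_files)

  invisible(list(mesh = mesh, montage = montage, recording = rec,
                 epochs = epochs, erp = erp, erp_rows = erp_rows,
                 erp_times_ms = erp_times_ms, plv = plv, camera = cam,
                 files = files, map_files = map_files,
                 net_files = net_files))
}
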