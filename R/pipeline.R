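# End-to-end orchestration: simulate (or read) replicate sections, normalize,
# extract ion images, mask, segment, map segments to compartments, compute
# the image statistics and the targeting report, and write every artifact to
# disk. Stage outputs are files so each stage is independently re-runnable;
# one structured log line per stage.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed recorded in every output.
#' @param n_replicates replicate sections to simulate (ignored when `imzml`
#'   paths are given).
#' @param imzml optional character vector of imzML paths to analyze instead
#'   of simulating.
#' @param scenario a `lung_scenario` (default [lung_scenario()]).
#' @param analyte_table optional CSV/YAML path overriding
#'   [default_analytes()].
#' @param plasma list with `inhaled`, `iv` concentrations (and optional
#'   units); required for the targeting stage.
#' @param k,sigma_px,bin_width,n_restarts segmentation parameters.
#' @param mask_method,mask_quantile tissue-mask parameters.
#' @param ring_threshold epithelium ring-shape cut for ROI naming.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_replicates = 3L,
                            imzml = NULL,
                            scenario = lung_scenario(),
                            analyte_table = NULL,
                            plasma = scenario$plasma,
                            k = 6L, sigma_px = 1, bin_width = 0.5,
                            n_restarts = 5L,
                            mask_method = "tic_threshold",
                            mask_quantile = 0.45,
                            ring_threshold = 30) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates), imzml = imzml,
                 scenario = scenario, analyte_table = analyte_table,
                 plasma = plasma, k = as.integer(k), sigma_px = sigma_px,
                 bin_width = bin_width, n_restarts = as.integer(n_restarts),
                 mask_method = mask_method, mask_quantile = mask_quantile,
                 ring_threshold = ring_threshold),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[lungtarget] stage %-12s done in %6.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full MSI targeting pipeline
#'
#' Executes, in order: input (simulate or read), normalization, ion-image
#' extraction, tissue masking, segmentation, ROI naming, heterogeneity and
#' correlation statistics, targeting-factor computation, and report writing.
#' Any stage error aborts with the stage name; artifacts written before the
#' failure are preserved. Outputs (CSV/JSON/YAML) are byte-identical across
#' runs with the same configuration and seed.
#'
#' @param config a `pipeline_config` (or list coercible to one).
#' @return invisibly, a list with the in-memory results (`sections`,
#'   `masks`, `segmentations`, `rois`, `ion_images`, `correlations`,
#'   `heterogeneity`, `targeting`) and `paths` of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(...) file.path(config$out_dir, paste0(...))

  analytes <- stage("analytes", {
    if (is.null(config$analyte_table)) default_analytes()
    else read_analyte_table(config$analyte_table)
  })
  roles <- vapply(analytes, `[[`, character(1), "role")
  inhaled <- analytes[[which(roles == "drug_inhaled")[1]]]
  iv <- analytes[[which(roles == "drug_iv")[1]]]
  markers <- analytes[roles %in% c("marker_vessel", "marker_alveolar",
                                   "marker_bronchiolar")]

  input <- stage("input", {
    if (!is.null(config$imzml)) {
      lapply(config$imzml, read_imzml)
    } else {
      lapply(seq_len(config$n_replicates), function(r)
        simulate_msi(config$scenario, seed = config$seed + r))
    }
  })
  simulated <- is.null(config$imzml)
  sections <- if (simulated) lapply(input, `[[`, "dataset") else input

  masks <- stage("mask", lapply(sections, function(s)
    compute_tissue_mask(tic_image(s), method = config$mask_method,
                        threshold_quantile = config$mask_quantile)))

  normalized <- stage("normalize", lapply(sections, function(s)
    suppressMessages(tic_normalize(s))))

  ion_images <- stage("extract", lapply(normalized, function(s)
    lapply(analytes, function(a) extract_ion_image(s, a))))
  for (a in names(ion_images[[1]])) {
    paths[[paste0("ion_image_", a)]] <-
      write_image_csv(ion_images[[1]][[a]], out("ion_image_", a, ".csv"))
    write_image_tiff(ion_images[[1]][[a]], out("ion_image_", a, ".tiff"))
  }

  segmentations <- stage("segment", lapply(seq_along(sections), function(i)
    segment_msi(sections[[i]], k = config$k, sigma_px = config$sigma_px,
                bin_width = config$bin_width, seed = config$seed + i,
                n_restarts = config$n_restarts)))
  paths$segmentation <- out("segmentation_rep1.csv")
  utils::write.table(segmentations[[1]]$labels, paths$segmentation,
                     sep = ",", row.names = FALSE, col.names = FALSE)

  rois <- stage("rois", lapply(seq_along(sections), function(i) {
    mimgs <- ion_images[[i]][names(markers)]
    segments_to_rois(segmentations[[i]], mimgs,
                     tic = tic_image(sections[[i]]),
                     ring_threshold = config$ring_threshold)
  }))
  paths$rois <- out("roi_mapping.yaml")
  yaml::write_yaml(lapply(rois, function(r)
    stats::setNames(as.list(r$mapping$compartment),
                    paste0("segment_", r$mapping$label))), paths$rois)

  heterogeneity <- stage("heterogeneity", {
    rows <- do.call(rbind, lapply(seq_along(sections), function(i) {
      rin <- pixel_rsd(ion_images[[i]][[inhaled$name]], masks[[i]],
                       route = "inhaled")
      riv <- pixel_rsd(ion_images[[i]][[iv$name]], masks[[i]], route = "iv")
      data.frame(replicate = i, route = c("inhaled", "iv"),
                 analyte = c(rin$analyte, riv$analyte),
                 rsd_percent = c(rin$rsd_percent, riv$rsd_percent),
                 n_pixels = c(rin$n_pixels, riv$n_pixels))
    }))
    paths$heterogeneity <- out("heterogeneity.csv")
    utils::write.csv(rows, paths$heterogeneity, row.names = FALSE)
    rows
  })

  correlations <- stage("correlate", {
    tab <- correlation_table(ion_images[[1]][c(inhaled$name, iv$name,
                                               names(markers))],
                             mask = masks[[1]])
    paths$correlations <- out("correlation_table.csv")
    utils::write.csv(tab, paths$correlations)
    tab
  })

  targeting <- stage("targeting", {
    if (is.null(config$plasma))
      stop("plasma concentrations are required for targeting")
    rep <- lung_targeting(sections, rois, inhaled, iv, config$plasma,
                          masks = masks)
    paths$targeting_json <- out("targeting_report.json")
    jsonlite::write_json(list(aggregate = rep$aggregate,
                              per_replicate = rep$per_replicate,
                              section_level = rep$section_level,
                              seed = config$seed),
                         paths$targeting_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    paths$targeting_csv <- out("targeting_per_replicate.csv")
    utils::write.csv(rep$per_replicate, paths$targeting_csv,
                     row.names = FALSE)
    grDevices::png(out("targeting_report.png"), width = 900, height = 320)
    plot(rep)
    grDevices::dev.off()
    rep
  })

  manifest <- stage("manifest", {
    cfg <- unclass(config)
    cfg$out_dir <- NULL  # the hash identifies the analysis, not its location
    cfg$scenario <- if (simulated) unclass(config$scenario) else NULL
    m <- list(package = "lungtarget",
              version = as.character(utils::packageVersion("lungtarget")),
              seed = config$seed,
              config_hash = digest::digest(cfg, algo = "sha1"),
              n_replicates = length(sections),
              n_pixels = vapply(sections, n_pixels, integer(1)),
              artifacts = lapply(paths, basename))
    paths$manifest <- out("manifest.json")
    jsonlite::write_json(m, paths$manifest, auto_unbox = TRUE, digits = NA)
    m
  })

  invisible(list(sections = sections, masks = masks,
                 segmentations = segmentations, rois = rois,
                 ion_images = ion_images, correlations = correlations,
                 heterogeneity = heterogeneity, targeting = targeting,
                 manifest = manifest, paths = paths,
                 truth = if (simulated) lapply(input, `[[`, "truth")))
}
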