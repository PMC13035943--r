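# Run orchestration: JSON configuration, batch processing over image files,
# CSV/TIFF outputs and a run manifest. Partial failures are logged and the
# run continues; the status is nonzero iff any image failed.

#' Build or load a run configuration
#'
#' Either a path to a JSON file or a list. Required: `command` (one of
#' simulate, profile, lyso, coloc) and `output_dir`. Commands other than
#' simulate need `inputs` (a character vector of TIFF paths or a glob) and
#' `channel_map` (role -> 1-based page index). Optional keys: `segmentation`
#' (arguments to [seg_params()]), `radial` (`n_annuli` or `thickness_px`,
#' `background_mode`), `lyso` (`den_floor`), `scene` (arguments to
#' [scene_spec()] for simulate), `seed`.
#'
#' @param x path to a JSON file, or a named list.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    jsonlite::read_json(x, simplifyVector = TRUE)
  } else if (is.list(x)) x else
    stop("config must be a file path or a list", call. = FALSE)
  problems <- character()
  if (is.null(cfg$command) ||
      !cfg$command %in% c("simulate", "profile", "lyso", "coloc"))
    problems <- c(problems,
                  "command must be one of simulate/profile/lyso/coloc")
  if (is.null(cfg$output_dir)) problems <- c(problems, "output_dir missing")
  if (!is.null(cfg$command) &&
      isTRUE(cfg$command %in% c("profile", "lyso", "coloc"))) {
    if (is.null(cfg$inputs)) problems <- c(problems, "inputs missing")
    if (is.null(cfg$channel_map)) problems <- c(problems,
                                                "channel_map missing")
    need <- switch(cfg$command, profile = c("envelope", "nuclear", "signal"),
                   lyso = c("envelope", "nuclear", "ratio_num", "ratio_den"),
                   coloc = c("ratio_num", "ratio_den"))
    if (!is.null(cfg$channel_map)) {
      missing_roles <- setdiff(need, names(cfg$channel_map))
      if (length(missing_roles))
        problems <- c(problems, paste0("channel_map lacks role(s): ",
                                       paste(missing_roles, collapse = ", ")))
    }
  }
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  semantic <- cfg[setdiff(names(cfg), c("log"))]
  semantic <- semantic[order(names(semantic))]
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(semantic, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

expand_inputs <- function(inputs) {
  hits <- unlist(lapply(inputs, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  }))
  unique(hits)
}

seg_params_from <- function(cfg) {
  do.call(seg_params, as.list(cfg$segmentation %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured pipeline command
#'
#' `simulate` renders the configured scene and writes the five channels as
#' one multi-page TIFF plus ground-truth CSVs; `profile`, `lyso` and
#' `coloc` process each input image and write per-image plus pooled CSV
#' tables. Every run writes a `manifest.json` (inputs, config hash, package
#' version, per-image status).
#'
#' @param cfg a [run_config()] (or something accepted by it).
#' @return invisibly, a list with `status` (0 = all images succeeded) and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- character()
  outputs <- character()

  if (cfg$command == "simulate") {
    scene_args <- as.list(cfg$scene %||% list())
    scene_args$seed <- NULL
    spec <- do.call(scene_spec, c(scene_args, list(seed = cfg$seed)))
    sc <- generate_scene(spec)
    img_path <- file.path(cfg$output_dir, "scene.tif")
    # one common scale across channels so between-channel ratios survive
    gmax <- max(1, vapply(sc$images$channels, max, numeric(1)))
    pages <- lapply(sc$images$channels, function(ch) ch / gmax)
    tiff::writeTIFF(unname(pages), img_path, bits.per.sample = 32L,
                    reduce = FALSE)
    write_labelmap(sc$truth$cell_mask,
                   file.path(cfg$output_dir, "true_cell_mask.tif"))
    write_labelmap(sc$truth$nuclei,
                   file.path(cfg$output_dir, "true_nuclei.tif"))
    write_table(sc$truth$cells, file.path(cfg$output_dir, "true_cells.csv"),
                key_cols = "cell_id")
    if (!is.null(sc$truth$puncta))
      write_table(sc$truth$puncta,
                  file.path(cfg$output_dir, "true_puncta.csv"),
                  key_cols = c("cell_id", "row", "col"))
    jsonlite::write_json(unclass(spec),
                         file.path(cfg$output_dir, "scene_spec.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c("scene.tif", "true_cell_mask.tif", "true_nuclei.tif",
                 "true_cells.csv", "scene_spec.json")
  } else {
    files <- expand_inputs(cfg$inputs)
    if (length(files) == 0L) stop("no inputs matched", call. = FALSE)
    params <- seg_params_from(cfg)
    cmap <- unlist(cfg$channel_map)
    pooled <- list()
    for (f in files) {
      image_id <- sub("\\.tiff?$", "", basename(f))
      res <- tryCatch({
        imgset <- read_image_set(f, cmap)
        switch(cfg$command,
          profile = {
            r <- radial_profile_pipeline(
              imgset, params,
              n_annuli = cfg$radial$n_annuli %||% 10L,
              thickness_px = cfg$radial$thickness_px,
              background_mode = cfg$radial$background_mode %||%
                "median_outside",
              image_id = image_id)
            write_labelmap(r$annulus_labels,
                           file.path(cfg$output_dir,
                                     paste0(image_id, "_annuli.tif")))
            r$table
          },
          lyso = {
            r <- lysosome_pipeline(imgset, params,
                                   den_floor = cfg$lyso$den_floor %||% 0,
                                   image_id = image_id)
            write_table(r$particles,
                        file.path(cfg$output_dir,
                                  paste0(image_id, "_particles.csv")),
                        key_cols = c("image_id", "particle_id"))
            r$quartiles
          },
          coloc = {
            mask <- NULL
            src <- "whole_image"
            if (isTRUE(cfg$coloc$use_cell_mask)) {
              mask <- segment_cell_mask(imgset$channels$envelope, params)
              src <- "cell_mask"
            }
            p <- pearson_coloc(imgset$channels$ratio_num,
                               imgset$channels$ratio_den, mask)
            data.frame(image_id = image_id, pcc = p$pcc,
                       n_pixels = p$n_pixels, mask_source = src)
          })
      }, error = function(e) {
        message("FAILED ", f, ": ", conditionMessage(e))
        failures <<- c(failures, paste0(f, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) pooled[[length(pooled) + 1L]] <- res
    }
    if (length(pooled)) {
      tab <- do.call(rbind, pooled)
      out_name <- switch(cfg$command, profile = "profiles.csv",
                         lyso = "quartiles.csv", coloc = "coloc.csv")
      write_table(tab, file.path(cfg$output_dir, out_name),
                  key_cols = intersect(c("image_id", "nucleus_id", "cell_id",
                                         "annulus_index", "quartile"),
                                       names(tab)))
      outputs <- c(outputs, out_name)
    }
  }

  manifest <- list(command = cfg$command,
                   config_hash = config_hash(unclass(cfg)),
                   package_version =
                     as.character(utils::packageVersion("cytoradial")),
                   inputs = if (cfg$command == "simulate") character() else
                     expand_inputs(cfg$inputs),
                   outputs = outputs,
                   failures = failures,
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = as.integer(length(failures) > 0), manifest = manifest))
}
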