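# Orchestration: validated run configurations, an end-to-end synthetic
# retina -> segmentation -> morphometry pipeline with a checksummed
# manifest, and blinded file renaming for manual counting.

knownStages <- c("synth_retina", "segment", "morphometry")

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (typically read from YAML or JSON)
#' with global fields \code{out_dir}, \code{seed}, \code{pixel_size} and
#' \code{stages}, plus optional per-stage parameter blocks under the stage
#' names. Validation errors name the offending field.
#'
#' @param config list, or path to a YAML/JSON file.
#' @return the validated config list, invisibly on success.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  required <- c("out_dir", "seed", "pixel_size", "stages")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (config$pixel_size <= 0) stop("config field pixel_size must be > 0")
  bad <- setdiff(unlist(config$stages), knownStages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(knownStages, collapse = ", "), ")")
  invisible(config)
}

writeStampedCsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# perivasc v", as.character(utils::packageVersion(
    "perivasc")), " seed=", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run the synthetic retina pipeline end to end
#'
#' Executes the configured stages in order -- synthetic retina generation,
#' segmentation (invert/stretch, Phansalkar threshold, size filter) and
#' skeleton morphometry -- writing per-image TIFFs, masks, ground-truth JSON
#' and a morphometry CSV under \code{config$out_dir}, plus a run manifest
#' (parameters, seed, package version, MD5 checksum per output). Re-running
#' the same configuration and seed reproduces identical CSVs. A failing
#' stage aborts the run, removes that stage's partial outputs and reports
#' the stage name.
#'
#' @param config list or YAML/JSON path accepted by [validateRunConfig()].
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- unlist(config$stages)
  ps <- config$pixel_size
  sy <- config$synth_retina
  nImages <- if (is.null(sy$n_images)) 3L else sy$n_images
  manifest <- list(package = "perivasc",
                   version = as.character(utils::packageVersion("perivasc")),
                   seed = config$seed, parameters = config,
                   outputs = character(0))
  state <- new.env()
  runStage <- function(name, fn) {
    before <- list.files(config$out_dir, full.names = TRUE)
    tryCatch(fn(), error = function(e) {
      created <- setdiff(list.files(config$out_dir, full.names = TRUE),
                         before)
      unlink(created)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if ("synth_retina" %in% stages) runStage("synth_retina", function() {
    state$images <- lapply(seq_len(nImages), function(i) {
      cfg <- synthConfig(
        imageSize = if (is.null(sy$image_size)) c(256L, 256L)
                    else as.integer(sy$image_size),
        pixelSize = ps,
        noiseSd = if (is.null(sy$noise_sd)) 0.02 else sy$noise_sd,
        seed = config$seed + i)
      out <- generateRetinaImage(
        cfg,
        nBranches = if (is.null(sy$n_branches)) 4 else sy$n_branches,
        trunkWidth = if (is.null(sy$trunk_width)) 8 * ps
                     else sy$trunk_width,
        branchWidth = if (is.null(sy$branch_width)) 6 * ps
                      else sy$branch_width)
      base <- file.path(config$out_dir, sprintf("retina_%03d", i))
      writeMultiChannelTiff(MultiChannelImage(list(vessel = out$image),
                                              pixelSize = ps),
                            paste0(base, ".tif"))
      writeGroundTruth(list(
        n_branch_points = out$truth$n_branch_points,
        roi_area = out$truth$roi_area,
        mean_tortuosity = mean(vapply(out$truth$segments, `[[`,
                                      numeric(1), "tortuosity")),
        widths_um = vapply(out$truth$segments, `[[`, numeric(1),
                           "width_um")), paste0(base, "_truth.json"))
      out
    })
  })
  if ("segment" %in% stages) runStage("segment", function() {
    sg <- config$segment
    state$masks <- lapply(seq_along(state$images), function(i) {
      pre <- preprocessRoi(state$images[[i]]$image)
      m <- phansalkarThreshold(pre, windowRadius =
        if (is.null(sg$window_radius)) 15L else sg$window_radius)
      m <- filterMask(m,
        minObjectArea = if (is.null(sg$min_object_area)) 25 * ps^2
                        else sg$min_object_area,
        fillHoleArea = if (is.null(sg$fill_hole_area)) 25 * ps^2
                       else sg$fill_hole_area,
        pixelSize = ps)
      writeMultiChannelTiff(
        MultiChannelImage(list(mask = m * 1), pixelSize = ps),
        file.path(config$out_dir, sprintf("mask_%03d.tif", i)))
      m
    })
  })
  if ("morphometry" %in% stages) runStage("morphometry", function() {
    mo <- config$morphometry
    rows <- lapply(seq_along(state$masks), function(i) {
      cbind(image = sprintf("retina_%03d", i),
            morphometry(state$masks[[i]], pixelSize = ps,
                        pruneLen = if (is.null(mo$prune_len)) 8L
                                   else mo$prune_len))
    })
    writeStampedCsv(do.call(rbind, rows),
                    file.path(config$out_dir, "morphometry.csv"),
                    config$seed)
  })
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- data.frame(
    file = basename(files), md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Blind and unblind file names for manual counting
#'
#' Copies the given files under randomised names (a seeded bijection), the
#' digital equivalent of randomising image titles before blinded manual
#' counting; the mapping is stored separately for unblinding.
#'
#' @param files character vector of existing files with unique basenames.
#' @param seed integer seed; the same seed reproduces the same mapping.
#' @param outDir directory receiving the renamed copies.
#' @param mappingFile CSV path for the original-to-blinded mapping.
#' @return \code{blindLabels}: the mapping data.frame, invisibly;
#'   \code{unblindLabels}: the restored file paths, invisibly.
#' @export
blindLabels <- function(files, seed, outDir,
                        mappingFile = file.path(outDir,
                                                "blind_mapping.csv")) {
  if (anyDuplicated(basename(files)))
    stop("file basenames must be unique")
  if (!all(file.exists(files))) stop("missing input file(s)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- length(files)
  perm <- withSeed(seed, sample.int(n))
  ext <- sub("^[^.]*\\.?", "", basename(files))
  blinded <- sprintf("blind_%04d%s", perm,
                     ifelse(ext == "", "", paste0(".", ext)))
  if (anyDuplicated(blinded)) stop("blinded name collision")
  ok <- file.copy(files, file.path(outDir, blinded), overwrite = FALSE)
  if (!all(ok)) stop("failed to copy ", sum(!ok), " file(s)")
  map <- data.frame(original = basename(files), blinded = blinded)
  utils::write.csv(map, mappingFile, row.names = FALSE)
  invisible(map)
}

#' @rdname blindLabels
#' @param blindDir directory holding the blinded copies.
#' @param restoreDir directory receiving files under their original names.
#' @export
unblindLabels <- function(mappingFile, blindDir, restoreDir) {
  map <- utils::read.csv(mappingFile, stringsAsFactors = FALSE)
  dir.create(restoreDir, showWarnings = FALSE, recursive = TRUE)
  src <- file.path(blindDir, map$blinded)
  dst <- file.path(restoreDir, map$original)
  ok <- file.copy(src, dst, overwrite = FALSE)
  if (!all(ok)) stop("failed to restore ", sum(!ok), " file(s)")
  invisible(dst)
}
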