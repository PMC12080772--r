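# Image, manifest, configuration and checkpoint I/O. Images travel as 8-bit
# PNG (grayscale for OCT, RGB for fundus); labels and lesion counts as CSV
# manifests; counterfactual metadata as JSON sidecars; checkpoints as a
# serialized container of the numeric arrays plus a metadata block.

#' Write an image as 8-bit PNG
#'
#' @param path Output path.
#' @param pixels H x W matrix (grayscale) or H x W x 3 array, values in
#'   `[0,1]`.
#' @return The path, invisibly.
#' @export
write_image <- function(path, pixels) {
  if (any(pixels < 0) || any(pixels > 1)) stop("pixels must lie in [0,1]")
  png::writePNG(pixels, path)
  invisible(path)
}

#' Read a PNG image
#'
#' @param path PNG file path.
#' @return H x W matrix or H x W x C array in `[0,1]`.
#' @export
read_image <- function(path) png::readPNG(path)

manifest_required_cols <- c("path", "subject_id", "split", "label")

#' Write a dataset to a directory of PNGs with a CSV manifest
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$images), function(i) {
    im <- dataset$images[[i]]
    fn <- sprintf("img_%04d.png", i)
    write_image(file.path(dir, fn), im$pixels)
    cbind(data.frame(path = fn, subject_id = im$subject_id,
                     split = dataset$split[i], label = im$grade),
          as.data.frame(as.list(im$lesion_counts)))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image directory through its manifest
#'
#' @param dir Directory containing PNGs and `manifest.csv`.
#' @param manifest Optional manifest path (default `dir/manifest.csv`).
#' @return List with `X` (flattened image rows) and the `manifest` data
#'   frame; errors when a required manifest column is missing.
#' @export
read_image_dir <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_required_cols, names(mf))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  X <- do.call(rbind, lapply(mf$path, function(p) {
    as.vector(read_image(file.path(dir, p)))
  }))
  list(X = X, manifest = mf)
}

#' Write a counterfactual image with a JSON sidecar
#'
#' @param result A `counterfactual_result`.
#' @param path PNG output path; the sidecar lands at `path` with extension
#'   `.json`.
#' @param i Row index within the result batch.
#' @param img_dim Image dimensions for reshaping the stored row.
#' @return The sidecar list, invisibly.
#' @export
write_counterfactual <- function(result, path, i = 1L, img_dim) {
  px <- array(result$image[i, ], dim = img_dim)
  write_image(path, px)
  side <- list(target = result$target,
               target_confidence = result$target_confidence[i],
               l2_distance = result$l2_distance[i],
               flipped = result$flipped[i])
  jsonlite::write_json(side, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(side)
}

# --- configuration -------------------------------------------------------

config_defaults <- function(component) {
  switch(component,
         guidance = formals(guidance_config),
         svc = formals(svc_config),
         attack = formals(attack_config),
         phantom = formals(phantom_config),
         stop("unknown component '", component, "'"))
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON file, rejects unknown keys, fills unset keys with
#' the component's defaults, and runs the component constructor (which
#' enforces the value constraints, e.g. `lambda_d >= 0`). An empty file
#' yields all defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param component One of `"guidance"`, `"svc"`, `"attack"`, `"phantom"`.
#' @return The validated configuration object.
#' @export
load_config <- function(path, component = "guidance") {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(config_defaults(component))
  known <- known[known != "..."]
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s) for ", component, ": ",
         paste(unknown, collapse = ", "))
  }
  ctor <- switch(component, guidance = guidance_config, svc = svc_config,
                 attack = attack_config, phantom = phantom_config)
  do.call(ctor, vals)
}

#' Save a configuration object to YAML
#'
#' @param config A configuration list (e.g. from [guidance_config()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# --- checkpoints ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Stores the object's numeric arrays together with a metadata block
#' (class, creation time, and a content hash of the serialized parameters).
#'
#' @param object A `denoiser` or `retina_classifier`.
#' @param path Output path.
#' @return The metadata block, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  meta <- list(class = class(object)[1],
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               hash = sum(vapply(object$net$W, function(w) sum(abs(w)), 0)))
  saveRDS(list(object = object, meta = meta), path)
  invisible(meta)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path from [save_checkpoint()].
#' @return The stored object, with the metadata attached as attribute
#'   `"meta"`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  obj <- ck$object
  attr(obj, "meta") <- ck$meta
  obj
}
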