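#' Parse underscore-delimited sample metadata from an image file name
#'
#' Confocal images are acquired with file names that encode the sample
#' description as six underscore-separated tokens: plate location, antibody,
#' genotype, age, tissue type, and biological replicate, e.g.
#' `"C08R6_LM10_Col_21-day-old_Hyp_BR1"`. Any file extension is stripped
#' before tokenising. Tokens are opaque strings used only as grouping
#' factors.
#'
#' @param name File name (basename, without directory components).
#' @return A one-row tibble with columns `plate_location`, `antibody`,
#'   `genotype`, `age`, `tissue`, `replicate`.
#' @seealso [format_image_filename()] for the inverse.
#' @examples
#' parse_image_filename("C08R6_LM10_Col_21-day-old_Hyp_BR1")
#' @export
parse_image_filename <- function(name) {
  if (length(name) != 1L || !is.character(name))
    rc_abort("`name` must be a single file name", "rc_type_error")
  if (name != basename(name))
    rc_abort("`name` must be a basename without directory components",
             "rc_malformed_name")
  stem <- tools::file_path_sans_ext(name)
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(tokens) != 6L || any(!nzchar(tokens)))
    rc_abort(
      sprintf(
        "malformed image name '%s': expected 6 non-empty underscore-delimited tokens (plate_antibody_genotype_age_tissue_replicate), found %d",
        name, sum(nzchar(tokens))
      ),
      "rc_malformed_name"
    )
  tibble::tibble(
    plate_location = tokens[1], antibody = tokens[2], genotype = tokens[3],
    age = tokens[4], tissue = tokens[5], replicate = tokens[6]
  )
}

#' Format sample metadata back into the canonical file-name stem
#'
#' @param metadata One-row tibble as returned by [parse_image_filename()].
#' @return The underscore-delimited stem (no extension).
#' @export
format_image_filename <- function(metadata) {
  cols <- c("plate_location", "antibody", "genotype", "age", "tissue",
            "replicate")
  if (!all(cols %in% names(metadata)))
    rc_abort("metadata must contain the six sample-metadata columns",
             "rc_type_error")
  paste(unlist(metadata[1, cols]), collapse = "_")
}

#' Construct a two-channel image object
#'
#' Bundles the cell-wall counterstain (reference) channel used for
#' segmentation, the immunofluorescence (signal) channel, the pixel size and
#' the sample metadata. Rasters are numeric matrices with non-negative
#' intensities; both channels must share dimensions.
#'
#' @param reference Counterstain channel, numeric matrix.
#' @param signal Immunofluorescence channel, numeric matrix, same shape.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param metadata Optional one-row metadata tibble
#'   (see [parse_image_filename()]).
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(reference, signal, pixel_size_um,
                              metadata = NULL) {
  stopifnot_matrix(reference)
  stopifnot_matrix(signal)
  if (!identical(dim(reference), dim(signal)))
    rc_abort("reference and signal channels must share dimensions",
             "rc_shape_error")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    rc_abort("`pixel_size_um` must be a positive scalar", "rc_type_error")
  if (any(reference < 0) || any(signal < 0))
    rc_abort("channel intensities must be non-negative", "rc_type_error")
  structure(
    list(reference = reference, signal = signal,
         pixel_size_um = pixel_size_um, metadata = metadata),
    class = "two_channel_image"
  )
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, %.3g um/px\n",
              nrow(x$reference), ncol(x$reference), x$pixel_size_um))
  if (!is.null(x$metadata))
    cat("  sample:", format_image_filename(x$metadata), "\n")
  invisible(x)
}

#' Load a two-channel TIFF image
#'
#' Accepts both multi-channel dialects: a single page with two samples per
#' pixel, or two grayscale pages (page 1 = reference counterstain, page 2 =
#' immunofluorescence signal). Intensities are read at their stored integer
#' scale.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param metadata Optional metadata tibble; if `NULL`, an attempt is made to
#'   parse it from the file name, falling back to `NULL` on failure.
#' @return A [two_channel_image()].
#' @export
load_two_channel_image <- function(path, pixel_size_um, metadata = NULL) {
  if (!file.exists(path))
    rc_abort(sprintf("image file '%s' does not exist", path), "rc_io_error")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF normalises intensities to [0, 1]; restore the stored scale
  denorm <- function(p) {
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    round(p * (2^bits - 1))
  }
  pages <- lapply(pages, denorm)
  if (length(pages) == 1L) {
    arr <- pages[[1]]
    nch <- if (length(dim(arr)) == 3L) dim(arr)[3] else 1L
    if (nch != 2L)
      rc_abort(sprintf("expected a 2-channel TIFF, found %d channel(s) in '%s'",
                       nch, path), "rc_channel_error")
    ref <- arr[, , 1]
    sig <- arr[, , 2]
  } else if (length(pages) == 2L) {
    dims <- lapply(pages, dim)
    if (any(vapply(dims, length, 1L) != 2L))
      rc_abort("multi-page TIFF must contain grayscale pages",
               "rc_channel_error")
    ref <- pages[[1]]
    sig <- pages[[2]]
  } else {
    rc_abort(sprintf("expected a 2-channel TIFF, found %d pages in '%s'",
                     length(pages), path), "rc_channel_error")
  }
  if (is.null(metadata)) {
    metadata <- tryCatch(parse_image_filename(basename(path)),
                         error = function(e) NULL)
  }
  two_channel_image(ref, sig, pixel_size_um, metadata)
}

#' Write a two-channel image as a two-page 16-bit TIFF
#'
#' Intensities are rounded to integers and stored at 16-bit depth, so images
#' with integer intensities in \[0, 65535\] round-trip exactly through
#' [load_two_channel_image()].
#'
#' @param image A [two_channel_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_channel_image <- function(image, path) {
  sc <- 65535
  pages <- list(round(image$reference) / sc, round(image$signal) / sc)
  if (max(image$reference, image$signal) > sc)
    rc_abort("intensities exceed the 16-bit storage range", "rc_io_error")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Build the experiment catalogue from a folder of images
#'
#' Scans `source_folder` for TIFF images with parseable six-token names,
#' creates a fresh time-stamped output folder `<title>_<timestamp>` under
#' `output_root`, and persists the catalogue (one record per image, with its
#' parsed metadata) as `catalog.json` inside it. Re-running with the same
#' title creates a new folder; prior outputs are never touched. Files whose
#' names do not parse are skipped with a warning.
#'
#' @param source_folder Folder containing the images.
#' @param experiment_title Working title for the experiment.
#' @param output_root Where to create the time-stamped folder (defaults to
#'   `source_folder`'s parent).
#' @return An `experiment_catalog`: a tibble with one row per image
#'   (`image_id`, metadata columns, `source_path`), carrying the experiment
#'   title and output directory as attributes.
#' @export
build_experiment_catalog <- function(source_folder, experiment_title,
                                     output_root = dirname(source_folder)) {
  if (!dir.exists(source_folder))
    rc_abort(sprintf("source folder '%s' does not exist", source_folder),
             "rc_io_error")
  files <- list.files(source_folder, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L)
    rc_abort(sprintf("no TIFF images found in '%s'", source_folder),
             "rc_empty_catalog")
  parsed <- lapply(files, function(f) {
    tryCatch(parse_image_filename(basename(f)), error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    rc_warn(sprintf("skipping %d file(s) with unparseable names: %s",
                    sum(bad), paste(basename(files[bad]), collapse = ", ")),
            "rc_skipped_files")
  if (all(bad))
    rc_abort("no images with parseable names found", "rc_empty_catalog")
  files <- files[!bad]
  meta <- dplyr::bind_rows(parsed[!bad])
  records <- dplyr::bind_cols(
    tibble::tibble(image_id = tools::file_path_sans_ext(basename(files))),
    meta,
    tibble::tibble(source_path = normalizePath(files))
  )
  stamp <- format(Sys.time(), "%Y-%m-%dT%H-%M-%OS3")
  out_dir <- file.path(output_root, paste0(experiment_title, "_", stamp))
  dir.create(out_dir, recursive = TRUE)
  catalog <- structure(records, class = c("experiment_catalog", class(records)),
                       title = experiment_title, output_dir = out_dir)
  write_experiment_catalog(catalog)
  catalog
}

catalog_path <- function(catalog) {
  file.path(attr(catalog, "output_dir"), "catalog.json")
}

#' Persist the experiment catalogue to its output folder
#' @param catalog An `experiment_catalog`.
#' @return The catalogue, invisibly.
#' @export
write_experiment_catalog <- function(catalog) {
  payload <- list(
    title = attr(catalog, "title"),
    output_dir = attr(catalog, "output_dir"),
    records = as.data.frame(catalog)
  )
  jsonlite::write_json(payload, catalog_path(catalog), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(catalog)
}

#' Read an experiment catalogue back from disk
#' @param path Path to a `catalog.json` (or the folder containing it).
#' @return The `experiment_catalog`.
#' @export
read_experiment_catalog <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "catalog.json")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  records <- tibble::as_tibble(payload$records)
  structure(records, class = c("experiment_catalog", class(records)),
            title = payload$title, output_dir = payload$output_dir)
}

#' Register a per-stage output file for an image in the catalogue
#'
#' @param catalog An `experiment_catalog`.
#' @param image_id Image id (file-name stem).
#' @param stage Short stage name, e.g. `"quantified"`, `"segmentation"`.
#' @param path Path of the stored output.
#' @return The updated catalogue (also persisted).
#' @export
catalog_register_output <- function(catalog, image_id, stage, path) {
  col <- paste0("path_", stage)
  if (!col %in% names(catalog)) catalog[[col]] <- NA_character_
  row <- which(catalog$image_id == image_id)
  if (length(row) != 1L)
    rc_abort(sprintf("image id '%s' not in catalogue", image_id),
             "rc_catalog_error")
  catalog[[col]][row] <- path
  write_experiment_catalog(catalog)
  catalog
}

#' Export the compiled per-cell result table ("DataRawCompile")
#'
#' Concatenates the per-image quantified cell tables registered in the
#' catalogue into one CSV with one row per retained cell: image id, the six
#' metadata tokens, cell id, class, confidence, all 22 morphometric features,
#' the per-quadrant measures (ROI-kind-major C, L, W; quadrants 1-4), and the
#' derived fluorescence measures.
#'
#' @param catalog An `experiment_catalog` whose selected records carry a
#'   registered `"quantified"` output (see [catalog_register_output()]).
#' @param factor_filter Named list mapping metadata factors to allowed
#'   tokens, e.g. `list(antibody = "LM10")`. `NULL` selects everything.
#' @param out Output CSV path; defaults to `DataRawCompile.csv` in the
#'   catalogue's output folder.
#' @return The compiled tibble, invisibly; the CSV is written to `out`.
#' @export
export_compiled_data <- function(catalog, factor_filter = NULL, out = NULL) {
  sel <- catalog
  for (fac in names(factor_filter)) {
    if (!fac %in% names(sel))
      rc_abort(sprintf("unknown metadata factor '%s'", fac), "rc_filter_error")
    sel <- sel[sel[[fac]] %in% factor_filter[[fac]], , drop = FALSE]
  }
  if (nrow(sel) == 0L)
    rc_abort("factor filter selects zero images", "rc_filter_error")
  if (!"path_quantified" %in% names(sel) || anyNA(sel$path_quantified))
    rc_abort("selected records lack quantification outputs", "rc_catalog_error")
  meta_cols <- c("plate_location", "antibody", "genotype", "age", "tissue",
                 "replicate")
  parts <- purrr::map2(sel$path_quantified, seq_len(nrow(sel)), function(p, i) {
    cells <- readr::read_csv(p, show_col_types = FALSE)
    dplyr::bind_cols(
      tibble::tibble(image_id = sel$image_id[i]),
      sel[rep(i, nrow(cells)), meta_cols],
      cells
    )
  })
  compiled <- dplyr::bind_rows(parts)
  if (is.null(out))
    out <- file.path(attr(catalog, "output_dir"), "DataRawCompile.csv")
  readr::write_csv(compiled, out)
  invisible(compiled)
}
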