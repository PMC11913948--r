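MAP_KINDS <- c("wt1", "pdff", "b0", "water", "fat", "composite")

#' Write / read parameter maps and complex series as NIfTI
#'
#' Real-valued maps (`wt1`, `pdff`, `b0`) are stored as 2D/3D volumes;
#' complex series (`water`, `fat`, `composite`) as paired real/imaginary
#' volumes along a trailing dimension. Voxel geometry encodes the slice gap
#' as center-to-center slice spacing (thickness + gap). A JSON sidecar with
#' the kind, geometry, seed and config hash is written next to the image.
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param data Numeric matrix/array (maps) or complex array (series).
#' @param kind One of `"wt1"`, `"pdff"`, `"b0"`, `"water"`, `"fat"`,
#'   `"composite"`.
#' @param voxel_mm In-plane voxel size (length 2) in mm.
#' @param slice_thickness_mm,slice_gap_mm Through-plane geometry in mm.
#' @param seed,config_hash Provenance recorded in the sidecar.
#' @return `write_map()` the path invisibly; `read_map()` a list with
#'   `data`, `kind` and the sidecar `meta`.
#' @export
write_map <- function(path, data, kind, voxel_mm = c(2, 2),
                      slice_thickness_mm = 5, slice_gap_mm = 1,
                      seed = NULL, config_hash = NULL) {
  kind <- match.arg(kind, MAP_KINDS)
  complex_kind <- kind %in% c("water", "fat", "composite")
  if (complex_kind) {
    stopifnot(is.complex(data))
    arr <- array(c(Re(data), Im(data)), c(dim(data), 2))
  } else {
    stopifnot(is.numeric(data))
    arr <- data
  }
  spacing <- slice_thickness_mm + slice_gap_mm
  pixdim <- c(voxel_mm, spacing, rep(1, max(0, length(dim(arr)) - 3)))
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- pixdim[seq_along(dim(arr))]
  RNifti::writeNifti(img, path, datatype = "float")
  meta <- list(kind = kind, complex = complex_kind, voxel_mm = voxel_mm,
               slice_thickness_mm = slice_thickness_mm,
               slice_gap_mm = slice_gap_mm,
               slice_spacing_mm = spacing,
               seed = seed, config_hash = config_hash)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map
#' @param expect_kind If given, reading a file whose sidecar kind differs
#'   raises an error.
#' @export
read_map <- function(path, expect_kind = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(expect_kind) && !identical(meta$kind, expect_kind)) {
    stop(sprintf("map kind mismatch: file is '%s', expected '%s'",
                 meta$kind, expect_kind))
  }
  arr <- as.array(RNifti::readNifti(path))
  if (isTRUE(meta$complex)) {
    nd <- length(dim(arr))
    half <- dim(arr)[nd]
    stopifnot(half == 2)
    idx_re <- slice.index(arr, nd) == 1
    re <- array(arr[idx_re], dim(arr)[-nd])
    im <- array(arr[!idx_re], dim(arr)[-nd])
    arr <- re + 1i * im
  }
  list(data = arr, kind = meta$kind, meta = meta)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read / write pipeline configuration as YAML
#'
#' The YAML schema has top-level sections `sequence` (fields of
#' [seq_config()]), `fat_model` (`name` or explicit peak table),
#' `dictionary` (`t1_min`, `t1_max`, `t1_step`, `t2_ms`), `phantom`
#' (fields of [phantom_spec()]), and scalars `mode` and `seed`. Missing
#' sections fall back to the package defaults, which are the stated
#' acquisition parameters.
#'
#' @param path YAML file.
#' @return A list with elements `config`, `fat_model`, `dictionary_args`,
#'   `phantom`, `mode`, `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(seq_config, raw$sequence %||% list())
  fm <- parse_fat_model(raw$fat_model)
  dict_args <- raw$dictionary %||% list()
  ph <- if (is.null(raw$phantom)) phantom_spec() else {
    pargs <- raw$phantom
    if (!is.null(pargs$vials)) pargs$vials <- as.data.frame(pargs$vials)
    do.call(phantom_spec, pargs)
  }
  list(config = cfg, fat_model = fm, dictionary_args = dict_args,
       phantom = ph, mode = raw$mode %||% "image_space",
       seed = raw$seed %||% 1L)
}

#' @rdname read_config
#' @param config A list as returned by [read_config()] (or compatible).
#' @export
write_config <- function(config, path) {
  fm <- config$fat_model
  yaml::write_yaml(list(
    sequence = unclass(config$config),
    fat_model = list(name = fm$name, peak_shift_ppm = fm$peak_shift_ppm,
                     rel_amplitudes = fm$rel_amplitudes,
                     field_T = fm$field_T),
    dictionary = config$dictionary_args,
    phantom = c(unclass(config$phantom)[c("matrix_size", "fov_mm",
                                          "background", "noise_sigma",
                                          "seed")],
                list(vials = as.list(config$phantom$vials))),
    mode = config$mode,
    seed = config$seed
  ), path, precision = 15)
  invisible(path)
}

parse_fat_model <- function(x) {
  if (is.null(x)) return(fat_model_7peak())
  if (!is.null(x$peak_shift_ppm)) {
    return(fat_model(unlist(x$peak_shift_ppm), unlist(x$rel_amplitudes),
                     x$field_T %||% 3, x$name %||% "custom"))
  }
  switch(x$name,
         "7peak_invivo" = fat_model_7peak(x$field_T %||% 3),
         "10peak_peanut_oil" = fat_model_peanut10(x$field_T %||% 3),
         stop("unknown fat model: ", x$name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
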