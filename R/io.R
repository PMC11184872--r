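#' Map and mask export
#'
#' Scalar maps and structure masks are written as NIfTI-1 volumes (via
#' RNifti) with the voxel spacing in the header; grid origin, units and kind
#' go into a JSON sidecar next to the volume, since NIfTI has no units field
#' for dose. `write_map_nrrd` writes the same data as a minimal NRRD file
#' (raw little-endian encoding) for toolchains that prefer NRRD.
#'
#' @param map a [scalar_map()] (or `mdr_map`); for masks, a
#'   [structure_mask()].
#' @param path output path (`.nii` / `.nii.gz`, or `.nrrd`).
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(map, path, sidecar = TRUE) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$grid$spacing
  RNifti::writeNifti(img, path)
  if (sidecar) {
    meta <- list(units = map$units %||% "", kind = map$kind %||% "scalar",
                 origin_mm = map$grid$origin, spacing_mm = map$grid$spacing,
                 dims = map$grid$dims)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
write_mask_nifti <- function(mask, path, sidecar = TRUE) {
  m <- scalar_map(mask$grid, array(as.integer(mask$voxels),
                                   dim = mask$grid$dims),
                  units = "binary", kind = paste0("mask:", mask$name))
  write_map_nifti(m, path, sidecar)
}

#' @rdname write_map_nifti
#' @param grid the [voxel_grid()] the volume lives on (for reading).
#' @return `read_map_nifti`: a [scalar_map()].
#' @export
read_map_nifti <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  meta_path <- paste0(path, ".json")
  units <- ""; kind <- "scalar"; origin <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    units <- meta$units %||% ""; kind <- meta$kind %||% "scalar"
    origin <- meta$origin_mm
  }
  if (is.null(grid))
    grid <- voxel_grid(dim(img), RNifti::pixdim(img)[1:3], origin)
  scalar_map(grid, vals, units = units, kind = kind)
}

#' @rdname write_map_nifti
#' @export
write_map_nrrd <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by pbsmdr",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", map$grid$dims[1], map$grid$dims[2],
                   map$grid$dims[3]),
           "space: left-posterior-superior",
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   map$grid$spacing[1], map$grid$spacing[2],
                   map$grid$spacing[3]),
           sprintf("space origin: (%g,%g,%g)", map$grid$origin[1],
                   map$grid$origin[2], map$grid$origin[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(map$values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_map_nifti
#' @return `read_map_nrrd`: a [scalar_map()] (raw little-endian NRRD only).
#' @export
read_map_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || ln == "") break
    hdr <- c(hdr, ln)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("NRRD header missing field: ", key)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  if (get_field("encoding") != "raw") stop("only raw NRRD encoding supported")
  dims <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.]+", s))[[1]])
  dirs <- nums(get_field("space directions"))
  spacing <- dirs[c(1, 5, 9)]
  origin <- nums(get_field("space origin"))
  vals <- readBin(con, numeric(), n = prod(dims), size = 8, endian = "little")
  scalar_map(voxel_grid(dims, spacing, origin), array(vals, dim = dims))
}

#' Spot-map CSV and cohort roster JSON
#'
#' The spot-map dialect is a CSV with header
#' `field_id,spot_id,energy_mev,x_mm,y_mm,mu`. The roster JSON stores the
#' per-case prescription, fractionation, toxicity grade, index flag and field
#' list.
#'
#' @param spots spot data.frame (extra columns are dropped on write).
#' @param path file path.
#' @export
write_spot_map_csv <- function(spots, path) {
  utils::write.csv(spots[, c("field_id", "spot_id", "energy_mev",
                             "x_mm", "y_mm", "mu")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_map_csv
#' @export
read_spot_map_csv <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "spot_id", "energy_mev", "x_mm", "y_mm", "mu")
  if (!all(need %in% names(sp)))
    stop("spot map is missing columns: ",
         paste(setdiff(need, names(sp)), collapse = ", "))
  if (any(sp$mu <= 0)) stop("spot map contains non-positive mu")
  sp
}

#' @rdname write_spot_map_csv
#' @param cohort list of `plan_case` objects from [make_cohort()].
#' @export
write_roster_json <- function(cohort, path) {
  roster <- lapply(cohort, function(cs) list(
    case_id = cs$case_id, diagnosis = cs$diagnosis,
    prescribed_dose = cs$prescribed_dose, fraction_dose = cs$fraction_dose,
    n_fractions = cs$n_fractions, toxicity_grade = cs$toxicity_grade,
    index_flag = cs$index_flag,
    fields = cs$fields, n_spots = nrow(cs$spots)))
  jsonlite::write_json(roster, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
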