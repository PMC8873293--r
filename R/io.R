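#' Read a volume from NIfTI
#'
#' Loads a 3D NIfTI file as a [vol_grid()]; files with an integer datatype
#' (or when `as_labels = TRUE`) load as a [label_map()]. Non-RAS
#' orientations are reoriented to the canonical axis-aligned RAS
#' convention with a warning.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param as_labels force loading as a label map.
#' @return a [vol_grid()] or [label_map()].
#' @export
read_volume <- function(path, as_labels = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  }
  if (!identical(RNifti::orientation(img), "RAS")) {
    warning("reorienting ", path, " from ", RNifti::orientation(img),
            " to RAS")
    RNifti::orientation(img) <- "RAS"
  }
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  hdr <- RNifti::niftiHeader(img)
  data <- array(as.numeric(img), dim(img))
  integer_type <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  lab <- if (is.na(as_labels)) {
    integer_type && all(data >= 0) && all(data <= 8) &&
      all(data == round(data))
  } else {
    as_labels
  }
  if (lab) label_map(data, spacing, origin) else
    vol_grid(data, spacing, origin)
}

#' Write a volume to NIfTI
#'
#' @param vg a [vol_grid()] or [label_map()]; label maps are stored with an
#'   integer datatype.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vg, path) {
  affine <- diag(c(vg$spacing, 1))
  affine[1:3, 4] <- vg$origin
  img <- RNifti::asNifti(vg$data)
  RNifti::pixdim(img) <- vg$spacing
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(
    img, path,
    datatype = if (inherits(vg, "label_map")) "uint8" else "double")
  invisible(path)
}

SCHEMA <- "couinaud3d/v1"

#' Write a landmark set to JSON
#'
#' Coordinates are physical mm; polylines are n x 3 arrays under the named
#' keys `IVC`, `MHV`, `RHV`, `LHV`, `LLF`, `GB_vertex`, `RPV`, `LPV_sag`,
#' `VL_fissure`.
#'
#' @param landmarks a [landmark_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  payload <- c(list(schema = SCHEMA),
               lapply(unclass(landmarks), function(v) {
                 if (is.matrix(v)) unname(v) else unname(as.numeric(v))
               }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a landmark set from JSON
#' @param path JSON file from [write_landmarks()].
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, SCHEMA)) {
    stop("unrecognized landmark schema in ", path)
  }
  landmark_set(IVC = j$IVC, MHV = j$MHV, RHV = j$RHV, LHV = j$LHV,
               LLF = j$LLF, GB_vertex = j$GB_vertex, RPV = j$RPV,
               LPV_sag = j$LPV_sag, VL_fissure = j$VL_fissure,
               ivc_radius_mm = j$ivc_radius_mm %||% 8)
}

#' Write lesion ground truth to JSON
#'
#' Stores centre (mm), diameter (mm), intensity type and true segment set
#' per lesion; voxel masks are reconstructed from the sphere geometry on
#' load.
#'
#' @param lesions list of `lesion` objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lesions <- function(lesions, path) {
  payload <- list(schema = SCHEMA, lesions = lapply(lesions, function(l) {
    list(id = l$id, center_mm = unname(l$center_mm),
         diameter_mm = l$diameter_mm, type = l$type,
         true_segments = as.integer(l$true_segments))
  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read lesion ground truth from JSON
#'
#' @param path JSON file from [write_lesions()].
#' @param grid a [vol_grid()]/[label_map()] defining the voxel grid on
#'   which lesion masks are reconstructed.
#' @return list of `lesion` objects.
#' @export
read_lesions <- function(path, grid) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, SCHEMA)) {
    stop("unrecognized lesion schema in ", path)
  }
  les <- j$lesions
  if (is.null(les) || (is.data.frame(les) && nrow(les) == 0)) return(list())
  if (is.data.frame(les)) {
    les <- lapply(seq_len(nrow(les)), function(i) as.list(les[i, ]))
  }
  lapply(les, function(l) {
    vox <- sphere_voxels(grid, unlist(l$center_mm), l$diameter_mm)
    lesion <- new_lesion(l$id, unlist(l$center_mm), l$diameter_mm, vox,
                         integer(0), l$type)
    lesion$true_segments <- sort(as.integer(unlist(l$true_segments)))
    lesion
  })
}

#' Split a set of case manifests into train/validation/test
#'
#' Seeded shuffle followed by a contiguous split. The default fractions
#' 0.54/0.23/0.23 mirror a 367/157/158 train/validation/test design.
#'
#' @param manifests data.frame with one row per case (any columns).
#' @param fractions length-3 nonnegative fractions summing to 1.
#' @param seed integer.
#' @return the manifest data.frame with a `split` column
#'   (`train`/`val`/`test`).
#' @export
split_dataset <- function(manifests, fractions = c(0.54, 0.23, 0.23),
                          seed = 1L) {
  n <- nrow(manifests)
  if (is.null(n) || n == 0) stop("empty manifest list")
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            isTRUE(all.equal(sum(fractions), 1)))
  with_seed(seed, {
    ord <- sample.int(n)
    counts <- diff(c(0L, round(cumsum(fractions) * n)))
    tags <- rep(c("train", "val", "test"), counts)
    manifests$split <- tags[order(ord)]
    manifests
  })
}
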