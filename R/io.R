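#' Write and read a BOLD series or 3D map as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} that preserve the affine and repetition
#' time. Masks are written as 0/1 volumes.
#'
#' @param series a [bold_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (writers); a [bold_series()] (reader).
#' @export
write_bold_nifti <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$data, reference = list(
    pixdim = c(-1, voxel_sizes(series$affine), series$tr_seconds, 0, 0, 0)))
  RNifti::qform(img) <- structure(series$affine, code = 2L)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param tr_seconds repetition time to attach when the header lacks one.
#' @export
read_bold_nifti <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  tr <- tr_seconds %||% unname(RNifti::pixdim(img)[4])
  if (is.na(tr) || tr <= 0) tr <- 3
  bold_series(array(as.vector(img, mode = "double"), dim = dim(img)),
              affine = aff, tr_seconds = tr)
}

#' @rdname write_bold_nifti
#' @param map a [gfcd_map()] or a 3D array (values or mask).
#' @param affine affine for plain arrays.
#' @export
write_map_nifti <- function(map, path, affine = NULL) {
  if (inherits(map, "gfcd_map")) {
    data <- map$data
    affine <- map$affine
  } else {
    data <- map * 1  # logical -> numeric
    affine <- affine %||% make_affine(dim = dim(data))
  }
  img <- RNifti::asNifti(data)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Phenotype table and motion-trace text I/O
#'
#' Phenotypes are tab-separated with a header; motion traces are the
#' conventional 6 whitespace-separated columns per frame (translations mm,
#' rotations radians), no header.
#'
#' @param pheno phenotype data frame.
#' @param path file path.
#' @return `path` invisibly (writers); a data frame / matrix (readers).
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_phenotypes
#' @param motion n x 6 motion matrix.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

#' Read or write a run configuration as YAML
#'
#' Configurations round-trip unchanged (up to numeric representation).
#'
#' @param config a [default_run_config()]-shaped list.
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `run_config` list (reader).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("grid_shape", "voxel_mm")) {
    cfg$cohort[[f]] <- as.numeric(cfg$cohort[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Write a cluster report as TSV with a JSON sidecar
#'
#' The TSV carries the per-cluster table (sizes in voxels and mm3, peak world
#' coordinates and statistics); the sidecar records the thresholds,
#' connectivity rule and extent threshold that produced it.
#'
#' @param report a [form_clusters()] result.
#' @param path TSV path; the sidecar is written next to it as `.json`.
#' @return `path` invisibly.
#' @export
write_cluster_report <- function(report, path) {
  stopifnot(inherits(report, "cluster_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(voxel_p = report$voxel_p, k_min = report$k_min,
                            connectivity = report$connectivity),
                       side, auto_unbox = TRUE)
  invisible(path)
}
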