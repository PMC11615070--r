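# On-disk formats: NIfTI-1 (.nii.gz) for volumes, HDF5 for MEG sensor arrays
# (one file per subject, dataset `data` plus `fs` / `subject_id` attributes),
# and TSV for the subject metadata table.

#' Write / read an MRI volume as NIfTI-1
#'
#' The affine is stored as the sform; the round trip preserves voxel data
#' exactly at the stored precision and the spatial metadata.
#'
#' @param volume An `nf_mri` (see [generate_mri()]) or a bare 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `read_nifti()` returns an `nf_mri`.
#' @export
write_nifti <- function(volume, path) {
  if (!inherits(volume, "nf_mri"))
    volume <- structure(list(data = volume, voxel_size = c(1, 1, 1),
                             affine = diag(4), subject_id = ""),
                        class = "nf_mri")
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`pixdim<-`(img, volume$voxel_size)
  aff <- structure(volume$affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @param subject_id Subject identifier attached to the returned object.
#' @export
read_nifti <- function(path, subject_id = "") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 voxel_size = RNifti::pixdim(img)[1:3],
                 affine = matrix(as.numeric(aff), 4, 4),
                 subject_id = subject_id),
            class = "nf_mri")
}

#' Write / read a MEG recording as HDF5
#'
#' One file per subject with a float dataset `data` (sensors x samples) and
#' attributes `fs` and `subject_id`.
#'
#' @param rec An `nf_meg` (see [generate_meg()]).
#' @param path Output `.h5` path.
#' @return `read_meg_h5()` returns an `nf_meg`.
#' @export
write_meg_h5 <- function(rec, path) {
  stopifnot(inherits(rec, "nf_meg"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  rhdf5::h5writeAttribute(rec$fs, did, "fs")
  rhdf5::h5writeAttribute(rec$subject_id, did, "subject_id")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_meg_h5
#' @export
read_meg_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- tryCatch(rhdf5::h5read(path, "data", read.attributes = TRUE),
                  error = function(e) stop("malformed MEG container '", path,
                                           "': ", conditionMessage(e)))
  at <- attributes(dat)
  structure(list(data = matrix(as.numeric(dat), nrow(dat), ncol(dat)),
                 fs = as.numeric(at$fs %||% NA_real_),
                 subject_id = as.character(at$subject_id %||% "")),
            class = "nf_meg")
}

#' Write / read the subject metadata table as TSV
#'
#' @param cohort An `nf_cohort` data.frame.
#' @param path Output `.tsv` path.
#' @return `read_cohort_tsv()` returns an `nf_cohort`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort)[, c("id", "group", "site", "sex",
                                               "age", "education", "mmse",
                                               "recording_duration")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("id", "group", "site", "sex", "age", "education", "mmse",
            "recording_duration")
  if (!all(need %in% names(tab)))
    stop("metadata TSV is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  class(tab) <- c("nf_cohort", "data.frame")
  tab
}

#' Write a generated dataset to a directory
#'
#' Lays out `cohort.tsv`, `meg/<id>.h5` and `mri/<id>.nii.gz`; the directory
#' can be read back with [read_dataset_dir()] and consumed by [nf_train()].
#'
#' @param ds An `nf_dataset` from [generate_dataset()].
#' @param dir Output directory.
#' @param fs MEG sampling rate recorded in the containers.
#' @return The directory, invisibly.
#' @export
write_dataset_dir <- function(ds, dir, fs = 500) {
  dir.create(file.path(dir, "meg"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "mri"), recursive = TRUE, showWarnings = FALSE)
  write_cohort_tsv(ds$cohort, file.path(dir, "cohort.tsv"))
  for (s in ds$subjects) {
    write_meg_h5(structure(list(data = s$meg, fs = fs, subject_id = s$id),
                           class = "nf_meg"),
                 file.path(dir, "meg", paste0(s$id, ".h5")))
    write_nifti(structure(list(data = s$mri, voxel_size = c(1, 1, 1),
                               affine = diag(4), subject_id = s$id),
                          class = "nf_mri"),
                file.path(dir, "mri", paste0(s$id, ".nii.gz")))
  }
  invisible(dir)
}

#' @rdname write_dataset_dir
#' @export
read_dataset_dir <- function(dir) {
  cohort <- read_cohort_tsv(file.path(dir, "cohort.tsv"))
  subjects <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$id[i]
    list(id = id, label = cohort$group[i],
         meg = read_meg_h5(file.path(dir, "meg", paste0(id, ".h5")))$data,
         mri = read_nifti(file.path(dir, "mri", paste0(id, ".nii.gz")))$data)
  })
  structure(list(cohort = cohort, subjects = subjects, seed = NA),
            class = "nf_dataset")
}
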