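## Volume input/output.
##
## Two on-disk layouts are supported: NIfTI files (.nii / .nii.gz, one file
## per volume, via RNifti) and directories of per-slice PNGs named
## slice000.png, slice001.png, ... (masks stored as 0/255 PNGs). Slice
## ordering for PNG directories follows the natural (numeric) sort of the
## file names.

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

natural_sort <- function(files) {
  nums <- as.numeric(gsub("\\D", "", basename(files)))
  files[order(nums, basename(files), na.last = TRUE)]
}

#' Write a volume to disk
#'
#' @param vol a [volume_stack()] or 3D array.
#' @param path output path: a `.nii`/`.nii.gz` file or a directory (created)
#'   that receives one PNG per slice.
#' @param is_mask write PNG slices as 0/255 masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, is_mask = FALSE) {
  data <- unclass(vol)
  if (is_nifti_path(path)) {
    sp <- attr(vol, "spacing_mm") %||% 0.5
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- c(1, 1, sp)
    RNifti::writeNifti(img, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    d <- dim(data)
    for (s in seq_len(d[3])) {
      sl <- data[, , s]
      sl <- if (is_mask) matrix(as.numeric(sl > 0), d[1], d[2]) else
        pmin(pmax(sl, 0), 1)
      png::writePNG(sl, file.path(path, sprintf("slice%03d.png", s - 1L)))
    }
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path a NIfTI file or a directory of per-slice PNGs.
#' @param spacing_mm inter-slice spacing used for PNG directories (NIfTI
#'   files carry their own).
#' @return a [volume_stack()]; PNG intensities are on the 0-1 scale.
#' @export
read_volume <- function(path, spacing_mm = 0.5) {
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    sp <- tryCatch(RNifti::pixdim(img)[3], error = function(e) spacing_mm)
    data <- array(as.numeric(img), dim(img))
    volume_stack(data, sp)
  } else {
    files <- natural_sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path, call. = FALSE)
    slices <- lapply(files, function(f) {
      p <- png::readPNG(f)
      if (length(dim(p)) == 3L) p <- p[, , 1]
      p
    })
    data <- array(unlist(slices), c(dim(slices[[1]]), length(slices)))
    volume_stack(data, spacing_mm)
  }
}

#' Save network weights and configuration as a checkpoint
#'
#' @param state a fit result (its `network_handle`s are stored) or a single
#'   `network_handle`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  nets <- if (inherits(state, "network_handle")) list(generator = state) else
    Filter(function(x) inherits(x, "network_handle"), state)
  saveRDS(nets, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return named list of `network_handle`s (`generator`, possibly
#'   `discriminator`).
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
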