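# File interfaces: NIfTI-1 for volumes and tensor fields (RNifti),
# CSV for montages, connectomes and EEG, JSON for reports/manifests.

#' Write / read a phantom label volume as NIfTI-1
#'
#' The conductivity table and landmarks travel in side-car CSV files
#' (`<stem>_tissues.csv`, `<stem>_landmarks.csv`).
#'
#' @param phantom a [TissuePhantom-class].
#' @param stem output path stem (files `<stem>.nii.gz` etc. are written).
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(phantom, stem) {
  img <- RNifti::asNifti(phantom@labels,
                         pixdim = c(phantom@spacing))
  RNifti::writeNifti(img, paste0(stem, ".nii.gz"))
  write.csv(phantom@tissueTable, paste0(stem, "_tissues.csv"),
            row.names = FALSE)
  lm <- data.frame(name = rownames(phantom@landmarks), phantom@landmarks,
                   row.names = NULL)
  names(lm) <- c("name", "x", "y", "z")
  write.csv(lm, paste0(stem, "_landmarks.csv"), row.names = FALSE)
  meta <- c(list(origin = phantom@origin, spacing = phantom@spacing),
            phantom@meta)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, c(".nii.gz", "_tissues.csv", "_landmarks.csv",
                           "_meta.json")))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  tab <- read.csv(paste0(stem, "_tissues.csv"), stringsAsFactors = FALSE)
  lm <- read.csv(paste0(stem, "_landmarks.csv"), stringsAsFactors = FALSE)
  landmarks <- as.matrix(lm[, c("x", "y", "z")])
  rownames(landmarks) <- lm$name
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim(img))
  new("TissuePhantom", labels = labels,
      spacing = as.numeric(meta$spacing), origin = as.numeric(meta$origin),
      tissueTable = tab, landmarks = landmarks,
      meta = meta[setdiff(names(meta), c("origin", "spacing"))])
}

#' Write / read a symmetric tensor field as 6-component NIfTI
#'
#' Lower-triangular component order xx, xy, yy, xz, yz, zz in the 4th
#' dimension; the mask is stored alongside (`<stem>_mask.nii.gz`).
#'
#' @param tf a [TensorField-class].
#' @param stem path stem.
#' @export
writeTensorField <- function(tf, stem) {
  RNifti::writeNifti(RNifti::asNifti(tf@data, pixdim = tf@spacing),
                     paste0(stem, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(tf@mask), dim(tf@mask)),
                                     pixdim = tf@spacing),
                     paste0(stem, "_mask.nii.gz"))
  jsonlite::write_json(list(units = tf@units, origin = tf@origin,
                            spacing = tf@spacing),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeTensorField
#' @export
readTensorField <- function(stem) {
  dat <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  msk <- RNifti::readNifti(paste0(stem, "_mask.nii.gz"))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  new("TensorField", data = array(as.numeric(dat), dim(dat)),
      spacing = as.numeric(meta$spacing), origin = as.numeric(meta$origin),
      units = meta$units, mask = array(as.integer(msk) > 0, dim(msk)))
}

#' Write / read an electrode montage as CSV (label,x,y,z,radius)
#' @param montage an [ElectrodeMontage-class].
#' @param path CSV path.
#' @param reference reference label (stored as an attribute column).
#' @export
writeMontage <- function(montage, path) {
  tab <- montage@electrodes
  tab$reference <- tab$label == montage@reference
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMontage
#' @export
readMontage <- function(path, reference = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(reference))
    reference <- if ("reference" %in% names(tab) && any(tab$reference))
      tab$label[which(tab$reference)[1]] else tab$label[1]
  new("ElectrodeMontage",
      electrodes = tab[, c("label", "x", "y", "z", "radius")],
      reference = reference)
}

#' Write / read a connectome as CSV matrices plus a centroid table
#' @param con a [Connectome-class].
#' @param stem path stem (`<stem>_weights.csv`, `_lengths.csv`, `_regions.csv`).
#' @export
writeConnectome <- function(con, stem) {
  write.csv(con@weights, paste0(stem, "_weights.csv"))
  write.csv(con@lengths, paste0(stem, "_lengths.csv"))
  reg <- data.frame(name = con@names, con@centroids,
                    hemisphere = con@hemisphere, row.names = NULL)
  names(reg) <- c("name", "x", "y", "z", "hemisphere")
  write.csv(reg, paste0(stem, "_regions.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname writeConnectome
#' @export
readConnectome <- function(stem) {
  w <- as.matrix(read.csv(paste0(stem, "_weights.csv"), row.names = 1,
                          check.names = FALSE))
  l <- as.matrix(read.csv(paste0(stem, "_lengths.csv"), row.names = 1,
                          check.names = FALSE))
  reg <- read.csv(paste0(stem, "_regions.csv"), stringsAsFactors = FALSE)
  w <- unname(w); l <- unname(l)
  dimnames(w) <- dimnames(l) <- list(reg$name, reg$name)
  new("Connectome", weights = w, lengths = l,
      centroids = as.matrix(reg[, c("x", "y", "z")]),
      names = reg$name, hemisphere = as.integer(reg$hemisphere))
}

#' Write an EEG record as CSV (channels x samples, labelled rows)
#' @param rec an [EEGRecord-class].
#' @param path CSV path.
#' @export
writeEEG <- function(rec, path) {
  df <- data.frame(channel = rec@labels, rec@data, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
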