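# Dataset indices and loaders for the two public slice-collection layouts:
# class-per-subfolder image trees (JPEG/PNG) and directories of per-slice
# MATLAB container files holding an image array plus an integer label.

#' @export
print.dataset_index <- function(x, ...) {
  labs <- dataset_labels(x)
  cat("dataset_index:", length(x$records), "records,",
      length(x$class_names), "classes\n")
  tab <- table(factor(x$class_names[labs + 1L], levels = x$class_names))
  for (i in seq_along(tab)) cat("  ", names(tab)[i], ": ", tab[i], "\n", sep = "")
  invisible(x)
}

#' Labels and images of a dataset index
#'
#' @param dataset a `dataset_index`.
#' @param ids record indices (images only).
#' @return `dataset_labels` returns the integer 0-based label vector;
#'   `dataset_images` a list of intensity matrices in `[0, 255]`.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$records, `[[`, integer(1), "label")
}

#' @rdname dataset_labels
#' @export
dataset_images <- function(dataset, ids = NULL) {
  ids <- ids %||% seq_along(dataset$records)
  lapply(dataset$records, function(r) {
    if (!is.null(r$image)) r$image else read_image_file(r$path)
  })[ids]
}

# Decode one image file to a grayscale intensity matrix in [0, 255].
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the jpeg package is required to read ", path, call. = FALSE)
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read ", path, call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", path, call. = FALSE))
  if (length(dim(arr)) == 3) {
    # luminance of RGB(A)
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  arr * 255
}

#' Load a class-per-subfolder image tree
#'
#' Classes are the subdirectory names in lexicographic order; files are
#' indexed in lexicographic order, so repeated loads are identical.
#' Heterogeneous resolutions are allowed (images are resized downstream).
#' Undecodable files are skipped with a warning; empty class directories are
#' an error.
#'
#' @param root directory with one subdirectory per class.
#' @return a `dataset_index` with file-backed records.
#' @export
load_folder_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", root,
                                 call. = FALSE)
  records <- list()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0)
      stop("class directory '", classes[k], "' contains no images", call. = FALSE)
    for (f in files) {
      ok <- tryCatch({ read_image_file(f); TRUE },
                     error = function(e) {
                       warning("skipping undecodable file ", f, ": ",
                               conditionMessage(e), call. = FALSE)
                       FALSE
                     })
      if (ok) records[[length(records) + 1L]] <- list(path = f, label = k - 1L)
    }
  }
  structure(list(records = records, class_names = classes),
            class = "dataset_index")
}

#' Load a directory of per-slice MATLAB container files
#'
#' Each `.mat` file must hold one record with an integer label and a 2-D
#' image array, either as top-level variables or inside a struct (the public
#' per-slice distribution stores a `cjdata` struct with `label` and `image`
#' fields). Both the legacy binary container (v5) and the HDF5-based
#' container (v7.3, read through rhdf5) are accepted. Labels are remapped to
#' dense 0-based class ids in increasing order of the stored values.
#'
#' @param dir directory containing `.mat` files.
#' @return a `dataset_index` with in-memory images.
#' @export
load_mat_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mat$", full.names = TRUE))
  if (length(files) == 0) stop("no .mat files under ", dir, call. = FALSE)
  raw <- lapply(files, function(f) {
    rec <- tryCatch(read_mat_record(f), error = function(e)
      stop("failed to read ", f, ": ", conditionMessage(e), call. = FALSE))
    rec
  })
  stored <- vapply(raw, `[[`, numeric(1), "label")
  lv <- sort(unique(stored))
  records <- lapply(seq_along(raw), function(i) {
    list(image = raw[[i]]$image, label = match(stored[i], lv) - 1L)
  })
  structure(list(records = records,
                 class_names = paste0("class_", lv)),
            class = "dataset_index")
}

# Read one slice record (label + image) from either .mat dialect.
read_mat_record <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 8)
  close(con)
  hdf5_sig <- as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a))
  vars <- if (identical(magic, hdf5_sig)) read_mat_hdf5(path) else read_mat5(path)
  rec <- find_mat_record(vars)
  if (is.null(rec))
    stop("no label/image record found (fields present: ",
         paste(names(vars), collapse = ", "), ")")
  rec
}

find_mat_record <- function(vars) {
  has <- function(v) all(c("label", "image") %in% names(v))
  if (has(vars)) {
    return(list(label = as.numeric(vars$label)[1],
                image = as.matrix(vars$image)))
  }
  for (v in vars) {
    if (is.list(v) && has(v)) {
      return(list(label = as.numeric(v$label)[1], image = as.matrix(v$image)))
    }
  }
  NULL
}

read_mat_hdf5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5-based containers")
  ls <- rhdf5::h5ls(path)
  top <- unique(sub("^/", "", ls$group))
  out <- list()
  groups <- unique(ls$group[ls$group != "/"])
  for (g in groups) {
    nm <- sub("^/", "", g)
    dsets <- ls$name[ls$group == g & ls$otype == "H5I_DATASET"]
    out[[nm]] <- stats::setNames(
      lapply(dsets, function(d) {
        v <- rhdf5::h5read(path, paste0(g, "/", d))
        # HDF5 matrices written by the v7.3 container are transposed
        if (is.matrix(v)) t(v) else v
      }), dsets)
  }
  for (d in ls$name[ls$group == "/" & ls$otype == "H5I_DATASET"]) {
    v <- rhdf5::h5read(path, d)
    out[[d]] <- if (is.matrix(v)) t(v) else v
  }
  rhdf5::h5closeAll()
  out
}
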