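#' Write a numeric array to a NumPy `.npy` file
#'
#' Serialises a numeric vector, matrix, or array as a NumPy binary array
#' (format version 1.0, dtype `<f8`, C element order), so maps produced here
#' can be inspected from any NumPy-compatible stack. The round trip through
#' [read_npy()] is bit-exact.
#'
#' @param x numeric vector, matrix, or array with finite or non-finite values.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_npy()]
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x)) stop_validation("write_npy() requires a numeric array")
  shape <- dim(x) %||% length(x)
  shape_txt <- if (length(shape) == 1L) paste0("(", shape, ",)") else
    paste0("(", paste(shape, collapse = ", "), ")")
  header <- paste0("{'descr': '<f8', 'fortran_order': False, 'shape': ",
                   shape_txt, ", }")
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
                    utf8ToInt("P"), utf8ToInt("Y"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  # emit C order: last axis fastest
  v <- if (length(shape) > 1L) as.vector(aperm(x, rev(seq_along(shape)))) else as.vector(x)
  writeBin(as.numeric(v), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NumPy `.npy` file written with dtype `<f8`
#'
#' @param path file path produced by [write_npy()] or NumPy itself
#'   (`float64` arrays only).
#' @return numeric vector (1-d arrays) or array in the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (length(magic) < 8L || any(magic[1:6] != as.raw(c(0x93, utf8ToInt("N"),
      utf8ToInt("U"), utf8ToInt("M"), utf8ToInt("P"), utf8ToInt("Y"))))) {
    stop_validation("not a NumPy array file: ", path)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'descr':\\s*'<f8'", header)) {
    stop_validation("unsupported dtype in ", path, " (only little-endian float64)")
  }
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  n <- prod(shape)
  v <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(v) != n) stop_validation("truncated array file: ", path)
  if (length(shape) == 1L) return(v)
  if (fortran) array(v, shape) else aperm(array(v, rev(shape)), rev(seq_along(shape)))
}

#' Persist an attribution map together with its sample
#'
#' Writes one container per (sample, method) pair: a directory holding the
#' named arrays `values.npy` (the attribution) and `data.npy` (the input),
#' plus a `meta.json` sidecar with sample id, modality, method, labels, and
#' any method configuration echoed for provenance. Arrays round-trip
#' bit-exactly and are readable from NumPy.
#'
#' @param map an [attribution_map()]; must be normalized.
#' @param sample the paired [sample3d()].
#' @param path container path (a directory; created if needed).
#' @return `path`, invisibly.
#' @export
save_attribution <- function(map, sample, path) {
  stopifnot(inherits(map, "attribution_map"), inherits(sample, "sample3d"))
  if (!isTRUE(map$normalized)) stop_validation("attribution map must be normalized before saving")
  check_map_matches_sample(map, sample)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_npy(map$values, file.path(path, "values.npy"))
  write_npy(sample$data, file.path(path, "data.npy"))
  meta <- list(
    sample_id = sample$sample_id,
    modality = sample$modality,
    method = map$method,
    true_label = sample$true_label,
    predicted_label = sample$predicted_label,
    correct = sample$correct,
    normalized = map$normalized,
    shape = as.integer(dim(map$values) %||% length(map$values)),
    config = map$config %||% NULL
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load an attribution container written by [save_attribution()]
#'
#' @param path container directory.
#' @return list with elements `map` (an [attribution_map()]) and `sample`
#'   (the stored [sample3d()]).
#' @export
load_attribution <- function(path) {
  files <- c("values.npy", "data.npy", "meta.json")
  missing <- files[!file.exists(file.path(path, files))]
  if (length(missing)) {
    stop_validation("corrupt attribution container ", path,
                    ": missing member(s) ", paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  required <- c("sample_id", "modality", "method", "true_label", "predicted_label")
  absent <- required[!required %in% names(meta)]
  if (length(absent)) {
    stop_validation("corrupt attribution container ", path,
                    ": metadata lacks field(s) ", paste(absent, collapse = ", "))
  }
  values <- read_npy(file.path(path, "values.npy"))
  data <- read_npy(file.path(path, "data.npy"))
  shape <- as.integer(dim(values) %||% length(values))
  if (!identical(shape, as.integer(meta$shape))) {
    stop_validation("corrupt attribution container ", path,
                    ": stored shape disagrees with metadata")
  }
  sample <- sample3d(meta$sample_id, meta$modality, data,
                     true_label = meta$true_label,
                     predicted_label = meta$predicted_label)
  map <- attribution_map(values, method = meta$method, sample = sample,
                         normalized = isTRUE(meta$normalized))
  list(map = map, sample = sample)
}
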