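# Subject container file: a small schema-versioned binary format holding a
# JSON metadata block plus named numeric arrays (float64 / int32), one file
# per subject. Doubles are written raw, so load(save(x)) is bit-exact.

CONTAINER_MAGIC <- "MIFUSESUBJ"
CONTAINER_VERSION <- 1L

write_array_entry <- function(con, x) {
  if (is.double(x)) {
    writeBin(as.vector(x), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(as.vector(x)), con, size = 4, endian = "little")
  }
}

read_array_entry <- function(con, entry, path) {
  n <- prod(entry$dims)
  vals <- if (entry$type == "double") {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = 4, endian = "little")
  }
  if (length(vals) != n)
    stopf("truncated subject container '%s': array '%s' expected %d values, found %d",
          path, entry$name, n, length(vals))
  if (length(entry$dims) > 1) dim(vals) <- entry$dims
  vals
}

#' Save / load a subject dataset container file
#'
#' One self-contained file per subject: a schema-versioned header, a JSON
#' metadata block (identifiers, labels' class map, channel names), and the
#' numeric arrays in raw little-endian float64. The round trip is bit-exact.
#'
#' @param sd A [subject_dataset()].
#' @param path File path to write / read.
#' @return `load_subject` returns the reconstructed [subject_dataset()];
#'   `save_subject` returns `path` invisibly.
#' @export
save_subject <- function(sd, path) {
  viol <- validate_subject(sd)
  if (length(viol)) stopf("refusing to save invalid subject: %s", viol[1])
  arrays <- list(
    eeg_data = sd$eeg$data, eeg_labels = sd$eeg$labels, eeg_fs = sd$eeg$fs,
    fnirs_data = sd$fnirs$data, fnirs_labels = sd$fnirs$labels,
    fnirs_fs = sd$fnirs$fs
  )
  for (nm in names(sd$extras)) arrays[[paste0("extra_", nm)]] <- sd$extras[[nm]]
  manifest <- lapply(names(arrays), function(nm) {
    x <- arrays[[nm]]
    list(name = nm, dims = as.integer(dim(x) %||% length(x)),
         type = if (is.double(x)) "double" else "integer")
  })
  meta <- list(
    subject_id = sd$subject_id, cohort_tag = sd$cohort_tag,
    eeg = list(modality = sd$eeg$modality, channel_names = sd$eeg$channel_names,
               classes = sd$eeg$classes, subject_id = sd$eeg$subject_id),
    fnirs = list(modality = sd$fnirs$modality,
                 channel_names = sd$fnirs$channel_names,
                 classes = sd$fnirs$classes, subject_id = sd$fnirs$subject_id),
    extras = setdiff(names(sd$extras), ""),
    manifest = manifest
  )
  json <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(CONTAINER_VERSION, con, size = 4, endian = "little")
  writeBin(length(json), con, size = 4, endian = "little")
  writeBin(json, con)
  for (nm in names(arrays)) write_array_entry(con, arrays[[nm]])
  invisible(path)
}

#' @rdname save_subject
#' @export
load_subject <- function(path) {
  if (!file.exists(path)) stopf("subject container '%s' does not exist", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(CONTAINER_MAGIC)))
  if (!identical(magic, CONTAINER_MAGIC))
    stopf("'%s' is not a subject container (bad magic)", path)
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(version, CONTAINER_VERSION))
    stopf("subject container '%s' has schema version %s; this build reads version %d",
          path, version %||% "<missing>", CONTAINER_VERSION)
  jlen <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(jlen) != 1 || is.na(jlen) || jlen <= 0)
    stopf("truncated subject container '%s': missing metadata block", path)
  jraw <- readBin(con, "raw", n = jlen)
  if (length(jraw) != jlen)
    stopf("truncated subject container '%s': metadata block incomplete", path)
  meta <- jsonlite::fromJSON(rawToChar(jraw), simplifyDataFrame = FALSE)
  arrays <- list()
  for (entry in meta$manifest)
    arrays[[entry$name]] <- read_array_entry(con, entry, path)
  eeg <- trial_set(meta$eeg$subject_id, meta$eeg$modality, arrays$eeg_data,
                   arrays$eeg_labels, as.numeric(arrays$eeg_fs),
                   unlist(meta$eeg$channel_names), unlist(meta$eeg$classes))
  fnirs <- trial_set(meta$fnirs$subject_id, meta$fnirs$modality,
                     arrays$fnirs_data, arrays$fnirs_labels,
                     as.numeric(arrays$fnirs_fs),
                     unlist(meta$fnirs$channel_names), unlist(meta$fnirs$classes))
  extras <- list()
  for (nm in unlist(meta$extras)) extras[[nm]] <- arrays[[paste0("extra_", nm)]]
  subject_dataset(meta$subject_id, eeg, fnirs, meta$cohort_tag, extras)
}
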