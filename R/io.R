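# Plain-text readers and writers: recordings (wide TSV, rows = time,
# columns = channel x wavelength), montage TSV, annotation TSV, FC matrices
# as square delimited text with JSON sidecars, and ground-truth JSON.

#' Write a recording to delimited text
#'
#' Writes three files: `<stem>_recording.tsv` (rows = time points, columns
#' named `<channel>_<wavelength>`), `<stem>_montage.tsv`, and, when
#' annotations are present, `<stem>_annotations.tsv` (onset_s, duration_s,
#' label). A JSON sidecar `<stem>_meta.json` carries sampling rate,
#' wavelengths and subject metadata.
#'
#' @param rec a `nirs_recording`.
#' @param stem output path stem (directories must exist).
#' @return Invisibly, the vector of files written.
#' @export
write_recording <- function(rec, stem) {
  n_ch <- dim(rec$intensity)[1]; n_time <- dim(rec$intensity)[2]
  wide <- matrix(0, n_time, n_ch * 2L)
  cn <- character(n_ch * 2L)
  for (w in 1:2) {
    cols <- (w - 1L) * n_ch + seq_len(n_ch)
    wide[, cols] <- t(rec$intensity[, , w])
    cn[cols] <- paste0(rec$montage$channel, "_", rec$wavelengths[w])
  }
  colnames(wide) <- cn
  f_rec <- paste0(stem, "_recording.tsv")
  utils::write.table(format(wide, digits = 17, trim = TRUE, scientific = TRUE),
                     f_rec, sep = "\t", quote = FALSE, row.names = FALSE)
  f_mon <- paste0(stem, "_montage.tsv")
  utils::write.table(rec$montage, f_mon, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(f_rec, f_mon)
  if (!is.null(rec$annotations) && nrow(rec$annotations)) {
    f_ann <- paste0(stem, "_annotations.tsv")
    write_annotations(rec$annotations, f_ann)
    files <- c(files, f_ann)
  }
  meta <- list(fs = rec$fs, wavelengths = rec$wavelengths,
               subject = rec$subject[c("id", "group", "age")],
               condition = rec$condition %||% NA)
  f_meta <- paste0(stem, "_meta.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f_meta))
}

#' Read a recording from delimited text
#'
#' Counterpart of [write_recording()]; validates wavelength count, channel /
#' montage agreement and intensity positivity.
#'
#' @param stem path stem used when writing.
#' @return A `nirs_recording`.
#' @export
read_recording <- function(stem) {
  wide <- as.matrix(utils::read.table(paste0(stem, "_recording.tsv"),
                                      sep = "\t", header = TRUE,
                                      check.names = FALSE))
  montage <- utils::read.table(paste0(stem, "_montage.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  parts <- strsplit(colnames(wide), "_(?=[0-9]+$)", perl = TRUE)
  ch <- vapply(parts, `[`, "", 1)
  wl <- as.numeric(vapply(parts, `[`, "", 2))
  wavelengths <- sort(unique(wl))
  if (length(wavelengths) != 2L)
    stop("expected two wavelengths, found ", length(wavelengths))
  chans <- unique(ch)
  missing_ch <- setdiff(chans, montage$channel)
  extra_ch <- setdiff(montage$channel, chans)
  if (length(missing_ch) || length(extra_ch))
    stop("channel/montage mismatch: ",
         if (length(missing_ch)) paste("missing from montage:",
                                       paste(missing_ch, collapse = ", ")),
         if (length(extra_ch)) paste(" absent from recording:",
                                     paste(extra_ch, collapse = ", ")))
  montage <- montage[match(chans, montage$channel), ]
  n_ch <- length(chans); n_time <- nrow(wide)
  intensity <- array(0, dim = c(n_ch, n_time, 2L))
  for (w in 1:2) {
    for (i in seq_len(n_ch)) {
      col <- which(ch == chans[i] & wl == wavelengths[w])
      intensity[i, , w] <- wide[, col]
    }
  }
  if (any(intensity <= 0)) stop("nonpositive intensity values in recording")
  ann_file <- paste0(stem, "_annotations.tsv")
  ann <- if (file.exists(ann_file)) read_annotations(ann_file) else NULL
  rec <- list(intensity = intensity, fs = meta$fs,
              wavelengths = wavelengths, montage = montage,
              subject = as.list(meta$subject), condition = meta$condition,
              annotations = ann)
  class(rec) <- "nirs_recording"
  rec
}

#' Write annotations as three-column TSV
#' @param ann an [annotation_set()].
#' @param path output file.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[, c("onset_s", "duration_s", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read annotations from TSV
#' @param path file with columns onset_s, duration_s, label.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  annotation_set(df$onset_s, df$duration_s, df$label)
}

#' Write an FC matrix with JSON sidecar
#'
#' Square delimited text with a channel-name header plus a sidecar carrying
#' stage, condition, subject and window count.
#'
#' @param fc an [fc_matrix()].
#' @param path output TSV path (sidecar gets `.json` appended to the stem).
#' @param channels channel names for the header.
#' @export
write_fc_matrix <- function(fc, path, channels = NULL) {
  v <- fc$values
  if (!is.null(channels)) dimnames(v) <- list(channels, channels)
  utils::write.table(format(v, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE,
                     row.names = !is.null(channels), col.names = TRUE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(stage = fc$stage, condition = fc$condition,
                            subject = fc$subject,
                            n_samples_used = fc$n_samples_used),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read an FC matrix written by [write_fc_matrix()]
#' @param path TSV path.
#' @return An [fc_matrix()].
#' @export
read_fc_matrix <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  if (!is.null(rownames(v)) && !identical(rownames(v), as.character(seq_len(nrow(v)))))
    v <- v
  rn <- nrow(v); cn <- ncol(v)
  if (cn == rn + 1L) {  # row-name column read as data
    rownames(v) <- v[, 1]
    v <- v[, -1, drop = FALSE]
  }
  storage.mode(v) <- "double"
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  fc_matrix(unname(v) * 1, stage = meta$stage, condition = meta$condition,
            subject = meta$subject,
            n_samples_used = meta$n_samples_used %||% NA_integer_)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one list; every stochastic stage
#' derives its seed from `master_seed` and the stage name.
#'
#' @param master_seed integer master seed.
#' @param ... overrides for any default field.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    n_patients = 6L, n_controls = 6L,
    sim = list(n_channels = 50L, fs = 7.8, duration_s = 720,
               bad_channel_frac = 0),
    qc_band = c(0.8, 2.3), qc_threshold = 0.1,
    filter_band = c(0.001, 0.5), long_noise_s = 10, parafac_rank = 3L,
    n_windows = 200L, win_s = 60,
    grid = c(0.01, 0.17, 0.01), n_rand = 100L,
    n_perm = 2000L, alpha = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(master_seed = y$master_seed %||% 1L),
            y[setdiff(names(y), "master_seed")]))
}

# stable hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  jsonlite::write_json(cfg[sort(names(cfg))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
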