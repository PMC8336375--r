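#' Read a clip manifest
#'
#' A UTF-8 CSV with columns `clip_path` and `label` (0 = control,
#' 1 = patient); optional `subject_id` and `clip_id` columns are carried
#' through.
#'
#' @param path Manifest CSV path; relative clip paths resolve against the
#'   manifest's directory.
#' @return Data frame with validated columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clip_path", "label") %in% names(m))) {
    stop("manifest must have columns clip_path and label")
  }
  if (!all(m$label %in% c(0L, 1L))) {
    stop("manifest labels must be 0 (control) or 1 (patient)")
  }
  rel <- !file.exists(m$clip_path)
  m$clip_path[rel] <- file.path(dirname(path), m$clip_path[rel])
  m
}

#' Prepare network inputs from clips or a manifest
#'
#' Computes the log-magnitude spectrogram of every clip and resizes to the
#' network geometry.
#'
#' @param x A `synth_dataset`, a manifest data frame (clips are loaded from
#'   `clip_path`), or a list of [audio_clip] objects.
#' @param labels,subjects Required when `x` is a plain clip list.
#' @param n_fft,hop_length STFT parameters.
#' @return List with `images`, `labels`, `subjects`.
#' @export
prepare_inputs <- function(x, labels = NULL, subjects = NULL,
                           n_fft = 2048L, hop_length = 512L) {
  if (inherits(x, "synth_dataset")) {
    clips <- x$clips; labels <- x$labels; subjects <- x$subjects
  } else if (is.data.frame(x)) {
    clips <- lapply(x$clip_path, load_audio)
    labels <- x$label
    subjects <- x$subject_id
  } else {
    clips <- x
    if (is.null(labels)) stop("labels required for a plain clip list")
  }
  images <- lapply(clips, function(cl) {
    to_net_input(compute_spectrogram(cl, n_fft, hop_length))
  })
  list(images = images, labels = as.integer(labels), subjects = subjects)
}
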