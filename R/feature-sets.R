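#' Names of the available per-clip feature sets
#' @return Character vector of valid `set_name` values.
#' @export
feature_set_names <- function() {
  c("ste", "pitch", "fluency", "ltas", "spectrogram", "mfcc", "gtcc",
    "lp", "swlp", "xlp")
}

#' Extract a named fixed-length feature vector from a clip
#'
#' Dispatches to the individual feature operations and reduces each to a
#' per-clip vector: STE and pitch to their distribution summaries, fluency
#' to the five pause/segment statistics, LTAS to 128 band levels, the
#' spectrogram to the 128x256 network input mean-pooled 8x spatially
#' (512 dims), MFCC/GTCC to mean and sd of 13 coefficients, and the
#' LP-family sets to the frame-averaged 38 coefficients.
#'
#' @param clip An [audio_clip].
#' @param set_name One of [feature_set_names()].
#' @param lp_order Model order for the LP-family sets.
#' @param lp_max_frames Cap on analysis frames for the LP-family sets
#'   (frames are subsampled evenly beyond it).
#' @return A `clip_features` object: `feature_set_name`, `values` (named
#'   numeric vector), `clip_id`.
#' @export
extract_feature_set <- function(clip, set_name, lp_order = 38L,
                                lp_max_frames = 60L) {
  if (!set_name %in% feature_set_names()) {
    stop("unknown feature set '", set_name, "'; valid sets: ",
         paste(feature_set_names(), collapse = ", "))
  }
  values <- switch(set_name,
    ste = {
      s <- short_term_energy(clip)$summary
      stats::setNames(s, paste0("ste_", names(s)))
    },
    pitch = {
      s <- suppressWarnings(pitch_track(clip)$summary)
      stats::setNames(s, paste0("pitch_", names(s)))
    },
    fluency = suppressWarnings(fluency_features(vad_segment(clip))),
    ltas = ltas(compute_spectrogram(clip)),
    spectrogram = {
      img <- to_net_input(compute_spectrogram(clip))
      pooled <- cpp_avgpool_forward(array(unclass(img), c(dim(img), 1L, 1L)),
                                    8L)
      v <- as.numeric(pooled)
      stats::setNames(v, paste0("sgram_", seq_along(v)))
    },
    mfcc = mfcc(clip)$summary,
    gtcc = gtcc(clip)$summary,
    lp = lp_set_features(clip, lp_order, "none", lp_max_frames),
    swlp = lp_set_features(clip, lp_order, "swlp", lp_max_frames),
    xlp = lp_set_features(clip, lp_order, "xlp", lp_max_frames))
  structure(list(feature_set_name = set_name,
                 values = values, clip_id = clip$id),
            class = "clip_features")
}

lp_set_features <- function(clip, order, weighting, max_frames) {
  fr <- frame_signal(clip, frame_spec(window_name = "hamming"))
  w <- frame_window(fr$frame_len, "hamming")
  keep <- which(.colSums(fr$frames^2, fr$frame_len, ncol(fr$frames)) >
                  1e-8 * fr$frame_len)
  if (!length(keep)) keep <- seq_len(ncol(fr$frames))
  if (length(keep) > max_frames) {
    keep <- keep[round(seq(1L, length(keep), length.out = max_frames))]
  }
  A <- vapply(keep, function(j) {
    lp_family(fr$frames[, j] * w, order, weighting)$a
  }, numeric(order))
  stats::setNames(rowMeans(A), paste0(weighting_prefix(weighting), "_a",
                                      seq_len(order)))
}

weighting_prefix <- function(weighting) {
  switch(weighting, none = "lp", wlp = "wlp", swlp = "swlp", xlp = "xlp")
}

#' Extract one feature set for every clip of a dataset
#'
#' @param clips List of [audio_clip] objects.
#' @param set_name Feature set name.
#' @param ... Passed to [extract_feature_set()].
#' @return Numeric matrix, one clip per row, named columns.
#' @export
extract_features_batch <- function(clips, set_name, ...) {
  rows <- lapply(clips, extract_feature_set, set_name = set_name, ...)
  m <- do.call(rbind, lapply(rows, function(r) r$values))
  rownames(m) <- vapply(seq_along(clips), function(i) {
    if (is.null(clips[[i]]$id)) paste0("clip", i) else clips[[i]]$id
  }, character(1))
  m
}

#' Write extracted features as tidy and wide CSV files
#'
#' @param features Matrix from [extract_features_batch()].
#' @param labels 0/1 labels aligned with the rows.
#' @param set_name Feature set name recorded in the tidy output.
#' @param tidy_path,wide_path Output CSVs (either may be `NULL`).
#' @return Invisibly, the tidy data frame.
#' @export
export_features <- function(features, labels, set_name,
                            tidy_path = NULL, wide_path = NULL) {
  tidy <- data.frame(
    clip_id = rep(rownames(features), times = ncol(features)),
    label = rep(as.integer(labels), times = ncol(features)),
    feature_set = set_name,
    dim_name = rep(colnames(features), each = nrow(features)),
    value = as.numeric(features))
  if (!is.null(tidy_path)) utils::write.csv(tidy, tidy_path, row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- data.frame(clip_id = rownames(features),
                       label = as.integer(labels), features)
    utils::write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(tidy)
}
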