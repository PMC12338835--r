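# Frame subsampling plan shared by the record-level operations and the
# grid engine. Seconds and frames are 0-based; `positions` of analysed
# frames are 1-based and contiguous.
frame_plan <- function(duration_seconds, record_fps, fps) {
  if (fps >= 1) {
    k <- as.integer(round(fps))
    if (abs(fps - k) > 1e-9 || record_fps %% k != 0) {
      stop("fps >= 1 must be an integer divisor of record_fps")
    }
    secs <- seq.int(0L, duration_seconds - 1L)
    offsets <- floor((seq_len(k) - 1L) * record_fps / k)
  } else {
    step <- 1 / fps
    if (abs(step - round(step)) > 1e-9) {
      stop("fps < 1 must be the reciprocal of a whole number of seconds")
    }
    k <- 1L
    secs <- seq.int(0L, duration_seconds - 1L, by = as.integer(round(step)))
    offsets <- 0L
  }
  frames <- rep(secs * record_fps, each = k) + rep.int(offsets, length(secs))
  list(seconds = secs, per_second = k, n_frames = length(frames),
       frames = as.integer(frames))
}

#' Select the frames analysed at a given processing rate
#'
#' Deterministic subsampling of a recorded video: the first frame of each
#' second is kept, then frames are chosen evenly among the remaining ones of
#' the second to reach the target rate. Rates below 1 fps keep the first
#' frame of every `1/fps`-th second (0.25 fps = one image every 4 s).
#'
#' @param duration_seconds Video duration.
#' @param record_fps Recording frame rate (default 30).
#' @param fps Processing rate; the study grid uses
#'   0.25, 0.5, 1, 2, 5, 10 and 30.
#' @return Integer vector of 0-based frame indices
#'   (within `0 .. duration_seconds * record_fps - 1`).
#' @examples
#' length(select_frames(600, 30, 1))    # 600
#' length(select_frames(600, 30, 0.25)) # 150
#' head(select_frames(600, 30, 2))      # offsets 0 and 15 in each second
#' @export
select_frames <- function(duration_seconds, record_fps = 30, fps) {
  frame_plan(duration_seconds, record_fps, fps)$frames
}

# Ground-truth count of each composed species on each analysed frame,
# in sparse form (one row per nonzero species-frame cell).
truth_instances <- function(video, frames) {
  secs <- frames %/% video$record_fps
  sub <- video$second_matrix[, secs + 1L, drop = FALSE]
  nz <- which(sub > 0L, arr.ind = TRUE)
  list(
    species = video$composition$species_id[nz[, 1L]],
    frame = frames[nz[, 2L]],
    count = sub[nz]
  )
}

#' Number of detectable species on the analysed frames
#'
#' A species is detectable if at least one of its individuals is present on
#' at least one analysed frame; this is the pipeline-independent upper bound
#' on what any detector can find at a given processing rate.
#'
#' @param video A `gt_video`.
#' @param frames Frame indices from [select_frames()].
#' @return Integer count of detectable composed species.
#' @export
detectable_species <- function(video, frames) {
  ti <- truth_instances(video, frames)
  length(unique(ti$species))
}

#' Simulate the detection stage
#'
#' Every individual present on an analysed frame is detected independently
#' with probability `recall` (a per-image Bernoulli draw; missed individuals
#' are dropped for good, as in a real pipeline). The number of background
#' false positives is then set from the detector's precision,
#' `round(TP * (1 - precision) / precision)` where `TP` is the total number
#' of true detections, and the false positives are scattered uniformly at
#' random over the analysed frames.
#'
#' @param video A `gt_video`.
#' @param frames Frame indices from [select_frames()].
#' @param recall,precision Detector performance in (0, 1].
#' @return A tibble of detection records: `frame`, `true_species`
#'   (`NA` for background false positives) and `origin`
#'   (`"true"` or `"fp"`).
#' @export
simulate_detection <- function(video, frames, recall, precision) {
  stopifnot(recall > 0, recall <= 1, precision > 0, precision <= 1)
  ti <- truth_instances(video, frames)
  det <- stats::rbinom(length(ti$count), ti$count, recall)
  tp <- sum(det)
  n_fp <- as.integer(round(tp * (1 - precision) / precision))
  tibble::tibble(
    frame = c(rep.int(ti$frame, det),
              frames[sample.int(length(frames), n_fp, replace = TRUE)]),
    true_species = c(rep.int(ti$species, det), rep(NA_integer_, n_fp)),
    origin = rep(c("true", "fp"), c(tp, n_fp))
  )
}

#' Simulate the classification stage
#'
#' Each detected true individual keeps its correct species label with
#' probability `accuracy`; otherwise it receives a label drawn uniformly
#' among the other `n_pool - 1` learned species (misidentifications are
#' even across species pairs). Background false positives have no true
#' class, so the classifier - which always outputs one of its learned
#' classes - labels them uniformly over the whole pool, and every one of
#' them counts as a misidentification.
#'
#' @param records Detection records from [simulate_detection()].
#' @param accuracy Classifier accuracy in (0, 1].
#' @param n_pool Number of learned species (default 30).
#' @return The records with `label` (assigned species) and `correct`
#'   (logical) columns added.
#' @export
simulate_classification <- function(records, accuracy, n_pool = 30) {
  stopifnot(accuracy > 0, accuracy <= 1)
  n <- nrow(records)
  label <- integer(n)
  correct <- logical(n)
  is_true <- records$origin == "true"

  nt <- sum(is_true)
  if (nt > 0) {
    keep <- stats::runif(nt) < accuracy
    truth <- records$true_species[is_true]
    lab <- truth
    n_wrong <- sum(!keep)
    if (n_wrong > 0) {
      u <- sample.int(n_pool - 1L, n_wrong, replace = TRUE)
      lab[!keep] <- u + (u >= truth[!keep])
    }
    label[is_true] <- lab
    correct[is_true] <- keep
  }
  nf <- n - nt
  if (nf > 0) {
    label[!is_true] <- sample.int(n_pool, nf, replace = TRUE)
  }
  records$label <- label
  records$correct <- correct
  records
}

#' Apply confidence-threshold post-processing
#'
#' Emulates score-threshold filtering of classifier outputs: each
#' misidentified record (wrongly labelled true individual, or any background
#' false positive) is relabelled "unsure" with probability `threshold`,
#' while each correct identification is relabelled "unsure" with probability
#' `threshold / 20`. Unsure records are excluded from all downstream
#' metrics. `threshold = NA` (no post-processing) leaves every record
#' retained.
#'
#' @param records Classified records from [simulate_classification()].
#' @param threshold Confidence-threshold level in (0, 1), or `NA` for none.
#' @return The records with a logical `retained` column added.
#' @export
apply_threshold <- function(records, threshold = NA) {
  n <- nrow(records)
  if (is.na(threshold)) {
    records$retained <- rep(TRUE, n)
    return(records)
  }
  stopifnot(threshold > 0, threshold < 1)
  drop_prob <- ifelse(records$correct, threshold / 20, threshold)
  records$retained <- stats::runif(n) >= drop_prob
  records
}

#' Estimate per-species abundance with MaxN
#'
#' MaxN of a species is the maximum number of retained records carrying its
#' label on a single analysed frame - the abundance estimate routinely used
#' in video-based surveys. Species never labelled get 0.
#'
#' @param records Records with `frame`, `label` and (optionally) `retained`
#'   columns; non-retained records are ignored.
#' @param n_pool Number of learned species (default 30).
#' @return Named integer vector of length `n_pool` (names = species ids).
#' @export
estimate_maxn <- function(records, n_pool = 30) {
  out <- stats::setNames(integer(n_pool), as.character(seq_len(n_pool)))
  if (!is.null(records$retained)) records <- records[records$retained, ]
  if (nrow(records) > 0) {
    per_frame <- dplyr::count(records, .data$frame, .data$label)
    mx <- tapply(per_frame$n, per_frame$label, max)
    out[names(mx)] <- as.integer(mx)
  }
  out
}

#' Run one processing pipeline on one video
#'
#' Record-level reference implementation of a full pipeline: frame
#' subsampling, Bernoulli detection with recall, precision-driven false
#' positives, accuracy-driven classification, optional confidence-threshold
#' post-processing and MaxN estimation. [run_grid()] runs the same model
#' through a vectorised engine for factorial experiments.
#'
#' @param video A `gt_video`.
#' @param fps Processing rate.
#' @param recall,precision Detector performance in (0, 1].
#' @param accuracy Classifier accuracy in (0, 1].
#' @param threshold Post-processing level in (0, 1), or `NA` for none.
#' @param seed Optional seed; stage sub-seeds are derived from it.
#' @return A list with the estimated `maxn` vector, the `records` tibble,
#'   the analysed `frames`, and the configuration.
#' @examples
#' v <- simulate_video(seed = 7)
#' est <- run_pipeline(v, fps = 1, recall = 0.9, precision = 0.9,
#'                     accuracy = 0.9, seed = 7)
#' species_richness(est$maxn)
#' @export
run_pipeline <- function(video, fps, recall, precision, accuracy,
                         threshold = NA, seed = NULL) {
  frames <- select_frames(video$duration_seconds, video$record_fps, fps)
  if (!is.null(seed)) {
    set.seed(derive_seed(seed, "detect", video$video_id, fps, recall,
                         precision))
  }
  rec <- simulate_detection(video, frames, recall, precision)
  if (!is.null(seed)) {
    set.seed(derive_seed(seed, "classify", video$video_id, fps, recall,
                         accuracy))
  }
  rec <- simulate_classification(rec, accuracy, video$n_pool)
  if (!is.null(seed)) {
    set.seed(derive_seed(seed, "threshold", video$video_id, fps, recall,
                         precision, accuracy, threshold))
  }
  rec <- apply_threshold(rec, threshold)
  list(
    maxn = estimate_maxn(rec, video$n_pool),
    records = rec,
    frames = frames,
    config = list(fps = fps, recall = recall, precision = precision,
                  accuracy = accuracy, threshold = threshold)
  )
}
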