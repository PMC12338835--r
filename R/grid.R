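#' Specify a factorial grid of processing pipelines
#'
#' The default levels reproduce the full study grid: 7 processing rates x
#' 7 recalls x 7 precisions x 7 accuracies x 6 post-processing thresholds
#' (including "none", encoded `NA`) = 14,406 pipelines, run over 10
#' replicate videos.
#'
#' @param fps Processing rates (frames per second).
#' @param recall,precision Detection performance levels in (0, 1].
#' @param accuracy Classification accuracy levels in (0, 1].
#' @param threshold Post-processing levels in (0, 1); `NA` = none.
#' @param n_videos Number of replicate videos.
#' @param seed Master seed for video generation and all pipeline draws.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' prod(lengths(g[c("fps", "recall", "precision", "accuracy", "threshold")]))
#' @export
grid_spec <- function(fps = c(0.25, 0.5, 1, 2, 5, 10, 30),
                      recall = c(0.60, 0.70, 0.80, 0.85, 0.90, 0.95, 0.99),
                      precision = c(0.60, 0.70, 0.80, 0.85, 0.90, 0.95, 0.99),
                      accuracy = c(0.60, 0.70, 0.80, 0.85, 0.90, 0.95, 0.99),
                      threshold = c(NA, 0.80, 0.85, 0.90, 0.95, 0.99),
                      n_videos = 10, seed = 1) {
  stopifnot(all(recall > 0 & recall <= 1),
            all(precision > 0 & precision <= 1),
            all(accuracy > 0 & accuracy <= 1),
            all(is.na(threshold) | (threshold > 0 & threshold < 1)))
  structure(
    list(fps = fps, recall = recall, precision = precision,
         accuracy = accuracy, threshold = threshold,
         n_videos = n_videos, seed = seed),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  n <- prod(lengths(x[c("fps", "recall", "precision", "accuracy",
                        "threshold")]))
  cat("Pipeline grid:", n, "configurations x", x$n_videos,
      "videos (seed", paste0(x$seed, ")\n"))
  for (f in c("fps", "recall", "precision", "accuracy", "threshold")) {
    cat(" ", f, ":", paste(x[[f]], collapse = ", "), "\n")
  }
  invisible(x)
}

# Maximum of each length-nf block of v (v laid out frame-major within
# species): the MaxN vector over the full pool.
block_max <- function(v, nf, n_pool) {
  mx <- integer(n_pool)
  for (s in seq_len(n_pool)) {
    mx[s] <- max(v[((s - 1L) * nf + 1L):(s * nf)])
  }
  mx
}

# Vectorised pipeline engine for one video at one processing rate, over all
# (recall, precision, accuracy, threshold) cells. Count-based: detection
# and correct-classification counts live on the sparse nonzero
# species-frame cells of the truth; only misidentifications and false
# positives are materialised as individual records. Distributionally
# identical to the record-level operations (threshold thinning of a set of
# exchangeable records is performed as a Binomial count plus a uniform
# subset). Sub-seeds guarantee that detection draws are shared across all
# threshold levels (and across precision and accuracy) of a cell.
run_cells_video <- function(video, fps, recalls, precisions, accuracies,
                            thresholds, seed) {
  plan <- frame_plan(video$duration_seconds, video$record_fps, fps)
  k <- plan$per_second
  nf <- plan$n_frames
  S <- video$n_pool

  sub <- video$second_matrix[, plan$seconds + 1L, drop = FALSE]
  nz <- which(sub > 0L, arr.ind = TRUE)
  sp_g <- video$composition$species_id[nz[, 1L]]
  base <- (nz[, 2L] - 1L) * k
  cell_sp <- rep(sp_g, each = k)
  cell_frame <- rep(base, each = k) + rep.int(seq_len(k), nrow(nz))
  cell_n <- rep(sub[nz], each = k)
  ic <- cell_frame + nf * (cell_sp - 1L)
  z <- length(ic)
  nbins <- nf * S

  n_detectable <- length(unique(sp_g))
  realized <- integer(S)
  realized[video$composition$species_id] <-
    as.integer(apply(video$second_matrix, 1, max))
  truth_set <- which(realized > 0)

  n_cells <- length(recalls) * length(precisions) * length(accuracies) *
    length(thresholds)
  col_r <- col_p <- col_a <- col_t <- numeric(n_cells)
  col_tot <- col_rich <- col_det <- integer(n_cells)
  col_hill <- col_jac <- col_bc <- numeric(n_cells)
  i <- 0L

  for (r in recalls) {
    set.seed(derive_seed(seed, "detect", video$video_id, fps, r))
    det <- if (z) stats::rbinom(z, cell_n, r) else integer(0)
    tp <- sum(det)

    # Background false positives per precision level: count from the
    # realised precision identity, placement uniform over analysed frames,
    # label uniform over the learned pool.
    fp <- lapply(precisions, function(p) {
      set.seed(derive_seed(seed, "fp", video$video_id, fps, r, p))
      n_fp <- as.integer(round(tp * (1 - p) / p))
      list(n = n_fp,
           idx = sample.int(nf, n_fp, replace = TRUE) +
             nf * (sample.int(S, n_fp, replace = TRUE) - 1L))
    })

    for (a in accuracies) {
      set.seed(derive_seed(seed, "classify", video$video_id, fps, r, a))
      corr <- if (z) stats::rbinom(z, det, a) else integer(0)
      mis <- det - corr
      nm <- sum(mis)
      m_true <- rep.int(cell_sp, mis)
      u <- sample.int(S - 1L, nm, replace = TRUE)
      m_idx <- rep.int(cell_frame, mis) + nf * (u + (u >= m_true) - 1L)

      for (t in thresholds) {
        set.seed(derive_seed(seed, "threshold", video$video_id, fps,
                             r, a, t))
        if (is.na(t)) {
          corr_kept <- corr
          m_kept <- m_idx
        } else {
          corr_kept <- if (z) stats::rbinom(z, corr, 1 - t / 20)
                       else integer(0)
          m_kept <- m_idx[sample.int(nm, stats::rbinom(1L, nm, 1 - t))]
        }

        for (j in seq_along(precisions)) {
          if (is.na(t)) {
            f_kept <- fp[[j]]$idx
          } else {
            set.seed(derive_seed(seed, "threshold-fp", video$video_id,
                                 fps, r, precisions[j], t))
            f_kept <- fp[[j]]$idx[
              sample.int(fp[[j]]$n, stats::rbinom(1L, fp[[j]]$n, 1 - t))]
          }
          v <- tabulate(c(m_kept, f_kept), nbins)
          if (z) v[ic] <- v[ic] + corr_kept
          mx <- block_max(v, nf, S)

          i <- i + 1L
          col_r[i] <- r; col_p[i] <- precisions[j]
          col_a[i] <- a; col_t[i] <- t
          col_tot[i] <- sum(mx)
          col_rich[i] <- sum(mx > 0)
          col_hill[i] <- if (col_tot[i] > 0) hill_shannon(mx) else 0
          col_jac[i] <- jaccard(which(mx > 0), truth_set)
          col_bc[i] <- bray_curtis(mx, realized)
          col_det[i] <- n_detectable
        }
      }
    }
  }

  tibble::tibble(
    video_id = video$video_id, fps = fps, recall = col_r,
    precision = col_p, accuracy = col_a, threshold = col_t,
    total_abundance = col_tot, richness = col_rich, hill_shannon = col_hill,
    jaccard = col_jac, bray_curtis = col_bc, detectable_species = col_det
  )
}

#' Run a factorial grid of pipelines over replicate videos
#'
#' Executes every pipeline configuration of `spec` on every video and
#' returns one tidy row per (video, configuration) with the estimated
#' biodiversity metrics and the similarity of the estimate to the realized
#' ground truth. Deterministic given the spec's master seed; rows are
#' independent given their derived sub-seeds, so any execution order yields
#' the same table (rows are sorted by cell key).
#'
#' Jaccard is computed between the estimated species set (MaxN > 0) and the
#' species actually visible on the video; Bray-Curtis between the estimated
#' MaxN vector and the realized ground-truth MaxN vector.
#'
#' @param spec A [grid_spec()].
#' @param videos Optional list of `gt_video`s; by default `spec$n_videos`
#'   videos are simulated from `spec$seed`.
#' @return A tibble with columns `video_id`, `fps`, `recall`, `precision`,
#'   `accuracy`, `threshold` (`NA` = no post-processing),
#'   `total_abundance`, `richness`, `hill_shannon`, `jaccard`,
#'   `bray_curtis`, `detectable_species`.
#' @examples
#' g <- grid_spec(fps = 1, recall = 0.9, precision = 0.9, accuracy = 0.9,
#'                threshold = NA, n_videos = 2, seed = 1)
#' run_grid(g)
#' @export
run_grid <- function(spec, videos = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(videos)) videos <- simulate_videos(spec$n_videos, spec$seed)
  if (inherits(videos, "gt_video")) videos <- list(videos)
  out <- vector("list", length(videos) * length(spec$fps))
  i <- 0L
  for (v in videos) {
    for (f in spec$fps) {
      i <- i + 1L
      out[[i]] <- run_cells_video(v, f, spec$recall, spec$precision,
                                  spec$accuracy, spec$threshold, spec$seed)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out),
                 .data$fps, .data$recall, .data$precision, .data$accuracy,
                 .data$threshold, .data$video_id)
}

#' Summarise grid results over replicate videos
#'
#' Per pipeline configuration: mean, standard deviation and standard error
#' (sd / sqrt(n videos)) of each metric over the replicate videos.
#'
#' @param rows Result tibble from [run_grid()].
#' @return One row per configuration with `<metric>_mean`, `<metric>_sd`
#'   and `<metric>_se` columns plus `n_videos`.
#' @export
summarize_grid <- function(rows) {
  metrics <- c("total_abundance", "richness", "hill_shannon",
               "jaccard", "bray_curtis", "detectable_species")
  rows |>
    dplyr::group_by(.data$fps, .data$recall, .data$precision,
                    .data$accuracy, .data$threshold) |>
    dplyr::summarise(
      n_videos = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = mean,
                         sd = stats::sd,
                         se = ~ stats::sd(.x) / sqrt(length(.x)))),
      .groups = "drop"
    )
}

#' Relative estimation error, in percent
#'
#' `100 * (estimate - truth) / truth`; the paper-style "overestimated by
#' 160%" reading. Undefined for a zero truth (`NA` with a warning).
#'
#' @param estimate,truth Numeric vectors (recycled).
#' @return Percent error, same length as the longer input.
#' @examples
#' relative_error(169, 65) # +160%
#' @export
relative_error <- function(estimate, truth) {
  out <- 100 * (estimate - truth) / truth
  if (any(truth == 0)) {
    warning("relative error undefined for zero truth")
    out[truth == 0] <- NA_real_
  }
  out
}
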