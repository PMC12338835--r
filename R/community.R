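#' Simulate the presence timeline of one species
#'
#' Generates the per-second abundance of a species over one video through
#' four steps: (1) the mean slot duration is the species' occupancy time
#' divided by its number of presence slots; (2) each slot duration is drawn
#' from a Normal with that mean and a standard deviation equal to the square
#' root of the mean, rounded to whole seconds and clamped to at least 1 s;
#' (3) slots are placed left to right with the gap before each slot drawn
#' from a discrete uniform over the feasible range (at least 1 s per
#' remaining slot is reserved so packing always succeeds); (4) the number of
#' individuals in each second of a slot is
#' `1 + Binomial(abundance - 1, presence_prob)`, i.i.d. across seconds:
#' a presence slot always shows at least one individual (that is what makes
#' it a presence slot), and each of the remaining `abundance - 1` group
#' mates is on screen independently with probability `presence_prob`.
#'
#' Durations are redrawn (up to `max_tries` times) in the rare event that
#' their sum leaves less than one free second per gap.
#'
#' @param group One design row (list or single-row data frame) with
#'   `abundance`, `occupancy_pct`, `n_slots`.
#' @param duration_seconds Video duration (default 600 s = 10 min).
#' @param presence_prob Per-second probability that each individual beyond
#'   the first is on screen during a slot. The default 0.9034 makes the
#'   expected number of visible fish instances per default video at 1 fps
#'   approximately 5,295.
#' @param max_tries Redraw budget for infeasible slot-duration draws.
#' @return A tibble of presence slots: `start_second` (0-based),
#'   `duration_seconds`, and a `counts` list-column of per-second
#'   individual counts.
#' @examples
#' set.seed(1)
#' tl <- simulate_timeline(default_design()[1, ])
#' nrow(tl) # 5 slots
#' @export
simulate_timeline <- function(group, duration_seconds = 600,
                              presence_prob = 0.9034, max_tries = 100) {
  n <- as.integer(group$n_slots)
  occ_sec <- group$occupancy_pct / 100 * duration_seconds
  if (occ_sec < n) stop("occupancy too small to fill every slot")
  mean_dur <- occ_sec / n

  dur <- NULL
  for (i in seq_len(max_tries)) {
    cand <- pmax(1L, as.integer(round(stats::rnorm(n, mean_dur,
                                                   sqrt(mean_dur)))))
    if (sum(cand) <= duration_seconds - n) {
      dur <- cand
      break
    }
  }
  if (is.null(dur)) {
    stop("could not pack ", n, " slots into ", duration_seconds,
         " seconds after ", max_tries, " draws")
  }

  # Left-to-right placement; reserve >= 1 s of gap for each later slot so
  # every draw keeps the remaining packing feasible.
  free <- duration_seconds - sum(dur)
  start <- integer(n)
  t <- 0L
  for (k in seq_len(n)) {
    remaining_after <- n - k
    gap <- sample.int(free - remaining_after, 1L)
    start[k] <- t + gap
    t <- start[k] + dur[k]
    free <- free - gap
  }

  counts <- lapply(seq_len(n), function(k) {
    1L + stats::rbinom(dur[k], as.integer(group$abundance) - 1L,
                       presence_prob)
  })
  tibble::tibble(start_second = start, duration_seconds = dur,
                 counts = counts)
}

#' Assemble a ground-truth video from per-species timelines
#'
#' Combines the sampled composition and the species timelines into the
#' per-second truth matrix of one video. The simulation resolution is one
#' second; video recording at `record_fps` frames per second is represented
#' implicitly: every frame of a second carries that second's counts (frame
#' expansion is constant within each second).
#'
#' @param pool A `regional_pool`.
#' @param composition Tibble from [sample_composition()].
#' @param timelines Named list of slot tibbles (names = species ids as
#'   character), one per composed species.
#' @param video_id Identifier stored with the video.
#' @param duration_seconds,record_fps Video length and recording rate.
#' @return An object of class `gt_video`: composition (with nominal
#'   abundance), the species-by-second truth matrix, the slot tibbles, and
#'   the recording parameters.
#' @export
assemble_video <- function(pool, composition, timelines, video_id = 1,
                           duration_seconds = 600, record_fps = 30) {
  ids <- composition$species_id
  if (!setequal(names(timelines), as.character(ids))) {
    stop("need exactly one timeline per composed species")
  }
  m <- matrix(0L, nrow = length(ids), ncol = duration_seconds,
              dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    tl <- timelines[[as.character(ids[i])]]
    end <- tl$start_second + tl$duration_seconds
    if (any(end > duration_seconds)) stop("slot extends past video end")
    if (nrow(tl) > 1) {
      o <- order(tl$start_second)
      if (any(tl$start_second[o][-1] < end[o][-nrow(tl)])) {
        stop("overlapping slots for species ", ids[i])
      }
    }
    for (k in seq_len(nrow(tl))) {
      sec <- tl$start_second[k] + seq_len(tl$duration_seconds[k])
      m[i, sec] <- as.integer(tl$counts[[k]])
    }
  }
  composition$abundance <-
    pool$design$abundance[match(composition$group_id, pool$design$group_id)]
  structure(
    list(
      video_id = video_id,
      duration_seconds = duration_seconds,
      record_fps = record_fps,
      n_pool = nrow(pool$species),
      design = pool$design,
      composition = composition,
      second_matrix = m,
      slots = timelines
    ),
    class = "gt_video"
  )
}

#' @export
print.gt_video <- function(x, ...) {
  cat("Ground-truth video", x$video_id, "-", x$duration_seconds, "s at",
      x$record_fps, "fps\n")
  cat(nrow(x$composition), "of", x$n_pool, "pool species; nominal total",
      sum(x$composition$abundance), "individuals\n")
  invisible(x)
}

#' Nominal and realized ground truth of a video
#'
#' The nominal truth is the design abundance of each composed species (what
#' the community "should" show); the realized truth is the per-species
#' maximum simultaneous count actually present on the video (MaxN of the
#' truth itself). Realized never exceeds nominal because within-slot counts
#' are binomial thinnings of the design abundance.
#'
#' @param video A `gt_video`.
#' @return A list with named integer vectors `nominal` and `realized`
#'   (names = species ids).
#' @export
nominal_truth <- function(video) {
  stopifnot(inherits(video, "gt_video"))
  nominal <- stats::setNames(as.integer(video$composition$abundance),
                             as.character(video$composition$species_id))
  realized <- apply(video$second_matrix, 1, max)
  list(nominal = nominal,
       realized = stats::setNames(as.integer(realized), names(nominal)))
}

#' Simulate ground-truth video surveys
#'
#' Top-level generator: builds the pool, samples the composition of each
#' video, simulates every species' timeline and assembles the truth
#' matrices. All randomness is driven by sub-seeds derived from
#' `seed`, so individual videos are reproducible independently of how many
#' are generated.
#'
#' @param n_videos Number of replicate surveys (default 10).
#' @param seed Master seed.
#' @param design Community design (default [default_design()]).
#' @inheritParams simulate_timeline
#' @param record_fps Recording frame rate (default 30).
#' @return `simulate_video()` returns one `gt_video`; `simulate_videos()` a
#'   list of them.
#' @examples
#' v <- simulate_video(video_id = 1, seed = 42)
#' nominal_truth(v)$nominal
#' @export
simulate_videos <- function(n_videos = 10, seed = 1,
                            design = default_design(),
                            duration_seconds = 600, record_fps = 30,
                            presence_prob = 0.9034) {
  lapply(seq_len(n_videos), function(i) {
    simulate_video(design = design, video_id = i, seed = seed,
                   duration_seconds = duration_seconds,
                   record_fps = record_fps, presence_prob = presence_prob)
  })
}

#' @rdname simulate_videos
#' @param video_id Identifier of the video to generate.
#' @export
simulate_video <- function(design = default_design(), video_id = 1,
                           seed = 1, duration_seconds = 600,
                           record_fps = 30, presence_prob = 0.9034) {
  pool <- build_pool(design, duration_seconds)
  set.seed(derive_seed(seed, "composition", video_id))
  comp <- sample_composition(pool)
  timelines <- lapply(seq_len(nrow(comp)), function(i) {
    set.seed(derive_seed(seed, "timeline", video_id, comp$species_id[i]))
    g <- design[design$group_id == comp$group_id[i], ]
    simulate_timeline(g, duration_seconds, presence_prob)
  })
  names(timelines) <- as.character(comp$species_id)
  assemble_video(pool, comp, timelines, video_id,
                 duration_seconds, record_fps)
}

#' Export / import ground truth as a long table
#'
#' One row per (video, species, second): columns `video_id`, `species_id`,
#' `group_id`, `second` (0-based) and `count`.
#'
#' @param videos A list of `gt_video` objects (or a single one).
#' @param file Path to a CSV file.
#' @return `ground_truth_table()` and `read_ground_truth()` return the long
#'   tibble; `write_ground_truth()` its file path, invisibly.
#' @export
ground_truth_table <- function(videos) {
  if (inherits(videos, "gt_video")) videos <- list(videos)
  dplyr::bind_rows(lapply(videos, function(v) {
    m <- v$second_matrix
    tibble::tibble(
      video_id = v$video_id,
      species_id = rep(v$composition$species_id, ncol(m)),
      group_id = rep(v$composition$group_id, ncol(m)),
      second = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
      count = as.integer(m)
    )
  }))
}

#' @rdname ground_truth_table
#' @export
write_ground_truth <- function(videos, file) {
  readr::write_csv(ground_truth_table(videos), file)
  invisible(file)
}

#' @rdname ground_truth_table
#' @export
read_ground_truth <- function(file) {
  readr::read_csv(file, show_col_types = FALSE,
                  col_types = readr::cols())
}
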