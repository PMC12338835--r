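# Fixtures built in code; no stored data.

# A two-group toy design: one schooling species and one rare singleton.
tiny_design <- function() {
  tibble::tibble(
    group_id        = 1:2,
    abundance       = c(3L, 1L),
    occupancy_pct   = c(50, 10),
    n_slots         = c(2L, 1L),
    n_pool_species  = c(2L, 2L),
    n_video_species = c(1L, 1L)
  )
}

# Build a gt_video directly from a species-by-second count matrix, for
# deterministic pipeline tests. Species ids are taken from rownames.
manual_video <- function(mat, n_pool = 30, record_fps = 30, video_id = 1) {
  ids <- as.integer(rownames(mat))
  structure(
    list(
      video_id = video_id,
      duration_seconds = ncol(mat),
      record_fps = record_fps,
      n_pool = n_pool,
      design = NULL,
      composition = tibble::tibble(
        species_id = ids,
        group_id = seq_along(ids),
        abundance = as.integer(apply(mat, 1, max))
      ),
      second_matrix = mat,
      slots = NULL
    ),
    class = "gt_video"
  )
}

# Independent MaxN oracle: per-frame tally with table(), max per label.
brute_force_maxn <- function(records, n_pool) {
  if (!is.null(records$retained)) records <- records[records$retained, ]
  out <- setNames(integer(n_pool), as.character(seq_len(n_pool)))
  for (s in seq_len(n_pool)) {
    fr <- records$frame[records$label == s]
    if (length(fr) > 0) out[s] <- max(table(fr))
  }
  out
}

# Realized ground-truth MaxN of a video, embedded on the full pool.
realized_vector <- function(video) {
  out <- integer(video$n_pool)
  out[video$composition$species_id] <- nominal_truth(video)$realized
  out
}
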