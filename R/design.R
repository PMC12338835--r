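#' Default eight-group community design
#'
#' The community design that drives all default simulations: a regional pool
#' of 30 species split into 8 groups with contrasting abundance (maximum
#' number of individuals seen simultaneously, 1--20), relative temporal
#' occupancy (proportion of the video during which the species is on screen,
#' 0.5--90%), and clustering of presence in time (1--15 presence slots).
#' Each 10-minute video samples 15 of the 30 species (1--3 per group).
#'
#' The groups span the spread of abundance, mobility and gregariousness seen
#' in communities surveyed with remote cameras: from 20 gregarious
#' individuals visible 20% of the time in 5 bouts, down to a single elusive
#' individual on screen 0.5% of the time in one pass.
#'
#' @return A tibble with one row per group and columns `group_id`,
#'   `abundance`, `occupancy_pct`, `n_slots`, `n_pool_species`,
#'   `n_video_species`.
#' @examples
#' d <- default_design()
#' sum(d$n_pool_species)  # 30 species in the regional pool
#' sum(d$n_video_species) # 15 species per video
#' @export
default_design <- function() {
  tibble::tibble(
    group_id        = 1:8,
    abundance       = c(20L, 2L, 2L, 8L, 8L, 1L, 1L, 1L),
    occupancy_pct   = c(20, 90, 30, 10, 5, 5, 1, 0.5),
    n_slots         = c(5L, 15L, 15L, 1L, 1L, 1L, 1L, 1L),
    n_pool_species  = c(3L, 3L, 3L, 3L, 3L, 5L, 5L, 5L),
    n_video_species = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 2L)
  )
}

design_columns <- c(
  "group_id", "abundance", "occupancy_pct", "n_slots",
  "n_pool_species", "n_video_species"
)

#' Validate a community design table
#'
#' Checks the structural invariants a design must satisfy before simulation:
#' positive abundances and slot counts, occupancy in (0, 100], at least as
#' many pool species as per-video species in every group, and enough
#' occupancy seconds to fill every slot with at least one second.
#'
#' @param design A design tibble as returned by [default_design()].
#' @param duration_seconds Video duration the design will be simulated at.
#' @return `design`, invisibly, after passing all checks.
#' @export
validate_design <- function(design, duration_seconds = 600) {
  if (!all(design_columns %in% names(design))) {
    stop("design must have columns: ", paste(design_columns, collapse = ", "))
  }
  with(design, {
    if (any(abundance < 1)) stop("abundance must be a positive integer")
    if (any(occupancy_pct <= 0 | occupancy_pct > 100)) {
      stop("occupancy_pct must lie in (0, 100]")
    }
    if (any(n_slots < 1)) stop("n_slots must be a positive integer")
    if (any(n_pool_species < 1)) {
      stop("every group needs at least one species in the pool")
    }
    if (any(n_video_species > n_pool_species)) {
      stop("n_video_species cannot exceed n_pool_species")
    }
    occ_sec <- occupancy_pct / 100 * duration_seconds
    if (any(occ_sec < n_slots)) {
      stop("occupancy seconds must cover at least one second per slot")
    }
  })
  invisible(design)
}

#' Build the regional species pool from a design
#'
#' Assigns consecutive species identifiers to each group's pool members.
#' Deterministic: no randomness is involved; species `1..n` are numbered
#' group by group in design order.
#'
#' @inheritParams validate_design
#' @return An object of class `regional_pool`: a list with `species`
#'   (tibble of `species_id`, `group_id`) and the `design` it came from.
#' @examples
#' pool <- build_pool(default_design())
#' nrow(pool$species) # 30
#' @export
build_pool <- function(design, duration_seconds = 600) {
  validate_design(design, duration_seconds)
  species <- tibble::tibble(
    species_id = seq_len(sum(design$n_pool_species)),
    group_id = rep(design$group_id, design$n_pool_species)
  )
  structure(list(species = species, design = design), class = "regional_pool")
}

#' @export
print.regional_pool <- function(x, ...) {
  cat("Regional pool:", nrow(x$species), "species in",
      nrow(x$design), "groups\n")
  print(dplyr::count(x$species, .data$group_id, name = "n_species"))
  invisible(x)
}

#' Sample the species composition of one video
#'
#' Draws, for each group, the design's number of per-video species uniformly
#' without replacement from that group's pool members, emulating which pool
#' species happen to visit the camera during one survey.
#'
#' @param pool A `regional_pool` from [build_pool()].
#' @return A tibble (`species_id`, `group_id`) with one row per composed
#'   species (15 rows for the default design).
#' @examples
#' set.seed(1)
#' comp <- sample_composition(build_pool(default_design()))
#' table(comp$group_id)
#' @export
sample_composition <- function(pool) {
  stopifnot(inherits(pool, "regional_pool"))
  picks <- lapply(seq_len(nrow(pool$design)), function(g) {
    ids <- pool$species$species_id[pool$species$group_id ==
                                     pool$design$group_id[g]]
    n <- pool$design$n_video_species[g]
    ids[sample.int(length(ids), n)]
  })
  ids <- unlist(picks)
  tibble::tibble(
    species_id = ids,
    group_id = pool$species$group_id[match(ids, pool$species$species_id)]
  )
}

#' Read / write a community design as CSV
#'
#' The on-disk format has exactly the columns of [default_design()].
#'
#' @param file Path to a CSV file.
#' @return `read_design()` returns a validated design tibble.
#' @export
read_design <- function(file) {
  d <- readr::read_csv(file, show_col_types = FALSE,
                       col_types = readr::cols())
  d <- d[design_columns]
  for (col in setdiff(design_columns, "occupancy_pct")) {
    d[[col]] <- as.integer(d[[col]])
  }
  validate_design(d)
  d
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, file) {
  validate_design(design)
  readr::write_csv(design[design_columns], file)
  invisible(file)
}
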