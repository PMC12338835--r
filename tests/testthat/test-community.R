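test_that("composition sampling respects the per-group design", {
  pool <- build_pool(default_design())
  set.seed(11)
  for (i in 1:20) {
    comp <- sample_composition(pool)
    expect_equal(nrow(comp), 15)
    expect_equal(anyDuplicated(comp$species_id), 0)
    expect_equal(as.integer(table(comp$group_id)),
                 default_design()$n_video_species)
  }
})

test_that("groups sampled exhaustively always contribute all their species", {
  d <- tiny_design()
  d$n_video_species <- d$n_pool_species # take everything
  pool <- build_pool(d)
  set.seed(5)
  for (i in 1:10) {
    expect_setequal(sample_composition(pool)$species_id,
                    pool$species$species_id)
  }
})

test_that("within-group sampling is uniform", {
  # Group 1 contributes 1 of its 3 species; the pick must be uniform.
  pool <- build_pool(default_design())
  set.seed(21)
  picks <- replicate(3000, sample_composition(pool)$species_id[1])
  expect_setequal(unique(picks), 1:3)
  expect_gt(stats::chisq.test(table(picks))$p.value, 1e-4)
})

test_that("timelines implement the four-step procedure", {
  d <- default_design()
  set.seed(31)
  for (g in c(1, 2, 8)) {
    grp <- d[g, ]
    tl <- simulate_timeline(grp)
    expect_equal(nrow(tl), grp$n_slots)
    expect_true(all(tl$duration_seconds >= 1))
    # non-overlapping, in order, inside the video
    expect_true(all(diff(tl$start_second) >=
                      tl$duration_seconds[-nrow(tl)]))
    expect_lte(max(tl$start_second + tl$duration_seconds), 600)
    # every slot-second shows between 1 and `abundance` individuals
    counts <- unlist(tl$counts)
    expect_true(all(counts >= 1 & counts <= grp$abundance))
  }
})

test_that("mean slot duration matches occupancy / n_slots", {
  # group 1: 20% of 600 s over 5 slots -> 24 s; group 2: 90% over 15 -> 36 s
  d <- default_design()
  set.seed(41)
  for (case in list(c(1, 24), c(2, 36))) {
    sims <- replicate(400, mean(simulate_timeline(d[case[1], ],
                                                  600)$duration_seconds))
    se <- stats::sd(sims) / sqrt(length(sims))
    expect_lt(abs(mean(sims) - case[2]), 4 * se + 0.5) # 0.5: rounding bias
  }
})

test_that("realized occupancy tracks the design occupancy", {
  # Slot seconds always hold >= 1 individual, so realized occupancy is the
  # total slot time; its mean must sit close to the design's occupancy.
  d <- default_design()
  set.seed(51)
  for (g in c(1, 4, 8)) {
    occ <- replicate(1000, sum(simulate_timeline(d[g, ],
                                                 600)$duration_seconds))
    target <- d$occupancy_pct[g] / 100 * 600
    se <- stats::sd(occ) / sqrt(length(occ))
    expect_lt(abs(mean(occ) - target), 3 * se + 0.5)
  }
})

test_that("presence_prob = 1 realizes the nominal abundance exactly", {
  v <- simulate_video(seed = 3, presence_prob = 1)
  nt <- nominal_truth(v)
  expect_identical(nt$realized, nt$nominal)
})

test_that("realized truth never exceeds nominal and hits study headlines", {
  v <- simulate_video(seed = 8)
  nt <- nominal_truth(v)
  expect_equal(sum(nt$nominal), 65)
  expect_equal(length(nt$nominal), 15)
  expect_true(all(nt$realized <= nt$nominal))
  expect_true(all(nt$realized >= 0))
})

test_that("frame expansion is constant within seconds and conserves counts", {
  v <- simulate_video(seed = 13)
  ti30 <- maxnsim:::truth_instances(v, select_frames(600, 30, 30))
  # 30 identical frames per second: total instances = 30 x per-second total
  expect_equal(sum(ti30$count), 30 * sum(v$second_matrix))
  # every frame of a second carries that second's counts
  sec <- ti30$frame %/% 30
  per <- tapply(ti30$count, list(ti30$species, sec), unique)
  expect_true(all(vapply(per[!is.na(per)], length, 1L) == 1))
})

test_that("video simulation is seed-deterministic", {
  a <- simulate_video(seed = 99, video_id = 4)
  b <- simulate_video(seed = 99, video_id = 4)
  expect_identical(a$second_matrix, b$second_matrix)
  expect_identical(a$composition, b$composition)
  c <- simulate_video(seed = 99, video_id = 5)
  expect_false(identical(a$second_matrix, c$second_matrix))
})

test_that("overlapping slots are rejected at assembly", {
  d <- tiny_design()
  pool <- build_pool(d)
  comp <- tibble::tibble(species_id = c(1L, 3L), group_id = c(1L, 2L))
  bad <- tibble::tibble(start_second = c(0L, 5L), duration_seconds = c(10L, 3L),
                        counts = list(rep(1L, 10), rep(1L, 3)))
  ok <- tibble::tibble(start_second = 0L, duration_seconds = 3L,
                       counts = list(rep(1L, 3)))
  expect_error(
    assemble_video(pool, comp, list(`1` = bad, `3` = ok), duration_seconds = 60),
    "overlapping"
  )
})

test_that("ground-truth long table round-trips through CSV", {
  v <- simulate_videos(2, seed = 17)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(v, f)
  gt <- read_ground_truth(f)
  expect_equal(nrow(gt), 2 * 15 * 600)
  expect_equal(sum(gt$count), sum(sapply(v, function(x) sum(x$second_matrix))))
  m1 <- gt[gt$video_id == 1 & gt$species_id == v[[1]]$composition$species_id[1], ]
  expect_equal(m1$count[order(m1$second)],
               unname(v[[1]]$second_matrix[1, ]))
})
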