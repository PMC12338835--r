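test_that("the default grid spans 14,406 pipeline configurations", {
  g <- grid_spec()
  expect_equal(prod(lengths(g[c("fps", "recall", "precision", "accuracy",
                                "threshold")])), 14406)
  expect_equal(length(g$threshold), 6) # five levels plus "none"
})

test_that("run_grid emits one row per video and configuration", {
  videos <- simulate_videos(3, seed = 23)
  g <- grid_spec(fps = c(0.5, 1), recall = c(0.8, 0.99), precision = 0.9,
                 accuracy = c(0.7, 0.9), threshold = c(NA, 0.9),
                 n_videos = 3, seed = 23)
  r <- run_grid(g, videos)
  expect_equal(nrow(r), 3 * 2 * 2 * 1 * 2 * 2)
  key <- r[c("video_id", "fps", "recall", "precision", "accuracy",
             "threshold")]
  expect_equal(anyDuplicated(key), 0)

  # single-level spec: one row per video
  g1 <- grid_spec(fps = 1, recall = 0.9, precision = 0.9, accuracy = 0.9,
                  threshold = NA, n_videos = 3, seed = 23)
  expect_equal(nrow(run_grid(g1, videos)), 3)
})

test_that("grid runs are deterministic and order-independent", {
  videos <- simulate_videos(2, seed = 29)
  g <- grid_spec(fps = c(1, 2), recall = c(0.7, 0.9), precision = 0.8,
                 accuracy = 0.8, threshold = c(NA, 0.95), seed = 29)
  r1 <- run_grid(g, videos)
  r2 <- run_grid(g, videos)
  expect_identical(r1, r2)
  r3 <- run_grid(g, rev(videos))
  expect_identical(r1, r3)
})

test_that("threshold levels do not perturb detection draws", {
  # The no-threshold rows must be identical whether or not thresholded
  # cells are computed alongside them.
  v <- simulate_video(seed = 31)
  base <- grid_spec(fps = 1, recall = 0.8, precision = 0.8, accuracy = 0.8,
                    threshold = NA, seed = 31)
  wide <- grid_spec(fps = 1, recall = 0.8, precision = 0.8, accuracy = 0.8,
                    threshold = c(NA, 0.8, 0.99), seed = 31)
  r_base <- run_grid(base, list(v))
  r_wide <- run_grid(wide, list(v))
  expect_equal(r_base, r_wide[is.na(r_wide$threshold), ])
})

test_that("perfect-pipeline cells reproduce realized truth at every rate", {
  v <- simulate_video(seed = 37)
  truth <- realized_vector(v)
  g <- grid_spec(fps = c(0.25, 0.5, 1, 2, 5, 10, 30), recall = 1,
                 precision = 1, accuracy = 1, threshold = NA, seed = 37)
  r <- run_grid(g, list(v))
  full <- r[r$fps >= 1, ]
  expect_true(all(full$total_abundance == sum(truth)))
  expect_true(all(full$richness == sum(truth > 0)))
  expect_true(all(full$jaccard == 1))
  expect_true(all(full$bray_curtis == 1))
  expect_equal(full$hill_shannon,
               rep(hill_shannon(truth), nrow(full)))
})

test_that("summaries report mean, sd and standard error per cell", {
  rows <- tibble::tibble(
    video_id = 1:2, fps = 1, recall = 0.9, precision = 0.9, accuracy = 0.9,
    threshold = NA_real_, total_abundance = c(1, 3), richness = c(5L, 5L),
    hill_shannon = c(2, 4), jaccard = 0.5, bray_curtis = 0.8,
    detectable_species = 15L
  )
  s <- summarize_grid(rows)
  expect_equal(nrow(s), 1)
  expect_equal(s$total_abundance_mean, 2)
  expect_equal(s$total_abundance_sd, sqrt(2))
  expect_equal(s$total_abundance_se, 1)
  expect_equal(s$richness_sd, 0)
  expect_equal(s$n_videos, 2)
})

test_that("relative error is expressed in percent of the truth", {
  expect_equal(relative_error(169, 65), 160)
  expect_equal(relative_error(65, 65), 0)
  expect_equal(round(relative_error(69.6, 65), 1), 7.1)
  expect_warning(expect_true(is.na(relative_error(3, 0))), "zero truth")
})

test_that("the command-line interface drives the full workflow", {
  out <- withr::local_tempdir()
  expect_invisible(maxnsim_cli(c("simulate", "--seed", "5",
                                 "--replicates", "2", "--out", out)))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(file.exists(file.path(out, "design.csv")))

  res <- file.path(out, "results.csv")
  maxnsim_cli(c("run-grid", "--seed", "5", "--replicates", "2",
                "--fps", "1", "--recall", "0.9", "--precision", "0.9",
                "--accuracy", "0.9", "--threshold", "none,0.99",
                "--out", res))
  tab <- readr::read_csv(res, show_col_types = FALSE)
  expect_equal(nrow(tab), 2 * 2)

  summ <- file.path(out, "summary.csv")
  maxnsim_cli(c("summarize", "--results", res, "--out", summ))
  expect_equal(nrow(readr::read_csv(summ, show_col_types = FALSE)), 2)

  expect_equal(suppressMessages(maxnsim_cli("not-a-command")), 1L)
})
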