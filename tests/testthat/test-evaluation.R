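# a compact cohort reused across evaluation tests: 3 clips of A, 2 of B
make_cohort <- function() {
  c(sample_player(swing_style(seed = 2), 3, seed = 31, player_id = "A"),
    sample_player(swing_style(arc_radius = 1.5, top_height = -1.35,
                              plane_offset = 0.06, seed = 3),
                  2, seed = 32, player_id = "B"))
}

test_that("pairwise evaluation enumerates unordered pairs with classes", {
  tab <- pairwise_evaluation(make_cohort(), "dmsm")
  expect_s3_class(tab, "eval_table")
  expect_equal(nrow(tab), choose(5, 2))
  expect_equal(sum(tab$pair_class == "same_player"),
               choose(3, 2) + choose(2, 2))
  expect_equal(sum(tab$pair_class == "cross_player"), 3 * 2)
  expect_true(all(tab$clip_a != tab$clip_b))       # no self-pairs
  key <- paste(pmin(tab$clip_a, tab$clip_b), pmax(tab$clip_a, tab$clip_b))
  expect_false(any(duplicated(key)))               # each pair once
  expect_true(all(is.finite(tab$overall_DS)))
  expect_true(all(!is.na(tab[paste0("DS_", phase_names)])))
})

test_that("a single-player cohort yields a table but no separation", {
  two <- sample_player(swing_style(seed = 5), 2, seed = 41, player_id = "solo")
  tab <- pairwise_evaluation(two, "dmsm")
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$pair_class, "same_player")
  expect_error(separation_statistics(tab), "same-player and one cross-player")
})

test_that("clips that fail to segment are excluded with a logged reason", {
  cohort <- make_cohort()
  still <- make_test_seq(n = 90, clip_id = "frozen", player_id = "A")
  expect_warning(tab <- pairwise_evaluation(c(cohort, list(still)), "dmsm"),
                 "frozen")
  expect_equal(nrow(tab), choose(5, 2))
  fails <- attr(tab, "failures")
  expect_identical(fails$clip_id, "frozen")
  expect_match(fails$reason, "takeaway")
})

test_that("separation statistics recover a constructed effect size", {
  set.seed(4)
  n <- 50
  fake <- function(ds, cls) data.frame(overall_DS = ds, pair_class = cls)
  # null: both classes from the same distribution
  null_tab <- fake(c(rnorm(n), rnorm(n)),
                   rep(c("same_player", "cross_player"), each = n))
  st0 <- separation_statistics(null_tab, n_bootstrap = 500, seed = 9)
  expect_gt(st0$p_value, 0.05)
  expect_lt(abs(st0$separation), 0.5)

  # shifted: N(0,1) vs N(1,1) -> d ~ 1, p tiny, CI excludes 0
  shift_tab <- fake(c(rnorm(n, 0), rnorm(n, 1)),
                    rep(c("same_player", "cross_player"), each = n))
  st1 <- separation_statistics(shift_tab, n_bootstrap = 1000, seed = 9)
  expect_lt(st1$p_value, 0.01)
  expect_equal(st1$cohens_d, 1, tolerance = 0.35)
  expect_gt(st1$bootstrap_ci_95[1], 0)
  expect_identical(sign(st1$cohens_d), sign(st1$separation))
  expect_true(st1$bootstrap_ci_95[1] <= st1$bootstrap_ci_95[2])

  # bootstrap is reproducible under the seed
  st2 <- separation_statistics(shift_tab, n_bootstrap = 1000, seed = 9)
  expect_identical(st1$bootstrap_ci_95, st2$bootstrap_ci_95)
})

test_that("label permutation destroys the observed separation", {
  tab <- pairwise_evaluation(make_cohort(), "dmsm")
  obs <- separation_statistics(tab, n_bootstrap = 200, seed = 1)$separation
  set.seed(123)
  perm <- replicate(30, {
    sh <- tab
    sh$pair_class <- sample(sh$pair_class)
    separation_statistics(sh, n_bootstrap = 100, seed = 1)$separation
  })
  expect_gt(obs, stats::quantile(abs(perm), 0.9))
})

test_that("method comparison pairs methods on identical pair lists", {
  cohort <- make_cohort()
  mc <- method_comparison(cohort, c("dmsm", "dmsm"), n_bootstrap = 200)
  expect_identical(mc$summary$mean_paired_diff[2], 0)
  expect_identical(mc$summary$p_vs_reference[2], 1)

  mc2 <- method_comparison(cohort, c("dmsm", "dtw_cosine", "euclidean"),
                           n_bootstrap = 200)
  expect_identical(mc2$summary$method, c("dmsm", "dtw_cosine", "euclidean"))
  expect_equal(nrow(mc2$tables$dtw_cosine), choose(5, 2))
  expect_true(all(c("mean_similarity", "sd_similarity", "separation",
                    "p_vs_reference") %in% names(mc2$summary)))
  expect_false(any(is.na(mc2$summary$mean_similarity)))

  expect_error(method_comparison(cohort, character(0)), "non-empty")
})

test_that("evaluation works from an on-disk manifest", {
  dir <- withr::local_tempdir()
  cohort <- make_cohort()
  rows <- do.call(rbind, lapply(cohort, function(cl) {
    s <- cl$sequence
    path <- paste0(s$clip_id, ".csv")
    write_pose_sequence(s, file.path(dir, path))
    data.frame(clip_id = s$clip_id, player_id = s$player_id, path = path,
               handedness = s$handedness, fps = s$fps,
               level = "professional")
  }))
  mf <- file.path(dir, "clips.tsv")
  write_manifest(rows, mf)
  man <- read_manifest(mf)
  tab_disk <- pairwise_evaluation(man, "dmsm")
  tab_mem <- pairwise_evaluation(cohort, "dmsm")
  expect_equal(tab_disk$overall_DS, tab_mem$overall_DS, tolerance = 1e-6)
})
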