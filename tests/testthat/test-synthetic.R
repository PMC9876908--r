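task <- two_step_task()

small_spec <- cohort_spec(n_proself = 6, n_prosocial = 6, seed = 101)

test_that("cohort generation is deterministic and group-structured", {
  expect_length(generate_cohort(cohort_spec(0, 0)), 0L)

  c1 <- generate_cohort(small_spec, task)
  c2 <- generate_cohort(small_spec, task)
  expect_identical(c1[[3]]$trials, c2[[3]]$trials)
  expect_identical(c1[[9]]$true_params, c2[[9]]$true_params)
  expect_length(c1, 12L)
  groups <- vapply(c1, function(p) p$group, character(1))
  expect_equal(sum(groups == "proself"), 6L)

  # per-participant child seeds are recorded and distinct
  seeds <- vapply(c1, function(p) p$seed, numeric(1))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("generated trials satisfy the task invariants", {
  cohort <- generate_cohort(small_spec, task)
  tt <- task$transitions
  for (p in cohort[c(1, 7)]) {
    tr <- p$trials
    expect_equal(nrow(tr), 200L)
    for (i in c(1, 50, 200)) {
      r1 <- tt[tt$state == "S0" & tt$action == tr$a1[i], ]
      expect_true(tr$s2[i] %in% r1$next_state)
      expect_equal(tr$transition[i],
                   ifelse(r1$prob[match(tr$s2[i], r1$next_state)] >= 0.5,
                          "common", "rare"))
      expect_equal(tr$reward_yen[i], unname(task$reward_yen[tr$s3[i]]))
    }
    expect_true(all(tr$rt1_ms >= 150 & tr$rt1_ms <= 2000))
    expect_equal(nrow(p$true_params), 5L)
    expect_true(all(p$true_params$w >= 0 & p$true_params$w <= 1))
  }
})

test_that("cohort-wide common-transition frequency matches the task", {
  cohort <- generate_cohort(cohort_spec(n_proself = 40, n_prosocial = 40,
                                        seed = 103), task)
  trans <- unlist(lapply(cohort, function(p) p$trials$transition))
  expect_lt(abs(mean(trans == "common") - 0.7), 0.01)
})

test_that("sampled group parameters respect the block-1 weight ordering", {
  cohort <- generate_cohort(cohort_spec(n_proself = 30, n_prosocial = 30,
                                        seed = 104), task)
  w1 <- vapply(cohort, function(p) p$true_params$w[1], numeric(1))
  grp <- vapply(cohort, function(p) p$group, character(1))
  expect_gt(mean(w1[grp == "proself"]), mean(w1[grp == "prosocial"]))
  # SVO targets land inside their group's band
  ang <- vapply(cohort, function(p) p$svo_angle_target, numeric(1))
  expect_true(all(ang[grp == "proself"] <= 7.82))
  expect_true(all(ang[grp == "prosocial"] >= 37.48))
  # and scored responses reproduce the intended labels
  scored <- score_svo(do.call(rbind, lapply(cohort, function(p)
    cbind(participant_id = p$participant_id, p$svo))))
  expect_equal(unname(scored$group_strict[match(
    vapply(cohort, function(p) p$participant_id, character(1)),
    scored$participant_id)]),
    ifelse(grp == "proself", "proself", "prosocial"))
})

test_that("reaction times carry the surprise and practice structure", {
  m <- cohort_spec()$rt_model
  set.seed(105)
  base <- generate_rts(rep(150L, 500), rep(0, 500), m)
  set.seed(105)
  slow <- generate_rts(rep(150L, 500), rep(0.5, 500), m)
  expect_gt(mean(slow$rt2_ms), mean(base$rt2_ms))
  expect_equal(mean(base$rt2_ms), m$rt2_base, tolerance = 10)
  expect_true(all(slow$rt2_ms >= m$floor & slow$rt2_ms <= m$cap))
  set.seed(106)
  early <- generate_rts(1:10, rep(0, 10), m)
  set.seed(106)
  late <- generate_rts(191:200, rep(0, 10), m)
  expect_gt(mean(early$rt1_ms), mean(late$rt1_ms))
  expect_error(generate_rts(1:3, c(0, 0.5, 2), m), "surprise")

  # in a generated cohort, late blocks show RT1 < RT2 common < RT2 rare
  cohort <- generate_cohort(cohort_spec(n_proself = 10, n_prosocial = 10,
                                        seed = 107), task)
  s <- do.call(rbind, lapply(cohort, function(p)
    rt_block_summaries(p$trials)))
  late <- s[s$block == 5, ]
  expect_gt(mean(late$rt2_common_mean), mean(late$rt1_mean))
  expect_gt(mean(late$rt2_rare_mean, na.rm = TRUE),
            mean(late$rt2_common_mean))
})

test_that("cohorts round-trip through the CSV files field-for-field", {
  dir <- tempfile("cohort")
  cohort <- generate_cohort(small_spec, task)
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv", "svo.csv",
                                               "truth.csv")))))
  back <- read_cohort(dir)
  expect_length(back, length(cohort))
  for (i in c(1, 5, 12)) {
    expect_equal(back[[i]]$participant_id, cohort[[i]]$participant_id)
    expect_equal(back[[i]]$group, cohort[[i]]$group)
    expect_equal(back[[i]]$trials[, names(back[[i]]$trials)],
                 cohort[[i]]$trials[, names(back[[i]]$trials)],
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$svo, cohort[[i]]$svo, ignore_attr = TRUE)
    expect_equal(back[[i]]$true_params, cohort[[i]]$true_params,
                 ignore_attr = TRUE)
  }

  # missing RT cells survive the round trip
  cohort[[1]]$trials$rt2_ms[5] <- NA
  write_cohort(cohort, dir)
  expect_true(is.na(read_cohort(dir)[[1]]$trials$rt2_ms[5]))

  # schema violations name the offending row
  bad <- utils::read.csv(file.path(dir, "trials.csv"))
  bad$transition[7] <- "comon"
  utils::write.csv(bad, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "transition label.*7")
})

test_that("the ingestion adapter maps foreign column names", {
  cohort <- generate_cohort(cohort_spec(1, 0, seed = 108), task)
  foreign <- cohort[[1]]$trials
  names(foreign)[names(foreign) == "a1"] <- "choice1"
  names(foreign)[names(foreign) == "a2"] <- "choice2"
  f <- tempfile(fileext = ".csv")
  utils::write.csv(foreign, f, row.names = FALSE)
  expect_error(read_trial_log(f), "a1")
  mapped <- read_trial_log(f, col_map = c(a1 = "choice1", a2 = "choice2"))
  expect_equal(mapped$a1, cohort[[1]]$trials$a1)
})
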