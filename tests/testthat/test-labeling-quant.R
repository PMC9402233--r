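# Minimal hand-built record sets exercise each filter rule; simulator-backed
# cases cover the cascade end to end.

frag_row <- function(series = "y", proteo = TRUE, lys = 1L, excl = FALSE,
                     channel = "light", intensity = 100, rep = 1L, tm = 30,
                     prec = "pep1/2", idx = 4L, prot = "P1") {
  tibble::tibble(
    bait_id = "B1", condition = "none", replicate = rep, time_min = tm,
    protein_id = prot, is_proteotypic = proteo, precursor_id = prec,
    fragment_series = series, fragment_index = idx, fragment_charge = 1L,
    channel = channel, intensity = intensity, excluded_flag = excl,
    lysine_count = lys, missed_cleavages = 0L
  )
}

both_channels <- function(...) {
  dplyr::bind_rows(frag_row(channel = "light", ...),
                   frag_row(channel = "heavy", ...))
}

test_that("fragment filters enforce each selection rule", {
  rec <- dplyr::bind_rows(
    both_channels(idx = 4L),                       # retained
    both_channels(series = "b", idx = 5L),         # b-series out
    both_channels(lys = 2L, idx = 6L),             # two lysines out
    both_channels(proteo = FALSE, idx = 7L),       # non-proteotypic out
    both_channels(excl = TRUE, idx = 8L),          # flagged out
    frag_row(channel = "heavy", idx = 9L)          # never seen in light, out
  )
  out <- filter_fragments(rec)
  expect_identical(sort(unique(out$fragment_index)), 4L)
  expect_equal(attr(out, "n_removed"), nrow(rec) - nrow(out))
  # idempotence (the removal counter aside, the records are unchanged)
  again <- filter_fragments(out)
  expect_equal(again, out, ignore_attr = TRUE)
  expect_equal(attr(again, "n_removed"), 0L)
})

test_that("both-channels detection can be required per sample", {
  rec <- dplyr::bind_rows(
    both_channels(rep = 1L),
    frag_row(channel = "light", rep = 2L),   # heavy missing in replicate 2
    frag_row(channel = "heavy", rep = 2L, intensity = 0)
  )
  lib_level <- filter_fragments(rec, both_channels = "experiment")
  expect_equal(nrow(lib_level), 4)           # zero rows kept, sums see 0
  per_sample <- filter_fragments(rec, both_channels = "per_sample")
  expect_identical(unique(per_sample$replicate), 1L)
})

test_that("precursor aggregation sums fragments or their top 3", {
  rec <- dplyr::bind_rows(
    both_channels(idx = 4L, intensity = 100),
    both_channels(idx = 5L, intensity = 50)
  )
  rec$intensity[rec$channel == "light"] <- c(10, 5)
  sum_all <- aggregate_precursors(rec)
  expect_equal(sum_all$H, 150)
  expect_equal(sum_all$L, 15)

  four <- purrr::map_dfr(1:4, function(i) {
    r <- both_channels(idx = 3L + i, intensity = c(40, 30, 20, 10)[i])
    r
  })
  top3 <- aggregate_precursors(four, aggregation = "top3")
  expect_equal(top3$H, 90)   # 40 + 30 + 20

  # a sample with no detected fragment yields a missing FL
  rec2 <- dplyr::bind_rows(
    both_channels(rep = 1L),
    both_channels(rep = 2L, intensity = 0)
  )
  agg <- aggregate_precursors(rec2)
  expect_true(is.na(agg$FL[agg$replicate == 2]))
  expect_equal(agg$FL[agg$replicate == 1], 0.5)
})

test_that("presence filter applies the replicate rule per time point", {
  # detection pattern: 30 min in 2 reps, 60 min in 1 rep, 90 min in 3 reps
  pattern <- list(`30` = 1:2, `60` = 2L, `90` = 1:3)
  rec <- purrr::map_dfr(names(pattern), function(tm) {
    purrr::map_dfr(1:3, function(r) {
      det <- r %in% pattern[[tm]]
      both_channels(rep = as.integer(r), tm = as.numeric(tm),
                    intensity = if (det) 100 else 0)
    })
  })
  prec <- aggregate_precursors(filter_fragments(rec))
  expect_equal(nrow(presence_filter(prec, min_reps = 2)), 0)
  expect_equal(nrow(presence_filter(prec, min_reps = 1)), nrow(prec))
  expect_identical(presence_filter(prec, min_reps = 0), prec)
  expect_error(presence_filter(prec, min_reps = 4), class = "karma_value_error")
  expect_error(presence_filter(prec, time_points = c(0, 30)),
               class = "karma_value_error")
  # idempotence
  once <- presence_filter(prec, min_reps = 1)
  expect_identical(presence_filter(once, min_reps = 1), once)
})

test_that("fractional labeling follows H/(H+L) with the degenerate case", {
  expect_equal(fractional_labeling(3, 1), 0.75)
  expect_equal(fractional_labeling(0, 5), 0)
  expect_true(is.na(fractional_labeling(0, 0)))
  expect_error(fractional_labeling(-1, 1), class = "karma_value_error")
})

test_that("RMSE pruning reproduces the hand-computed example", {
  # 4 precursors x 2 post-labeling samples; pass-1 medians, per-precursor
  # RMSEs and the discarded pair were verified by hand before freezing
  fls <- list(p1 = c(0.2, 0.4), p2 = c(0.3, 0.5), p3 = c(0.8, 0.9),
              p4 = c(0.25, 0.45))
  prec <- purrr::map_dfr(names(fls), function(p) {
    tibble::tibble(
      bait_id = "B1", condition = "none", replicate = 1L,
      time_min = c(30, 60), protein_id = "P1", precursor_id = p,
      H = fls[[p]] * 100, L = (1 - fls[[p]]) * 100, FL = fls[[p]]
    )
  })
  prof <- protein_labeling(prec, discard_fraction = 0.5)
  expect_equal(prof$FL[prof$time_min == 30], 0.275)
  expect_equal(prof$FL[prof$time_min == 60], 0.475)
  pruning <- pruning_report(prof)
  expect_setequal(pruning$precursor_id[pruning$discarded], c("p1", "p3"))
  expect_equal(pruning$rmse[pruning$precursor_id == "p3"],
               sqrt(mean(c(0.8 - 0.275, 0.9 - 0.475)^2)))
  expect_equal(pruning$rmse[pruning$precursor_id == "p2"], 0.025)
})

test_that("pruning count uses the floor rule and RMSE-zero invariance", {
  one <- tibble::tibble(
    bait_id = "B1", condition = "none", replicate = 1L, time_min = c(30, 60),
    protein_id = "P1", precursor_id = "p1", H = c(30, 60), L = c(70, 40),
    FL = c(0.3, 0.6)
  )
  prof <- protein_labeling(one, discard_fraction = 0.5)
  expect_equal(prof$FL, c(0.3, 0.6))   # floor(1 * 0.5) = 0 discarded

  same <- purrr::map_dfr(c("a", "b", "c"), function(p) {
    dplyr::mutate(one, precursor_id = p)
  })
  prof2 <- protein_labeling(same, discard_fraction = 0.5)
  expect_equal(prof2$FL, c(0.3, 0.6))  # identical trajectories survive pruning
  expect_error(protein_labeling(same, discard_fraction = 1),
               class = "karma_value_error")
})

test_that("bait normalization divides by the bait trajectory", {
  prof <- purrr::map_dfr(
    list(c("NUP1", 0.25), c("BAIT", 0.5)),
    function(x) tibble::tibble(
      protein_id = x[1], bait_id = "B1", condition = "none",
      replicate = 1:3, time_min = 30, FL = as.numeric(x[2]),
      n_precursors = 3L
    )
  )
  out <- normalize_to_bait(prof, "BAIT")
  expect_equal(out$FL_norm[out$protein_id == "NUP1"], 0.5)
  expect_equal(out$FL_norm[out$protein_id == "BAIT"], 1)

  # missing bait value propagates as missing, with a warning
  prof2 <- dplyr::bind_rows(
    prof,
    tibble::tibble(protein_id = c("NUP1", "BAIT"), bait_id = "B1",
                   condition = "none", replicate = 1L, time_min = 60,
                   FL = c(0.4, NA), n_precursors = c(3L, 0L))
  )
  expect_warning(out2 <- normalize_to_bait(prof2, "BAIT"))
  expect_true(is.na(out2$FL_norm[out2$protein_id == "NUP1" &
                                   out2$time_min == 60]))
  expect_error(normalize_to_bait(prof, "ABSENT"), class = "karma_value_error")
})

test_that("treatment ratios pair replicates and report SEM", {
  mk <- function(fl, cond) {
    tidyr::expand_grid(replicate = 1:3, time_min = c(30, 60, 90)) %>%
      dplyr::mutate(protein_id = "P1", bait_id = "B1", condition = cond,
                    FL = fl, n_precursors = 3L)
  }
  same <- treatment_ratio(mk(0.4, "treated"), mk(0.4, "control"))
  expect_equal(same$mean_ratio, 1)
  expect_equal(same$sem, 0)
  expect_equal(same$n_pairs, 9L)

  one_pair <- treatment_ratio(
    mk(0.2, "treated")[1, ], mk(0.4, "control")[1, ])
  expect_equal(one_pair$mean_ratio, 0.5)
  expect_true(is.na(one_pair$sem))

  # known ratio 0.7 with noise: recovered within 3 SEM
  set.seed(42)
  tr <- mk(0.7 * 0.4 * exp(rnorm(9, 0, 0.05)), "treated")
  ct <- mk(0.4, "control")
  est <- treatment_ratio(tr, ct)
  expect_lt(abs(est$mean_ratio - 0.7), 3 * est$sem + 0.02)
})

test_that("noiseless simulator output reproduces the truth end to end", {
  d <- design_noiseless()
  sim <- simulate_karma_dataset(d, seed = 2)
  prof <- quantify_labeling(sim$records)
  chk <- dplyr::left_join(prof, truth_table(sim$truth, d$time_grid_min),
                          by = c("protein_id", "time_min"))
  expect_lt(max(abs(chk$FL - chk$FL_true)), 1e-12)
  # monotone in time for every protein and replicate
  mono <- prof %>%
    dplyr::arrange(protein_id, replicate, time_min) %>%
    dplyr::group_by(protein_id, replicate) %>%
    dplyr::summarise(ok = all(diff(FL) >= -1e-12), .groups = "drop")
  expect_true(all(mono$ok))
  # all reported values are proper fractions
  expect_true(all(prof$FL >= 0 & prof$FL <= 1))
})

test_that("trajectory noise filter removes only high-variance proteins", {
  d <- design_noisy()
  sim <- simulate_karma_dataset(d, seed = 9)
  prof <- quantify_labeling(sim$records)
  expect_identical(trajectory_noise_filter(prof)$protein_id, prof$protein_id)
  strict <- suppressMessages(trajectory_noise_filter(prof, 1e-6))
  expect_lt(dplyr::n_distinct(strict$protein_id),
            dplyr::n_distinct(prof$protein_id) + 1)
  expect_equal(attr(strict, "n_removed") +
                 dplyr::n_distinct(strict$protein_id),
               dplyr::n_distinct(prof$protein_id))
})

test_that("cascade equals the brute-force oracle on random small instances", {
  for (s in 1:12) {
    rec <- random_instance(s)
    oracle <- oracle_quantify(rec)
    pkg <- tryCatch(quantify_labeling(rec), error = function(e) NULL)
    if (is.null(oracle)) {
      expect_true(is.null(pkg) || nrow(pkg) == 0)
    } else {
      expect_false(is.null(pkg))
      expect_identical(pkg$protein_id, oracle$protein_id)
      expect_identical(pkg$FL, oracle$FL)
    }
  }
})
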