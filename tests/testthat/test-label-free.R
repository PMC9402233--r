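lf_prec <- function(bait, rep, values, prot = "P1") {
  tibble::tibble(
    bait_id = bait, condition = "none", replicate = rep, time_min = 0,
    protein_id = prot,
    precursor_id = sprintf("%s_q%02d/2", prot, seq_along(values)),
    intensity = values
  )
}

test_that("median normalization equalizes sample medians on the grand median", {
  prec <- dplyr::bind_rows(
    lf_prec("A", 1L, c(5, 10, 40)),     # median 10
    lf_prec("B", 1L, c(10, 20, 80))     # median 20
  )
  out <- median_normalize(prec)
  med <- out %>% dplyr::group_by(bait_id) %>%
    dplyr::summarise(m = median(intensity))
  expect_equal(med$m, c(15, 15))        # grand median of {10, 20} is 15
  expect_equal(out$intensity[out$bait_id == "A"], c(5, 10, 40) * 1.5)
  expect_equal(out$intensity[out$bait_id == "B"], c(10, 20, 80) * 0.75)

  # single sample: identity; constant data: unchanged
  one <- median_normalize(lf_prec("A", 1L, c(2, 4, 8)))
  expect_equal(one$intensity, c(2, 4, 8))
  flat <- median_normalize(dplyr::bind_rows(lf_prec("A", 1L, rep(7, 3)),
                                            lf_prec("B", 1L, rep(7, 3))))
  expect_equal(flat$intensity, rep(7, 6))

  # scale equivariance: scaling a sample by c leaves normalized values
  # unchanged (three samples so the grand median is anchored elsewhere)
  prec3 <- dplyr::bind_rows(prec, lf_prec("C", 1L, c(20, 40, 160)))
  base3 <- median_normalize(prec3)
  scaled <- prec3 %>%
    dplyr::mutate(intensity = ifelse(bait_id == "C", intensity * 37, intensity))
  expect_equal(median_normalize(scaled)$intensity, base3$intensity)

  empty <- dplyr::mutate(lf_prec("A", 1L, c(0, 0, 0)))
  expect_error(median_normalize(empty), class = "karma_value_error")
})

test_that("top-3 protein intensity averages the three largest precursors", {
  abund <- top3_protein_intensity(lf_prec("A", 1L, c(10, 5, 3, 1)),
                                  complete_in = "none")
  expect_equal(abund$intensity, 6)
  expect_equal(abund$n_precursors, 4L)

  exact3 <- top3_protein_intensity(lf_prec("A", 1L, c(9, 6, 3)),
                                   complete_in = "none")
  expect_equal(exact3$intensity, 6)

  # fewer than min_precursors detected: excluded
  few <- top3_protein_intensity(lf_prec("A", 1L, c(9, 6)),
                                complete_in = "none")
  expect_equal(nrow(few), 0)
})

test_that("replicate-completeness filter drops inconsistent precursors", {
  prec <- dplyr::bind_rows(
    lf_prec("A", 1L, c(10, 8, 6, 4)),
    lf_prec("A", 2L, c(10, 8, 6, 0))    # 4th precursor missing in rep 2
  )
  out <- top3_protein_intensity(prec, complete_in = "per_bait")
  expect_equal(unique(out$n_precursors), 3L)
})

test_that("tier enrichment reproduces the worked fold example", {
  abund <- purrr::map_dfr(
    list(c("E1", 1000), c("E2", 800), c("E3", 1200), c("E4", 900),
         c("L1", 190)),
    function(x) tibble::tibble(
      protein_id = "P1", bait_id = x[1], condition = "none", replicate = 1L,
      time_min = 0, intensity = as.numeric(x[2]), n_precursors = 3L
    )
  )
  tiers <- c(E1 = "early", E2 = "early", E3 = "early", E4 = "early",
             L1 = "late")
  sc <- tier_enrichment(abund, tiers)
  expect_equal(sc$fold, 950 / 190)      # median(1000,800,1200,900) / 190
  expect_equal(sc$fold, 5)

  # identical abundance everywhere: fold 1
  flat <- dplyr::mutate(abund, intensity = 500)
  expect_equal(tier_enrichment(flat, tiers)$fold, 1)

  # swapping tiers inverts the fold
  swapped <- c(E1 = "late", E2 = "late", E3 = "late", E4 = "late",
               L1 = "early")
  expect_equal(tier_enrichment(abund, swapped)$fold, 1 / 5)

  # absent from all late baits: +Inf sentinel with flag
  no_late <- dplyr::filter(abund, bait_id != "L1")
  expect_error(tier_enrichment(abund, tiers[1:4]),
               class = "karma_value_error")   # map without any late tier
  expect_error(tier_enrichment(abund, tiers[2:5]),
               class = "karma_value_error")   # map not covering bait E1
  sc3 <- tier_enrichment(dplyr::bind_rows(
    no_late,
    dplyr::mutate(abund[5, ], protein_id = "P2")
  ), tiers)
  expect_true(is.infinite(sc3$fold[sc3$protein_id == "P1"]))
  expect_equal(sc3$flag[sc3$protein_id == "P1"], "absent_in_late")

  # exclusion list flags but keeps proteins
  sc4 <- tier_enrichment(abund, tiers, exclude_ids = "P1")
  expect_true(sc4$excluded)
})

test_that("tier enrichment matches a brute-force recomputation", {
  set.seed(7)
  abund <- tidyr::expand_grid(
    protein_id = sprintf("P%d", 1:5),
    bait_id = c("E1", "E2", "L1", "L2", "M1"),
    replicate = 1:3
  ) %>%
    dplyr::mutate(condition = "none", time_min = 0,
                  intensity = round(stats::runif(dplyr::n(), 10, 1000), 3),
                  n_precursors = 3L)
  tiers <- c(E1 = "early", E2 = "early", L1 = "late", L2 = "late",
             M1 = "intermediate")
  sc <- tier_enrichment(abund, tiers)
  for (p in unique(abund$protein_id)) {
    bm <- sapply(c("E1", "E2", "L1", "L2"), function(b) {
      median(abund$intensity[abund$protein_id == p & abund$bait_id == b])
    })
    fold <- median(bm[1:2]) / median(bm[3:4])
    expect_equal(sc$fold[sc$protein_id == p], fold)
  }
})

test_that("simulated assembly factor enrichment is recovered", {
  baits <- c(E1 = "early", E2 = "early", M1 = "intermediate", L1 = "late")
  # noiseless: exact
  lf0 <- simulate_labelfree_dataset(design_noiseless(baits = baits),
                                    early_late_factor = 5, seed = 1)
  sc0 <- label_free_enrichment(lf0$records, baits)
  expect_equal(sc0$fold[sc0$protein_id == "ASSEMBLY_FACTOR_01"], 5)
  expect_equal(unique(sc0$fold[sc0$protein_id != "ASSEMBLY_FACTOR_01"]), 1)

  # null effect: all folds 1
  lf1 <- simulate_labelfree_dataset(design_noiseless(baits = baits),
                                    early_late_factor = 1, seed = 1)
  sc1 <- label_free_enrichment(lf1$records, baits)
  expect_equal(unique(sc1$fold), 1)
})
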