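#' Precursor intensities for label-free quantification
#'
#' Builds the precursor table the label-free analysis starts from: quality-
#' flagged fragments are dropped, only proteotypic precursors are kept, and
#' the remaining fragment intensities are summed per precursor and sample.
#' Unlike the pulse-labeling cascade there is no y-type / single-lysine
#' restriction and a single channel is quantified.
#'
#' @param records Single-channel fragment records.
#' @param channel Channel to quantify (default `"light"`).
#' @return Tibble: sample columns, `protein_id`, `precursor_id`,
#'   `intensity`.
#' @export
lf_precursor_intensities <- function(records, channel = "light") {
  records %>%
    filter(!.data$excluded_flag, .data$is_proteotypic,
           .data$channel == .env$channel) %>%
    group_by(across(all_of(c(sample_cols(), "protein_id", "precursor_id")))) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop")
}

#' Median-normalize precursor intensities across samples
#'
#' Divides every intensity by its sample's median over detected precursors
#' and rescales by the grand median of the sample medians, so that after the
#' transform all sample medians are equal while the data keep their original
#' intensity scale. Scale equivariant: multiplying one sample by a constant
#' leaves the normalized values unchanged.
#'
#' @param precursors Output of [lf_precursor_intensities()].
#' @return Same shape with normalized `intensity`.
#' @export
median_normalize <- function(precursors) {
  med <- precursors %>%
    group_by(across(all_of(sample_cols()))) %>%
    summarise(
      sample_median = median(.data$intensity[.data$intensity > 0]),
      .groups = "drop"
    )
  if (any(!is.finite(med$sample_median))) {
    abort("a sample has no detected precursors", class = "karma_value_error")
  }
  grand <- median(med$sample_median)
  precursors %>%
    left_join(med, by = sample_cols()) %>%
    mutate(intensity = .data$intensity / .data$sample_median * grand) %>%
    select(-"sample_median")
}

#' Top-3 protein intensity
#'
#' Protein abundance per sample as the average of its 3 most intense
#' detected precursor ions. Precursors not found in all biological
#' replicates of a bait are omitted beforehand (set
#' `complete_in = "all_baits"` for the stricter multi-bait variant requiring
#' detection in all replicates of every bait). Proteins characterized by
#' fewer than `min_precursors` detected precursors in a sample get no value
#' there; proteins below the threshold everywhere are excluded.
#'
#' @param precursors Normalized precursor tibble.
#' @param min_precursors Minimum detected precursors per sample (default 3).
#' @param complete_in Replicate-completeness scope: `"per_bait"` (default),
#'   `"all_baits"`, or `"none"` to skip the completeness filter.
#' @return Tibble: `protein_id`, sample columns, `intensity`,
#'   `n_precursors`.
#' @export
top3_protein_intensity <- function(precursors, min_precursors = 3L,
                                   complete_in = c("per_bait", "all_baits", "none")) {
  complete_in <- match.arg(complete_in)
  det <- precursors %>% filter(.data$intensity > 0)
  if (complete_in != "none") {
    n_expected <- det %>%
      distinct(.data$bait_id, .data$replicate) %>%
      dplyr::count(.data$bait_id, name = "n_rep")
    per_bait <- det %>%
      distinct(.data$protein_id, .data$precursor_id, .data$bait_id,
               .data$replicate) %>%
      dplyr::count(.data$protein_id, .data$precursor_id, .data$bait_id,
                   name = "n_seen") %>%
      left_join(n_expected, by = "bait_id")
    keep <- if (complete_in == "per_bait") {
      per_bait %>% filter(.data$n_seen == .data$n_rep) %>%
        distinct(.data$protein_id, .data$precursor_id, .data$bait_id)
    } else {
      per_bait %>%
        group_by(.data$protein_id, .data$precursor_id) %>%
        summarise(
          ok = all(.data$n_seen == .data$n_rep) &&
            n() == nrow(n_expected),
          .groups = "drop"
        ) %>%
        filter(.data$ok) %>%
        select("protein_id", "precursor_id")
      }
    by_cols <- if (complete_in == "per_bait") {
      c("protein_id", "precursor_id", "bait_id")
    } else c("protein_id", "precursor_id")
    det <- det %>% dplyr::semi_join(keep, by = by_cols)
  }
  out <- det %>%
    group_by(across(all_of(c("protein_id", sample_cols())))) %>%
    summarise(
      n_precursors = n(),
      intensity = mean(sort(.data$intensity, decreasing = TRUE)[
        seq_len(min(3L, n()))]),
      .groups = "drop"
    ) %>%
    filter(.data$n_precursors >= min_precursors)
  out
}

#' Early-versus-late assembly-tier enrichment
#'
#' The screen statistic for transient assembly factors: per protein, the
#' replicate-median intensity is taken for each bait, then the fold
#' difference between the median over early-tier baits and the median over
#' late-tier baits. A protein much more abundant in pulldowns of early-tier
#' baits than late-tier baits behaves like a factor that leaves the complex
#' as it matures.
#'
#' @param abundances [top3_protein_intensity()] output.
#' @param tier_map Named character vector or two-column data frame
#'   (`bait_id`, `tier`) assigning each bait to
#'   `early` / `intermediate` / `late`.
#' @param exclude_ids Protein ids to flag as excluded from ranking (e.g.
#'   known complex members and transport receptors when screening for new
#'   factors); they stay in the output with `excluded = TRUE`.
#' @return Tibble: `protein_id`, `early_median`, `late_median`, `fold`
#'   (`Inf` with `flag = "absent_in_late"` when undetected in all late
#'   baits), `excluded`.
#' @export
tier_enrichment <- function(abundances, tier_map, exclude_ids = character()) {
  if (is.data.frame(tier_map)) {
    tier_map <- setNames(tier_map$tier, tier_map$bait_id)
  }
  baits <- unique(abundances$bait_id)
  uncovered <- setdiff(baits, names(tier_map))
  if (length(uncovered)) {
    abort(paste0("tier map does not cover bait(s): ",
                 paste(uncovered, collapse = ", ")),
          class = "karma_value_error")
  }
  if (!any(tier_map == "early") || !any(tier_map == "late")) {
    abort("tier map needs at least one early and one late bait",
          class = "karma_value_error")
  }
  per_bait <- abundances %>%
    group_by(.data$protein_id, .data$bait_id) %>%
    summarise(bait_median = median(.data$intensity), .groups = "drop") %>%
    mutate(tier = unname(tier_map[.data$bait_id]))
  per_tier <- per_bait %>%
    filter(.data$tier %in% c("early", "late")) %>%
    group_by(.data$protein_id, .data$tier) %>%
    summarise(tier_median = median(.data$bait_median), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "tier", values_from = "tier_median")
  if (!"early" %in% names(per_tier)) per_tier$early <- NA_real_
  if (!"late" %in% names(per_tier)) per_tier$late <- NA_real_
  per_tier %>%
    mutate(
      early_median = .data$early,
      late_median = .data$late,
      fold = dplyr::case_when(
        is.finite(.data$early) & is.finite(.data$late) & .data$late > 0 ~
          .data$early / .data$late,
        is.finite(.data$early) & !is.finite(.data$late) ~ Inf,
        TRUE ~ NA_real_
      ),
      flag = dplyr::case_when(
        is.finite(.data$early) & !is.finite(.data$late) ~ "absent_in_late",
        TRUE ~ "ok"
      ),
      excluded = .data$protein_id %in% exclude_ids
    ) %>%
    select("protein_id", "early_median", "late_median", "fold", "flag",
           "excluded") %>%
    arrange(dplyr::desc(.data$fold))
}

#' Full label-free tier-enrichment analysis
#'
#' Chains [lf_precursor_intensities()], [median_normalize()],
#' [top3_protein_intensity()] and [tier_enrichment()].
#'
#' @param records Single-channel fragment records.
#' @param tier_map Bait -> tier assignment.
#' @param min_precursors,complete_in,exclude_ids Passed through.
#' @return [tier_enrichment()] result.
#' @export
label_free_enrichment <- function(records, tier_map, min_precursors = 3L,
                                  complete_in = "per_bait",
                                  exclude_ids = character()) {
  records %>%
    lf_precursor_intensities() %>%
    median_normalize() %>%
    top3_protein_intensity(min_precursors = min_precursors,
                           complete_in = complete_in) %>%
    tier_enrichment(tier_map, exclude_ids = exclude_ids)
}
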