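#' Fragment-level quality filters for labeling quantification
#'
#' Applies the fragment selection used for pulse-labeling quantification:
#' quality-flagged fragments are dropped, then only proteotypic y-type
#' fragment ions with a single lysine residue that were found in both the
#' heavy and the light channel are retained. "Found" means intensity above
#' `detection_threshold`; by default the both-channels criterion is evaluated
#' over the whole experiment (a fragment is kept if it has any detection in
#' each channel in any sample), with `both_channels = "per_sample"` as the
#' stricter alternative that additionally requires detection in both channels
#' within each sample it contributes to.
#'
#' @param records Fragment record tibble from [read_fragment_report()] or the
#'   simulators.
#' @param both_channels `"experiment"` (default) or `"per_sample"`.
#' @param detection_threshold Intensity strictly above this counts as
#'   detected.
#' @return Filtered records; idempotent. Attribute `n_removed` reports the
#'   number of rows dropped.
#' @export
filter_fragments <- function(records, both_channels = c("experiment", "per_sample"),
                             detection_threshold = 0) {
  both_channels <- match.arg(both_channels)
  n0 <- nrow(records)
  out <- records %>%
    filter(!.data$excluded_flag,
           .data$is_proteotypic,
           .data$fragment_series == "y",
           .data$lysine_count == 1L)
  frag_key <- c("protein_id", "precursor_id", fragment_cols())
  chan_seen <- out %>%
    filter(.data$intensity > detection_threshold) %>%
    distinct(across(all_of(c(frag_key, "channel")))) %>%
    dplyr::count(across(all_of(frag_key)), name = "n_channels") %>%
    filter(.data$n_channels == 2L)
  out <- out %>% dplyr::semi_join(chan_seen, by = frag_key)
  if (both_channels == "per_sample") {
    per_sample <- out %>%
      filter(.data$intensity > detection_threshold) %>%
      distinct(across(all_of(c(frag_key, sample_cols(), "channel")))) %>%
      dplyr::count(across(all_of(c(frag_key, sample_cols()))),
                   name = "n_channels") %>%
      filter(.data$n_channels == 2L)
    out <- out %>% dplyr::semi_join(per_sample, by = c(frag_key, sample_cols()))
  }
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Aggregate fragment intensities to precursor heavy/light intensities
#'
#' Per precursor, sample and channel, sums the retained fragment intensities
#' (`sum_all`, the pulse-labeling default) or the 3 most intense fragments in
#' that channel (`top3`, the targeted-acquisition convention). Undetected
#' fragments contribute 0. The precursor x sample grid is completed over all
#' samples present in the input, so precursors undetected in a sample appear
#' with `H = L = 0` and missing fractional labeling.
#'
#' @param records Fragment-filtered records.
#' @param aggregation `"sum_all"` or `"top3"`.
#' @return Precursor tibble: sample columns, `protein_id`, `precursor_id`,
#'   `H`, `L`, `FL` (`NA` where `H + L == 0`).
#' @export
aggregate_precursors <- function(records, aggregation = c("sum_all", "top3")) {
  aggregation <- match.arg(aggregation)
  agg_fun <- if (aggregation == "sum_all") {
    function(x) sum(x)
  } else {
    function(x) sum(sort(x, decreasing = TRUE)[seq_len(min(3L, length(x)))])
  }
  per_chan <- records %>%
    group_by(across(all_of(c(sample_cols(), "protein_id", "precursor_id",
                             "channel")))) %>%
    summarise(intensity = agg_fun(.data$intensity), .groups = "drop")
  wide <- per_chan %>%
    tidyr::pivot_wider(names_from = "channel", values_from = "intensity",
                       values_fill = 0)
  if (!"heavy" %in% names(wide)) wide$heavy <- 0
  if (!"light" %in% names(wide)) wide$light <- 0
  samples <- records %>% distinct(across(all_of(sample_cols())))
  precursors <- records %>% distinct(.data$protein_id, .data$precursor_id)
  tidyr::expand_grid(samples, precursors) %>%
    left_join(wide, by = c(sample_cols(), "protein_id", "precursor_id")) %>%
    mutate(
      H = dplyr::coalesce(.data$heavy, 0),
      L = dplyr::coalesce(.data$light, 0),
      FL = fractional_labeling(.data$H, .data$L)
    ) %>%
    select(all_of(sample_cols()), "protein_id", "precursor_id", "H", "L", "FL") %>%
    arrange(.data$protein_id, .data$precursor_id, .data$bait_id,
            .data$condition, .data$replicate, .data$time_min)
}

#' Replicate presence filter for precursors
#'
#' Drops unreliable precursors: a precursor is retained only if it is
#' detected (`H + L > 0`) in at least `min_reps` biological replicates at
#' *every* post-labeling time point. The default `min_reps = 2` ("fewer than
#' two out of three replicates in any post-labeling time point" removes it)
#' matches standard pulldown runs; the relaxed `min_reps = 1` variant is used
#' for degron time courses where coverage is sparser. Time-0 samples are
#' never part of the criterion. Retention is decided independently within
#' each bait x condition series.
#'
#' @param precursors Output of [aggregate_precursors()].
#' @param min_reps Minimum detected replicates per time point (0 = identity).
#' @param time_points Post-labeling time points to check; defaults to all
#'   `time_min > 0` in the data. Must not contain 0.
#' @return Filtered precursor tibble; idempotent.
#' @export
presence_filter <- function(precursors, min_reps = 2L, time_points = NULL) {
  time_points <- time_points %||%
    sort(unique(precursors$time_min[precursors$time_min > 0]))
  if (any(time_points <= 0)) {
    abort("time_points must be post-labeling (t > 0)", class = "karma_value_error")
  }
  if (min_reps < 0) abort("min_reps must be >= 0", class = "karma_value_error")
  n_reps <- length(unique(precursors$replicate))
  if (min_reps > n_reps) {
    abort(paste0("min_reps (", min_reps, ") exceeds the replicate count (",
                 n_reps, ")"), class = "karma_value_error")
  }
  if (min_reps == 0) return(precursors)
  keep <- precursors %>%
    filter(.data$time_min %in% time_points) %>%
    group_by(.data$bait_id, .data$condition, .data$protein_id,
             .data$precursor_id, .data$time_min) %>%
    summarise(n_det = sum(.data$H + .data$L > 0), .groups = "drop") %>%
    group_by(.data$bait_id, .data$condition, .data$protein_id,
             .data$precursor_id) %>%
    summarise(
      ok = all(.data$n_det >= min_reps) &&
        length(unique(.data$time_min)) == length(time_points),
      .groups = "drop"
    ) %>%
    filter(.data$ok)
  precursors %>%
    dplyr::semi_join(keep, by = c("bait_id", "condition", "protein_id",
                                  "precursor_id"))
}

#' Protein fractional labeling with RMSE-based precursor pruning
#'
#' Two-pass summary of precursor labeling into a per-protein trajectory.
#' Pass 1 computes, within each sample, the median fractional labeling over
#' all precursors of the protein. Each precursor is then scored by the root
#' mean square error of its labeling values against those sample medians,
#' over the post-labeling samples where it has a value (no imputation).
#' Per protein, the `floor(n x discard_fraction)` precursors with the highest
#' RMSE are discarded (ties broken by retaining the more intense precursor,
#' then by id), and the final per-sample protein labeling is the median over
#' the surviving precursors.
#'
#' @param precursors Precursor tibble (may contain several proteins; the
#'   procedure is applied per protein).
#' @param discard_fraction Share of precursors to prune, in `[0, 1)`
#'   (default 0.5: the half with the highest RMSEs).
#' @return Tibble with `protein_id`, sample columns, `FL` and
#'   `n_precursors` (contributing count per sample). The pruning record
#'   (per-precursor RMSE and whether it was discarded) is attached as
#'   attribute `pruning` and via [pruning_report()].
#' @export
protein_labeling <- function(precursors, discard_fraction = 0.5) {
  if (discard_fraction < 0 || discard_fraction >= 1) {
    abort("discard_fraction must lie in [0, 1)", class = "karma_value_error")
  }
  if (nrow(precursors) == 0) {
    abort("need at least one precursor", class = "karma_value_error")
  }
  pass1 <- precursors %>%
    group_by(across(all_of(c("protein_id", sample_cols())))) %>%
    summarise(sample_median = median(.data$FL, na.rm = TRUE), .groups = "drop")

  rmse_tbl <- precursors %>%
    left_join(pass1, by = c("protein_id", sample_cols())) %>%
    filter(.data$time_min > 0) %>%
    group_by(.data$protein_id, .data$precursor_id) %>%
    summarise(
      rmse = {
        d <- .data$FL - .data$sample_median
        d <- d[is.finite(d)]
        if (length(d) == 0) Inf else sqrt(mean(d^2))
      },
      total_intensity = sum(.data$H + .data$L, na.rm = TRUE),
      .groups = "drop"
    )

  pruned <- rmse_tbl %>%
    group_by(.data$protein_id) %>%
    arrange(dplyr::desc(.data$rmse), .data$total_intensity,
            dplyr::desc(.data$precursor_id), .by_group = TRUE) %>%
    mutate(discarded = row_number() <= floor(n() * discard_fraction)) %>%
    ungroup()

  survivors <- pruned %>% filter(!.data$discarded) %>%
    select("protein_id", "precursor_id")

  profile <- precursors %>%
    dplyr::semi_join(survivors, by = c("protein_id", "precursor_id")) %>%
    group_by(across(all_of(c("protein_id", sample_cols())))) %>%
    summarise(
      n_precursors = sum(is.finite(.data$FL)),
      FL = median(.data$FL, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(FL = if_else(is.nan(.data$FL), NA_real_, .data$FL)) %>%
    arrange(.data$protein_id, .data$bait_id, .data$condition,
            .data$replicate, .data$time_min)
  attr(profile, "pruning") <- pruned %>%
    select("protein_id", "precursor_id", "rmse", "discarded")
  profile
}

#' @rdname protein_labeling
#' @param profile A [protein_labeling()] result.
#' @export
pruning_report <- function(profile) attr(profile, "pruning")

#' Optional automated trajectory-noise filter
#'
#' Replaces manual curation of noisy labeling trajectories with an explicit
#' rule: a protein is dropped when its maximum within-time-point replicate
#' standard deviation of FL exceeds `max_replicate_sd`. Off unless a finite
#' threshold is supplied; removals are reported via a message and the
#' `n_removed` attribute.
#'
#' @param profile A [protein_labeling()] result.
#' @param max_replicate_sd Threshold on the replicate SD of FL (post-labeling
#'   time points); `Inf` disables the filter.
#' @return Filtered profile.
#' @export
trajectory_noise_filter <- function(profile, max_replicate_sd = Inf) {
  if (!is.finite(max_replicate_sd)) {
    attr(profile, "n_removed") <- 0L
    return(profile)
  }
  noisy <- profile %>%
    filter(.data$time_min > 0) %>%
    group_by(.data$protein_id, .data$bait_id, .data$condition,
             .data$time_min) %>%
    summarise(rep_sd = sd(.data$FL, na.rm = TRUE), .groups = "drop") %>%
    group_by(.data$protein_id) %>%
    summarise(max_sd = max(.data$rep_sd, na.rm = TRUE), .groups = "drop") %>%
    filter(.data$max_sd > max_replicate_sd)
  if (nrow(noisy)) {
    message("trajectory_noise_filter: removed ", nrow(noisy),
            " protein(s) with replicate SD > ", max_replicate_sd)
  }
  out <- profile %>% anti_join(noisy, by = "protein_id")
  attr(out, "n_removed") <- nrow(noisy)
  attr(out, "pruning") <- attr(profile, "pruning")
  out
}

#' Normalize protein labeling to the bait
#'
#' Aggregates replicates by the median per protein, condition and time
#' point, then divides every protein's labeling by the bait protein's
#' labeling in the same condition and time point. Samples where the bait has
#' missing or zero labeling yield missing normalized values (with a
#' warning).
#'
#' @param profile A [protein_labeling()] result.
#' @param bait_protein Protein id of the bait.
#' @return Tibble `protein_id`, `bait_id`, `condition`, `time_min`, `FL`
#'   (replicate median), `FL_norm`.
#' @export
normalize_to_bait <- function(profile, bait_protein) {
  if (!bait_protein %in% profile$protein_id) {
    abort(paste0("bait protein '", bait_protein, "' not found in profile"),
          class = "karma_value_error")
  }
  condensed <- profile %>%
    group_by(.data$protein_id, .data$bait_id, .data$condition,
             .data$time_min) %>%
    summarise(FL = median(.data$FL, na.rm = TRUE), .groups = "drop") %>%
    mutate(FL = if_else(is.nan(.data$FL), NA_real_, .data$FL))
  bait_fl <- condensed %>%
    filter(.data$protein_id == bait_protein) %>%
    select("bait_id", "condition", "time_min", bait_FL = "FL")
  out <- condensed %>%
    left_join(bait_fl, by = c("bait_id", "condition", "time_min")) %>%
    mutate(FL_norm = if_else(
      is.finite(.data$bait_FL) & .data$bait_FL > 0,
      .data$FL / .data$bait_FL, NA_real_
    ))
  n_bad <- sum(!(is.finite(out$bait_FL) & out$bait_FL > 0) &
                 is.finite(out$FL) & out$time_min > 0)
  if (n_bad > 0) {
    warn(paste0("bait labeling missing or zero for ", n_bad,
                " profile value(s); normalized values set to missing"))
  }
  out %>% select("protein_id", "bait_id", "condition", "time_min",
                 "FL", "FL_norm")
}

#' Treated / control labeling ratio per protein
#'
#' Pairs treated and control labeling by replicate and post-labeling time
#' point, computes the per-pair ratio, and summarises per protein as
#' mean +/- SEM over the available pairs. Pairs with zero control labeling
#' are dropped with a warning; `SEM` is missing when only one pair remains.
#'
#' @param profile_treated,profile_control [protein_labeling()] results for
#'   the two arms.
#' @return Tibble `protein_id`, `mean_ratio`, `sem`, `n_pairs`.
#' @export
treatment_ratio <- function(profile_treated, profile_control) {
  key <- c("protein_id", "bait_id", "replicate", "time_min")
  pairs <- profile_treated %>%
    filter(.data$time_min > 0) %>%
    select(all_of(key), FL_treated = "FL") %>%
    inner_join(
      profile_control %>%
        filter(.data$time_min > 0) %>%
        select(all_of(key), FL_control = "FL"),
      by = key
    ) %>%
    filter(is.finite(.data$FL_treated), is.finite(.data$FL_control))
  n_zero <- sum(pairs$FL_control == 0)
  if (n_zero > 0) {
    warn(paste0(n_zero, " pair(s) with zero control labeling dropped"))
    pairs <- pairs %>% filter(.data$FL_control > 0)
  }
  pairs %>%
    mutate(ratio = .data$FL_treated / .data$FL_control) %>%
    group_by(.data$protein_id) %>%
    summarise(
      mean_ratio = mean(.data$ratio),
      sem = if (n() > 1) sd(.data$ratio) / sqrt(n()) else NA_real_,
      n_pairs = n(),
      .groups = "drop"
    )
}

#' Run the full labeling-quantification cascade
#'
#' Convenience wrapper: fragment filters, precursor aggregation, replicate
#' presence filter, and protein labeling with RMSE pruning, with the stage
#' counts recorded in the `stages` attribute.
#'
#' @param records Fragment records.
#' @param min_reps,discard_fraction,aggregation,both_channels,
#'   detection_threshold,max_replicate_sd Stage parameters (see the
#'   individual functions).
#' @return A [protein_labeling()] profile with attribute `stages`.
#' @export
quantify_labeling <- function(records, min_reps = 2L, discard_fraction = 0.5,
                              aggregation = "sum_all",
                              both_channels = "experiment",
                              detection_threshold = 0,
                              max_replicate_sd = Inf) {
  frag <- filter_fragments(records, both_channels = both_channels,
                           detection_threshold = detection_threshold)
  prec <- aggregate_precursors(frag, aggregation = aggregation)
  kept <- presence_filter(prec, min_reps = min_reps)
  profile <- protein_labeling(kept, discard_fraction = discard_fraction)
  profile <- trajectory_noise_filter(profile, max_replicate_sd)
  attr(profile, "stages") <- tibble(
    stage = c("input_rows", "fragments_retained", "precursors",
              "precursors_after_presence", "proteins"),
    n = c(nrow(records), nrow(frag),
          dplyr::n_distinct(prec$precursor_id),
          dplyr::n_distinct(kept$precursor_id),
          dplyr::n_distinct(profile$protein_id))
  )
  profile
}
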