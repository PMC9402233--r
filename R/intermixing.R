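#' Subunit intermixing extent from a mixed-lysate pulldown
#'
#' Quantifies how much bait-bound subunits exchanged with the untagged
#' (heavy) lysate during affinity purification. The fragment records are run
#' through the labeling-quantification cascade with two extra filters suited
#' to the low labeling extents of this assay: precursor ions with summed
#' heavy + light intensity below `min_intensity` in a sample are treated as
#' undetected there, and only proteins characterized by more than three
#' precursor ions (`>= min_precursors`) are considered. Each subunit's
#' fractional labeling is then normalized to the mean fractional labeling of
#' all co-purified proteins (the fully intermixed reference), giving an
#' extent of 0 for no exchange and ~1 for complete intermixing.
#'
#' @param records Fragment records of one mixed-lysate pulldown sample set.
#' @param subunit_ids Protein ids of the bait-bound subunits of interest.
#' @param min_intensity Per-sample summed H+L detection floor for precursor
#'   ions (default 100 a.u.).
#' @param min_precursors Minimum precursor ions per protein (default 4, i.e.
#'   "more than three").
#' @param discard_fraction RMSE pruning share passed to
#'   [protein_labeling()].
#' @param exclude_from_reference Protein ids excluded from the co-purified
#'   bulk reference in addition to `subunit_ids` (e.g. the bait itself).
#' @return Tibble: `protein_id`, `raw_FL`, `bulk_FL`, `extent`.
#' @export
intermixing_extent <- function(records, subunit_ids, min_intensity = 100,
                               min_precursors = 4L, discard_fraction = 0.5,
                               exclude_from_reference = character()) {
  frag <- filter_fragments(records)
  prec <- aggregate_precursors(frag)
  # low-intensity precursor ions are treated as not detected in that sample
  prec <- prec %>%
    mutate(
      below = .data$H + .data$L < min_intensity,
      H = if_else(.data$below, 0, .data$H),
      L = if_else(.data$below, 0, .data$L),
      FL = fractional_labeling(.data$H, .data$L)
    ) %>%
    select(-"below")
  # only proteins characterized by enough precursor ions (detected anywhere)
  rich <- prec %>%
    filter(.data$H + .data$L > 0) %>%
    distinct(.data$protein_id, .data$precursor_id) %>%
    dplyr::count(.data$protein_id, name = "n_prec") %>%
    filter(.data$n_prec >= min_precursors)
  prec <- prec %>% dplyr::semi_join(rich, by = "protein_id")
  if (nrow(prec) == 0) {
    abort("no protein passes the intermixing filters", class = "karma_value_error")
  }
  profile <- protein_labeling(prec, discard_fraction = discard_fraction)
  per_protein <- profile %>%
    group_by(.data$protein_id) %>%
    summarise(FL = mean(.data$FL[is.finite(.data$FL)]), .groups = "drop")
  bulk <- per_protein %>%
    filter(!.data$protein_id %in% c(subunit_ids, exclude_from_reference),
           is.finite(.data$FL))
  if (nrow(bulk) == 0) {
    abort("no qualifying co-purified bulk proteins for the reference",
          class = "karma_value_error")
  }
  bulk_fl <- mean(bulk$FL)
  if (!is.finite(bulk_fl) || bulk_fl <= 0) {
    abort("bulk reference labeling must be positive", class = "karma_value_error")
  }
  measured <- per_protein %>%
    filter(.data$protein_id %in% subunit_ids) %>%
    mutate(raw_FL = .data$FL, bulk_FL = bulk_fl,
           extent = .data$raw_FL / bulk_fl) %>%
    select("protein_id", "raw_FL", "bulk_FL", "extent")
  # a subunit with no heavy-channel signal at all never passes the
  # both-channels fragment filter; that is the no-exchange case, extent 0
  heavy_sig <- records %>%
    filter(.data$protein_id %in% subunit_ids, .data$channel == "heavy") %>%
    group_by(.data$protein_id) %>%
    summarise(any_heavy = any(.data$intensity > 0), .groups = "drop")
  no_heavy <- heavy_sig$protein_id[!heavy_sig$any_heavy]
  no_heavy <- setdiff(no_heavy, measured$protein_id)
  if (length(no_heavy)) {
    measured <- bind_rows(
      measured,
      tibble(protein_id = no_heavy, raw_FL = 0, bulk_FL = bulk_fl, extent = 0)
    )
  }
  measured %>% arrange(.data$protein_id)
}
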