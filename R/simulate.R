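#' Simulation design for synthetic KARMA datasets
#'
#' Collects the experimental layout the generators emulate: the post-labeling
#' sampling grid (a time-0 sample plus three post-labeling time points, three
#' biological replicates), the baits and their assembly tiers, and the data
#' density per protein. Defaults reproduce the study conditions the analysis
#' functions assume.
#'
#' @param time_grid_min Sampling times in minutes; must include 0.
#' @param replicates Biological replicates per condition (>= 1).
#' @param baits Named character vector, bait id -> assembly tier
#'   (`early`, `intermediate`, `late`).
#' @param proteins_per_class Number of simulated proteins per kinetic class.
#' @param n_precursors Precursors per protein.
#' @param n_fragments Quantifiable y-type fragments per precursor.
#' @param noise_sigma Log-normal intensity noise scale (log-sd; median 1).
#' @param missing_rate Bernoulli missingness probability per
#'   fragment x sample.
#' @param doubling_time_min Culture doubling time driving growth dilution.
#' @return List with class `sim_design`.
#' @export
sim_design <- function(time_grid_min = c(0, 30, 60, 90),
                       replicates = 3L,
                       baits = c(AF1 = "early"),
                       proteins_per_class = 4L,
                       n_precursors = 5L,
                       n_fragments = 6L,
                       noise_sigma = 0.2,
                       missing_rate = 0.05,
                       doubling_time_min = 120) {
  if (!0 %in% time_grid_min) {
    abort("time grid must include the pre-labeling time 0",
          class = "karma_value_error")
  }
  if (replicates < 1) abort("replicates must be >= 1", class = "karma_value_error")
  if (length(baits) < 1 || is.null(names(baits))) {
    abort("baits must be a named vector bait_id -> tier", class = "karma_value_error")
  }
  structure(
    list(time_grid_min = sort(unique(time_grid_min)), replicates = as.integer(replicates),
         baits = baits, proteins_per_class = as.integer(proteins_per_class),
         n_precursors = as.integer(n_precursors), n_fragments = as.integer(n_fragments),
         noise_sigma = noise_sigma, missing_rate = missing_rate,
         doubling_time_min = doubling_time_min),
    class = "sim_design"
  )
}

# Kinetic parameters per protein class, chosen so that in an assembly-factor
# pulldown the noiseless ordering on the sampling grid is
# early > ntr_reference (bulk growth dilution) > intermediate > late,
# mirroring the qualitative labeling pattern of such assays. k_a = Inf marks
# classes labeled purely by growth dilution (bulk behaviour).
class_kinetics <- function(T_d) {
  mu <- log(2) / T_d
  phi2km <- function(phi) mu * phi / (1 - phi)
  tibble(
    class = c("early_nup", "intermediate_nup", "late_nup",
              "ntr_reference", "bulk", "bait"),
    k_a = c(0.2, 0.05, 0.008, Inf, Inf, 0.2),
    k_m = c(phi2km(0.4), phi2km(0.15), 0, 0, 0, phi2km(0.4))
  )
}

#' Ground truth for the synthetic generators
#'
#' One row per simulated protein with its kinetic class, three-state model
#' parameters, steady-state inaccessible-pool fraction `phi`, mean abundance
#' and data-density settings. This is the reference table recovery tests
#' compare against.
#'
#' @param design A [sim_design()].
#' @param classes Kinetic classes to instantiate.
#' @param abundance Mean protein abundance in arbitrary intensity units.
#' @return Tibble (one protein per row).
#' @export
default_ground_truth <- function(design,
                                 classes = c("early_nup", "intermediate_nup",
                                             "late_nup", "ntr_reference", "bulk"),
                                 abundance = 1e5) {
  kin <- class_kinetics(design$doubling_time_min)
  purrr::map_dfr(classes, function(cl) {
    k <- kin[kin$class == cl, ]
    mu <- log(2) / design$doubling_time_min
    tibble(
      protein_id = sprintf("%s_%02d", toupper(cl), seq_len(design$proteins_per_class)),
      class = cl,
      k_a = k$k_a,
      k_m = k$k_m,
      T_d = design$doubling_time_min,
      phi = k$k_m / (k$k_m + mu),
      abundance = abundance,
      n_precursors = design$n_precursors,
      noise_sigma = design$noise_sigma,
      missing_rate = design$missing_rate
    )
  })
}

#' True fractional-labeling curve of a simulated protein
#'
#' Evaluates the ground-truth labeling curve: the three-state model forward
#' solution for finite `k_a`, or pure growth-dilution labeling
#' (`1 - 2^(-t/T_d)` when `k_m = 0`) for bulk-like classes (`k_a = Inf`).
#'
#' @param t Times in minutes.
#' @param k_a,k_m,T_d Kinetic parameters (one protein).
#' @return Fractional labeling at each `t`.
#' @export
truth_labeling_curve <- function(t, k_a, k_m, T_d) {
  if (is.infinite(k_a)) {
    b <- k_m + log(2) / T_d
    return(1 - exp(-b * t))
  }
  ksm_forward(t, ksm_params(k_a, k_m, T_d))
}

# Sample table for one bait/condition over the design grid.
sim_samples <- function(design, bait_id, condition = "none") {
  tidyr::expand_grid(
    bait_id = bait_id, condition = condition,
    replicate = seq_len(design$replicates),
    time_min = design$time_grid_min
  )
}

# Deterministic per-fragment relative intensity ladder within a precursor:
# fragment j carries a fixed share of the precursor's intensity.
fragment_ladder <- function(n) 0.8^(seq_len(n) - 1)

# log-normal factor with median 1 (log-sd sigma); sigma = 0 gives exactly 1.
lnoise <- function(n, sigma) {
  if (sigma <= 0) rep(1, n) else exp(rnorm(n, 0, sigma))
}

# Build the deterministic fragment skeleton for one protein: `n_prec` good
# precursors of `n_frag` proteotypic single-lysine y ions, plus decoy rows
# that the fragment filters must remove (b-series, two-lysine, flagged,
# non-proteotypic, heavy-only). Decoys carry a corrupted labeling value so
# that a missing filter shows up as a wrong result, not a silent pass.
protein_skeleton <- function(protein_id, n_prec, n_frag, decoys = TRUE) {
  good <- tidyr::expand_grid(
    precursor_id = sprintf("%s_pep%02d/2", protein_id, seq_len(n_prec)),
    fragment_index = seq_len(n_frag) + 2L
  ) %>%
    mutate(
      protein_id = protein_id,
      fragment_series = "y", fragment_charge = 1L,
      is_proteotypic = TRUE, excluded_flag = FALSE,
      lysine_count = 1L, missed_cleavages = 0L,
      rel = fragment_ladder(.env$n_frag)[.data$fragment_index - 2L],
      decoy = "none"
    )
  if (!decoys) return(good)
  first_prec <- good$precursor_id[1]
  decoy_rows <- tibble(
    precursor_id = c(first_prec, first_prec, first_prec, first_prec,
                     sprintf("%s_shared01/2", protein_id)),
    fragment_index = c(20L, 21L, 22L, 23L, 3L),
    protein_id = protein_id,
    fragment_series = c("b", "y", "y", "y", "y"),
    fragment_charge = 1L,
    is_proteotypic = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    excluded_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    lysine_count = c(1L, 2L, 1L, 1L, 1L),
    missed_cleavages = c(0L, 1L, 0L, 0L, 0L),
    rel = 0.5,
    decoy = c("b_series", "two_lysine", "flagged", "heavy_only",
              "non_proteotypic")
  )
  bind_rows(good, decoy_rows)
}

# Expand a skeleton over samples into heavy/light fragment records with the
# given true labeling, log-normal channel noise and Bernoulli missingness.
expand_records <- function(skeleton, samples, fl_by_time, abundance,
                           noise_sigma, missing_rate) {
  grid <- tidyr::expand_grid(samples, skeleton)
  fl <- fl_by_time[as.character(grid$time_min)]
  # corrupted labeling for decoy fragments: downstream filters must drop them
  fl <- if_else(grid$decoy == "none", fl, pmin(1, fl * 1.5 + 0.1))
  total <- abundance * grid$rel
  miss <- if (missing_rate > 0) rbinom(nrow(grid), 1, missing_rate) == 1 else
    rep(FALSE, nrow(grid))
  heavy <- total * fl * lnoise(nrow(grid), noise_sigma)
  light <- total * (1 - fl) * lnoise(nrow(grid), noise_sigma)
  # heavy-only decoy: never detected in the light channel, so the
  # both-channels fragment filter must remove it
  light[grid$decoy == "heavy_only"] <- 0
  heavy[grid$decoy == "heavy_only"] <- total[grid$decoy == "heavy_only"]
  light[miss] <- 0
  heavy[miss] <- 0
  long <- bind_rows(
    grid %>% mutate(channel = "heavy", intensity = heavy),
    grid %>% mutate(channel = "light", intensity = light)
  )
  long %>%
    select(all_of(sample_cols()), "protein_id", "is_proteotypic",
           "precursor_id", "fragment_series", "fragment_index",
           "fragment_charge", "channel", "intensity", "excluded_flag",
           "lysine_count", "missed_cleavages") %>%
    arrange(.data$bait_id, .data$condition, .data$replicate, .data$time_min,
            .data$protein_id, .data$precursor_id, .data$fragment_series,
            .data$fragment_index, .data$channel)
}

#' Simulate a pulse-labeling pulldown dataset with known ground truth
#'
#' Generates a fragment-level heavy/light report for one affinity pulldown
#' over the design's time grid and replicates. Each protein follows its
#' ground-truth labeling curve; fragment channel intensities are
#' `total x FL` (heavy) and `total x (1 - FL)` (light) times independent
#' log-normal noise, with Bernoulli missingness per fragment x sample.
#' Decoy fragments (non-proteotypic, b-series, two-lysine, quality-flagged)
#' carrying corrupted labeling are interleaved so that the downstream filter
#' cascade is exercised, not bypassed.
#'
#' @param design A [sim_design()].
#' @param truth Ground-truth tibble ([default_ground_truth()] if `NULL`).
#' @param seed Integer seed; identical seeds give identical record sets.
#' @param bait_id,condition Sample annotations for the simulated pulldown.
#' @return List with `records` (fragment tibble) and `truth`.
#' @export
simulate_karma_dataset <- function(design, truth = NULL, seed = 1,
                                   bait_id = names(design$baits)[1],
                                   condition = "none") {
  stopifnot(inherits(design, "sim_design"))
  truth <- truth %||% default_ground_truth(design)
  if (nrow(truth) == 0) abort("empty design", class = "karma_value_error")
  samples <- sim_samples(design, bait_id, condition)
  records <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      fl <- truth_labeling_curve(design$time_grid_min, tr$k_a, tr$k_m, tr$T_d)
      names(fl) <- as.character(design$time_grid_min)
      skel <- protein_skeleton(tr$protein_id, tr$n_precursors, design$n_fragments)
      expand_records(skel, samples, fl, tr$abundance, tr$noise_sigma,
                     tr$missing_rate)
    })
  })
  list(records = records, truth = truth)
}

#' Simulate a multi-bait label-free abundance dataset
#'
#' Single-channel (light) fragment records across several baits with assembly
#' tiers. Background proteins are equally abundant in every pulldown; an
#' `assembly_factor` protein is enriched in early-tier baits by
#' `early_late_factor` (and by its square root in intermediate-tier baits),
#' the designed effect that [tier_enrichment()] should recover.
#'
#' @param design A [sim_design()] whose `baits` cover at least one early and
#'   one late tier.
#' @param early_late_factor Designed abundance ratio early : late for the
#'   assembly-factor protein.
#' @param n_background Number of background (bulk) proteins.
#' @param seed Integer seed.
#' @param abundance Mean background protein abundance (a.u.).
#' @return List with `records` (single-channel fragment tibble) and `truth`
#'   (protein classes and per-tier abundance multipliers).
#' @export
simulate_labelfree_dataset <- function(design, early_late_factor = 5,
                                       n_background = 20, seed = 1,
                                       abundance = 1e5) {
  stopifnot(inherits(design, "sim_design"))
  tiers <- unname(design$baits)
  if (!"early" %in% tiers || !"late" %in% tiers) {
    abort("tier map must contain at least one early and one late bait",
          class = "karma_value_error")
  }
  if (any(!tiers %in% c("early", "intermediate", "late"))) {
    abort("unknown tier in bait map", class = "karma_value_error")
  }
  tier_mult <- c(early = early_late_factor,
                 intermediate = sqrt(early_late_factor), late = 1)
  proteins <- bind_rows(
    tibble(protein_id = "ASSEMBLY_FACTOR_01", class = "assembly_factor",
           abundance = abundance / 2),
    tibble(protein_id = sprintf("BULK_%02d", seq_len(n_background)),
           class = "bulk", abundance = abundance)
  )
  samples <- purrr::map_dfr(names(design$baits), function(b) {
    tibble(bait_id = b, condition = "none",
           replicate = seq_len(design$replicates), time_min = 0)
  })
  records <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
      pr <- proteins[i, ]
      skel <- protein_skeleton(pr$protein_id, design$n_precursors,
                               design$n_fragments, decoys = FALSE)
      grid <- tidyr::expand_grid(samples, skel)
      mult <- if (pr$class == "assembly_factor") {
        unname(tier_mult[design$baits[grid$bait_id]])
      } else 1
      grid %>%
        mutate(
          channel = "light",
          intensity = pr$abundance * .data$rel * mult *
            lnoise(nrow(grid), design$noise_sigma)
        ) %>%
        select(all_of(sample_cols()), "protein_id", "is_proteotypic",
               "precursor_id", "fragment_series", "fragment_index",
               "fragment_charge", "channel", "intensity", "excluded_flag",
               "lysine_count", "missed_cleavages")
    })
  })
  truth <- proteins %>%
    mutate(designed_fold = if_else(.data$class == "assembly_factor",
                                   early_late_factor, 1))
  list(records = records, truth = truth)
}

#' Simulate a heavy/light lysate-intermixing pulldown
#'
#' Emulates mixing a heavy-grown untagged culture with a light-grown tagged
#' culture before affinity purification. Co-purified bulk proteins come from
#' both lysates and carry fractional labeling equal to the heavy share of the
#' mix; bait-bound subunits originate from the tagged (light) lysate and only
#' acquire heavy label through exchange during purification, so their
#' labeling is `mixing_fraction x heavy_share`.
#'
#' @param design A [sim_design()] (only replicates and density fields used;
#'   the assay is an end point, sampled at one time).
#' @param mixing_fraction Degree of subunit exchange in `[0, 1]`.
#' @param heavy_share Heavy lysate share of the mixture.
#' @param n_subunits,n_bulk Number of bait-bound subunit / co-purified bulk
#'   proteins.
#' @param seed Integer seed.
#' @param abundance Mean protein abundance (a.u.).
#' @return List with `records`, `subunit_ids`, `bait_id` and `truth`.
#' @export
simulate_intermixing_dataset <- function(design, mixing_fraction, seed = 1,
                                         heavy_share = 0.5, n_subunits = 4,
                                         n_bulk = 12, abundance = 1e5) {
  stopifnot(inherits(design, "sim_design"))
  if (mixing_fraction < 0 || mixing_fraction > 1) {
    abort("mixing_fraction must lie in [0, 1]", class = "karma_value_error")
  }
  bait <- names(design$baits)[1]
  proteins <- bind_rows(
    tibble(protein_id = sprintf("SUBUNIT_%02d", seq_len(n_subunits)),
           fl = mixing_fraction * heavy_share, role = "subunit"),
    tibble(protein_id = sprintf("COPURIFIED_%02d", seq_len(n_bulk)),
           fl = heavy_share, role = "bulk"),
    # sparse protein: too few precursors to pass the precursor-count filter
    tibble(protein_id = "SPARSE_01", fl = heavy_share, role = "sparse")
  )
  samples <- tibble(bait_id = bait, condition = "none",
                    replicate = seq_len(design$replicates), time_min = 90)
  records <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
      pr <- proteins[i, ]
      n_prec <- if (pr$role == "sparse") 2L else design$n_precursors
      skel <- protein_skeleton(pr$protein_id, n_prec, design$n_fragments,
                               decoys = FALSE)
      fl <- setNames(rep(pr$fl, 1), "90")
      ab <- if (pr$role == "sparse") abundance else abundance
      expand_records(skel %>% mutate(decoy = "none"), samples, fl, ab,
                     design$noise_sigma, design$missing_rate)
    })
  })
  list(records = records,
       subunit_ids = proteins$protein_id[proteins$role == "subunit"],
       bait_id = bait,
       truth = proteins)
}

#' Simulate a FRAP acquisition
#'
#' Produces a fluorescence-recovery trace: `n_pre` pre-bleach frames at a
#' constant level, then `n_post` post-bleach frames recovering as
#' `y(t) = y_bleach + mobile x (1 - y_bleach) x (1 - 2^(-t / tau_half))`
#' on the normalized scale, rendered back to raw intensities with a constant
#' extracellular background and whole-cell total, plus Gaussian noise.
#'
#' @param tau_half Recovery half-time, seconds.
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param background Extracellular background level (a.u.).
#' @param n_pre,n_post Frame counts before/after the bleach.
#' @param dt Frame interval, seconds.
#' @param noise Gaussian noise sd on the bleached-region intensity (a.u.).
#' @param seed Integer seed.
#' @param bleach_depth Normalized level immediately after the bleach.
#' @param scale Pre-bleach signal amplitude above background (a.u.).
#' @param total Whole-cell intensity (a.u., constant).
#' @return Tibble with `time`, `I_bl`, `I_bg`, `I_total` and attribute
#'   `n_pre`; post-bleach frames start at `time = 0`.
#' @export
simulate_frap_trace <- function(tau_half = 2, mobile_fraction = 1,
                                background = 50, n_pre = 20, n_post = 200,
                                dt = 0.12, noise = 0, seed = 1,
                                bleach_depth = 0.3, scale = 500,
                                total = 5000) {
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    abort("mobile_fraction must lie in [0, 1]", class = "karma_value_error")
  }
  t_pre <- -rev(seq_len(n_pre)) * dt
  t_post <- (seq_len(n_post) - 1) * dt
  y <- c(rep(1, n_pre),
         bleach_depth + mobile_fraction * (1 - bleach_depth) *
           (1 - 2^(-t_post / tau_half)))
  eps <- with_seed(seed, rnorm(n_pre + n_post, 0, noise))
  out <- tibble(
    time = c(t_pre, t_post),
    I_bl = background + scale * y + eps,
    I_bg = background,
    I_total = total
  )
  attr(out, "n_pre") <- as.integer(n_pre)
  out
}
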