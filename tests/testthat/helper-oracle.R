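# Naive brute-force reimplementation of the labeling-quantification cascade,
# written with plain loops and no vectorization, as an independent oracle.
# It mirrors the cascade's definitions only (filters, sum aggregation,
# presence rule, two-pass median with RMSE pruning) and shares no code with
# the package implementation.

oracle_quantify <- function(records, min_reps = 2, discard_fraction = 0.5) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)

  # --- fragment row filters ---
  row_ok <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    row_ok[i] <- !rec$excluded_flag[i] && rec$is_proteotypic[i] &&
      rec$fragment_series[i] == "y" && rec$lysine_count[i] == 1
  }
  rec <- rec[row_ok, , drop = FALSE]

  # --- both-channels-anywhere filter, evaluated on the row-filtered set:
  #     first pass tallies per-fragment channel detections, second pass keeps
  #     fragments seen in both channels ---
  fkey <- paste(rec$protein_id, rec$precursor_id, rec$fragment_series,
                rec$fragment_index, rec$fragment_charge, sep = "\r")
  seen_h <- new.env(parent = emptyenv())
  seen_l <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rec))) {
    if (rec$intensity[i] > 0) {
      if (rec$channel[i] == "heavy") assign(fkey[i], TRUE, envir = seen_h)
      else assign(fkey[i], TRUE, envir = seen_l)
    }
  }
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    keep[i] <- !is.null(seen_h[[fkey[i]]]) && !is.null(seen_l[[fkey[i]]])
  }
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)

  # --- sample and precursor universes, C-locale sorted like the package ---
  skey_of <- function(d) paste(d$bait_id, d$condition, d$replicate,
                               d$time_min, sep = "\r")
  samples <- unique(rec[, c("bait_id", "condition", "replicate", "time_min")])
  samples <- samples[order(samples$bait_id, samples$condition,
                           samples$replicate, samples$time_min,
                           method = "radix"), , drop = FALSE]
  precs <- unique(rec[, c("protein_id", "precursor_id")])
  precs <- precs[order(precs$protein_id, precs$precursor_id,
                       method = "radix"), , drop = FALSE]

  # --- sum aggregation per precursor x sample x channel: collect each
  #     cell's fragment intensities in input row order, then sum() ---
  H <- matrix(0, nrow(precs), nrow(samples))
  L <- matrix(0, nrow(precs), nrow(samples))
  pid <- paste(precs$protein_id, precs$precursor_id, sep = "\r")
  sid <- skey_of(samples)
  cell_h <- vector("list", nrow(precs) * nrow(samples))
  cell_l <- vector("list", nrow(precs) * nrow(samples))
  for (i in seq_len(nrow(rec))) {
    p <- match(paste(rec$protein_id[i], rec$precursor_id[i], sep = "\r"), pid)
    s <- match(paste(rec$bait_id[i], rec$condition[i], rec$replicate[i],
                     rec$time_min[i], sep = "\r"), sid)
    k <- (p - 1) * nrow(samples) + s
    if (rec$channel[i] == "heavy") {
      cell_h[[k]] <- c(cell_h[[k]], rec$intensity[i])
    } else {
      cell_l[[k]] <- c(cell_l[[k]], rec$intensity[i])
    }
  }
  for (p in seq_len(nrow(precs))) {
    for (s in seq_len(nrow(samples))) {
      k <- (p - 1) * nrow(samples) + s
      if (!is.null(cell_h[[k]])) H[p, s] <- sum(cell_h[[k]])
      if (!is.null(cell_l[[k]])) L[p, s] <- sum(cell_l[[k]])
    }
  }
  FLm <- matrix(NA_real_, nrow(precs), nrow(samples))
  for (p in seq_len(nrow(precs))) {
    for (s in seq_len(nrow(samples))) {
      tot <- H[p, s] + L[p, s]
      if (tot > 0) FLm[p, s] <- H[p, s] / tot
    }
  }

  # --- presence filter: detected in >= min_reps replicates at every
  #     post-labeling time point, per bait x condition ---
  tps <- sort(unique(samples$time_min[samples$time_min > 0]))
  keep_prec <- logical(nrow(precs))
  for (p in seq_len(nrow(precs))) {
    groups <- unique(samples[, c("bait_id", "condition")])
    ok_all <- TRUE
    for (g in seq_len(nrow(groups))) {
      for (tp in tps) {
        n_det <- 0
        for (s in seq_len(nrow(samples))) {
          if (samples$bait_id[s] == groups$bait_id[g] &&
              samples$condition[s] == groups$condition[g] &&
              samples$time_min[s] == tp &&
              (H[p, s] + L[p, s]) > 0) {
            n_det <- n_det + 1
          }
        }
        if (n_det < min_reps) ok_all <- FALSE
      }
    }
    keep_prec[p] <- ok_all
  }
  if (!any(keep_prec)) return(NULL)
  precs <- precs[keep_prec, , drop = FALSE]
  H <- H[keep_prec, , drop = FALSE]
  L <- L[keep_prec, , drop = FALSE]
  FLm <- FLm[keep_prec, , drop = FALSE]

  # --- two-pass protein median with RMSE pruning ---
  out <- NULL
  for (prot in sort(unique(precs$protein_id), method = "radix")) {
    rows <- which(precs$protein_id == prot)
    med1 <- numeric(nrow(samples))
    for (s in seq_len(nrow(samples))) {
      v <- FLm[rows, s]
      v <- v[!is.na(v)]
      med1[s] <- if (length(v)) median(v) else NA_real_
    }
    rmse <- numeric(length(rows))
    tot_int <- numeric(length(rows))
    for (k in seq_along(rows)) {
      sq <- c()
      hl <- c()
      for (s in seq_len(nrow(samples))) {
        if (samples$time_min[s] > 0) {
          d <- FLm[rows[k], s] - med1[s]
          if (is.finite(d)) sq <- c(sq, d^2)
          hl <- c(hl, H[rows[k], s] + L[rows[k], s])
        }
      }
      rmse[k] <- if (length(sq)) sqrt(mean(sq)) else Inf
      tot_int[k] <- sum(hl)
    }
    ord <- order(rmse, tot_int, precs$precursor_id[rows],
                 method = "radix", decreasing = c(TRUE, FALSE, TRUE))
    n_discard <- floor(length(rows) * discard_fraction)
    survivors <- rows[setdiff(seq_along(rows), ord[seq_len(n_discard)])]
    for (s in seq_len(nrow(samples))) {
      v <- FLm[survivors, s]
      v <- v[!is.na(v)]
      out <- rbind(out, data.frame(
        protein_id = prot,
        bait_id = samples$bait_id[s], condition = samples$condition[s],
        replicate = samples$replicate[s], time_min = samples$time_min[s],
        FL = if (length(v)) median(v) else NA_real_,
        stringsAsFactors = FALSE
      ))
    }
  }
  out[order(out$protein_id, out$bait_id, out$condition, out$replicate,
            out$time_min, method = "radix"), , drop = FALSE]
}

# Random small fragment-record instance for oracle-equivalence testing:
# up to 5 proteins x 6 precursors x 9 post-labeling samples, with random
# decoy flags, zeros and dropout.
random_instance <- function(seed) {
  set.seed(seed)
  n_prot <- sample(1:5, 1)
  reps <- 1:3
  times <- c(30, 60, 90)
  rows <- list()
  for (p in seq_len(n_prot)) {
    n_prec <- sample(1:6, 1)
    for (q in seq_len(n_prec)) {
      n_frag <- sample(1:4, 1)
      for (f in seq_len(n_frag)) {
        series <- sample(c("y", "y", "y", "b"), 1)
        proteo <- runif(1) > 0.1
        lys <- sample(c(1L, 1L, 1L, 2L), 1)
        excl <- runif(1) < 0.1
        for (r in reps) for (tm in times) {
          drop_sample <- runif(1) < 0.15
          fl <- runif(1)
          tot <- runif(1, 50, 1000)
          h <- if (drop_sample) 0 else tot * fl
          l <- if (drop_sample) 0 else tot * (1 - fl)
          if (runif(1) < 0.05) h <- 0   # occasional channel dropout
          if (runif(1) < 0.05) l <- 0
          for (ch in c("heavy", "light")) {
            rows[[length(rows) + 1]] <- data.frame(
              bait_id = "B1", condition = "none", replicate = r,
              time_min = tm, protein_id = sprintf("P%02d", p),
              is_proteotypic = proteo,
              precursor_id = sprintf("P%02d_q%02d/2", p, q),
              fragment_series = series, fragment_index = f + 2L,
              fragment_charge = 1L, channel = ch,
              intensity = if (ch == "heavy") h else l,
              excluded_flag = excl, lysine_count = lys,
              missed_cleavages = 0L, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
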