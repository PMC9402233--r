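#' Normalize a FRAP trace
#'
#' Background-subtracts and bleach-corrects a recovery trace:
#' `(I_bl - I_bg) / (I_total - I_bg)` per frame, then rescales so that the
#' mean over the pre-bleach frames equals 1. The rescale anchors the
#' normalized curve and makes the mobile-fraction definition well posed.
#'
#' @param trace Tibble with `time`, `I_bl`, `I_bg`, `I_total` and either an
#'   `n_pre` attribute or the `n_pre` argument (number of pre-bleach
#'   frames).
#' @param n_pre Number of pre-bleach frames; defaults to the trace
#'   attribute.
#' @return Tibble `time`, `norm`, `phase` (`"pre"` / `"post"`), with
#'   attribute `n_pre`.
#' @export
frap_normalize <- function(trace, n_pre = attr(trace, "n_pre")) {
  stopifnot(all(c("time", "I_bl", "I_bg", "I_total") %in% names(trace)))
  if (is.null(n_pre) || n_pre < 1) {
    abort("n_pre (pre-bleach frame count) must be >= 1",
          class = "karma_value_error")
  }
  denom <- trace$I_total - trace$I_bg
  bad <- which(denom <= 0)
  if (length(bad)) {
    abort(paste0("I_total <= I_bg at frame ", bad[1]),
          class = "karma_value_error")
  }
  norm <- (trace$I_bl - trace$I_bg) / denom
  pre_level <- mean(norm[seq_len(n_pre)])
  if (!is.finite(pre_level) || pre_level <= 0) {
    abort("pre-bleach level must be positive", class = "karma_value_error")
  }
  out <- tibble(
    time = trace$time,
    norm = norm / pre_level,
    phase = c(rep("pre", n_pre), rep("post", nrow(trace) - n_pre))
  )
  attr(out, "n_pre") <- as.integer(n_pre)
  out
}

#' Fit a FRAP recovery curve
#'
#' Least-squares fit of the half-time-parameterized single-exponential
#' recovery `y(t) = y0 + A * (1 - 2^(-t / tau_half))` to the post-bleach
#' part of a normalized trace. The mobile fraction is
#' `(y0 + A - y_bleach) / (y_pre - y_bleach)` clipped to `[0, 1]`, where
#' `y_bleach = y0` (the fitted level right after the bleach) and `y_pre` is
#' the normalized pre-bleach level (1 after [frap_normalize()]).
#'
#' @param norm Normalized post-bleach values (or a [frap_normalize()] result,
#'   from which the post phase is taken).
#' @param time Post-bleach times in seconds (first frame at 0); ignored when
#'   `norm` is a normalized trace tibble.
#' @param y_pre Normalized pre-bleach level (default 1).
#' @return Tibble with `tau_half`, `mobile_fraction`, `plateau`, `y0`,
#'   `rss`, `converged`. Non-convergence is flagged, not thrown.
#' @export
fit_frap_recovery <- function(norm, time = NULL, y_pre = 1) {
  if (is.data.frame(norm)) {
    post <- norm[norm$phase == "post", ]
    time <- post$time
    y <- post$norm
  } else {
    y <- norm
  }
  if (length(y) < 10) {
    abort("need at least 10 post-bleach points", class = "karma_value_error")
  }
  y0_start <- y[1]
  a_start <- max(max(y) - y0_start, 1e-6)
  # crude half-time start: first time the curve crosses half its span
  half_idx <- which(y - y0_start >= a_start / 2)
  tau_start <- if (length(half_idx)) max(time[half_idx[1]], 1e-3) else
    max(time) / 4
  d <- data.frame(t = time, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + A * (1 - 2^(-t / tau)),
      data = d,
      start = list(y0 = y0_start, A = a_start, tau = tau_start),
      lower = c(-Inf, 0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # flat series: no recovery, mobile fraction 0
    return(tibble(tau_half = NA_real_, mobile_fraction = 0,
                  plateau = mean(y), y0 = y[1],
                  rss = sum((y - mean(y))^2), converged = FALSE))
  }
  cf <- coef(fit)
  plateau <- cf[["y0"]] + cf[["A"]]
  denom <- y_pre - cf[["y0"]]
  mobile <- if (denom <= 0) 0 else (plateau - cf[["y0"]]) / denom
  tibble(
    tau_half = cf[["tau"]],
    mobile_fraction = min(max(mobile, 0), 1),
    plateau = plateau,
    y0 = cf[["y0"]],
    rss = sum(stats::resid(fit)^2),
    converged = TRUE
  )
}

#' Filter intensity profiles by standard-deviation cutoff
#'
#' Excludes envelope intensity profiles whose sample standard deviation
#' exceeds `sd_cutoff` (profiles dominated by large foci); the remaining
#' profiles and the exclusion count are returned.
#'
#' @param profiles List of numeric vectors (one intensity profile each).
#' @param sd_cutoff Exclusion threshold on the sample SD (a.u., default
#'   200); `Inf` keeps everything.
#' @return The retained profiles with attribute `n_excluded`.
#' @export
profile_sd_filter <- function(profiles, sd_cutoff = 200) {
  if (length(profiles) == 0) {
    abort("profiles must be nonempty", class = "karma_value_error")
  }
  sds <- vapply(profiles, function(p) sd(p), numeric(1))
  keep <- is.na(sds) | sds <= sd_cutoff
  out <- profiles[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Pearson correlation between two channel profiles
#'
#' Sample Pearson correlation between intensity values of two equally long
#' profiles (e.g. green and red channels along the same contour). Errors on
#' constant profiles, where the coefficient is undefined.
#'
#' @param green,red Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
profile_pearson <- function(green, red) {
  if (length(green) != length(red)) {
    abort("profiles must have equal length", class = "karma_value_error")
  }
  if (length(green) < 3) {
    abort("profiles must have length >= 3", class = "karma_value_error")
  }
  if (sd(green) == 0 || sd(red) == 0) {
    abort("correlation undefined for a constant profile",
          class = "karma_value_error")
  }
  cor(green, red, method = "pearson")
}

# Single-Gaussian model used by the peak fits.
gauss1 <- function(x, A, c, s, b) b + A * exp(-(x - c)^2 / (2 * s^2))

#' Peak centers and distances by Gaussian fitting of a line profile
#'
#' Measures membrane spacings on a 1-D intensity profile: local maxima seed
#' the `n_peaks` most prominent peaks, each is refined by a least-squares
#' Gaussian fit in a window of +/- 3 initial sigmas, and peaks whose windows
#' overlap are refined jointly as a multi-Gaussian model. Returns sorted
#' centers and adjacent-center distances in units of the spatial step.
#'
#' @param profile Numeric intensity profile.
#' @param n_peaks Number of peaks to fit (>= 1).
#' @param step Spatial step per sample (default 1; e.g. nm/px).
#' @return List with `centers` (sorted, in `step` units) and `distances`
#'   (adjacent differences; empty for a single peak).
#' @export
fit_profile_peak_distances <- function(profile, n_peaks, step = 1) {
  if (n_peaks < 1) abort("n_peaks must be >= 1", class = "karma_value_error")
  x <- seq_along(profile)
  pk <- pracma::findpeaks(as.numeric(profile), npeaks = 0, sortstr = TRUE)
  if (is.null(pk) || nrow(pk) < n_peaks) {
    abort(paste0("found ", if (is.null(pk)) 0 else nrow(pk),
                 " local maxima, need ", n_peaks),
          class = "karma_value_error")
  }
  pk <- pk[seq_len(n_peaks), , drop = FALSE]
  base <- min(profile)
  seeds <- tibble(
    center = pk[, 2],
    height = pk[, 1] - base,
    # initial sigma from the half-max width within the peak's support
    sigma = vapply(seq_len(nrow(pk)), function(i) {
      lo <- pk[i, 3]; hi <- pk[i, 4]
      seg_x <- x[lo:hi]; seg_y <- profile[lo:hi] - base
      half <- (pk[i, 1] - base) / 2
      above <- seg_x[seg_y >= half]
      w <- if (length(above) >= 2) diff(range(above)) else 2
      max(w / 2.355, 0.5)   # FWHM -> sigma
    }, numeric(1))
  ) %>% arrange(.data$center)

  win_lo <- seeds$center - 3 * seeds$sigma
  win_hi <- seeds$center + 3 * seeds$sigma
  overlap <- n_peaks > 1 && any(win_lo[-1] < win_hi[-n_peaks])

  fit_single <- function(seed) {
    idx <- x >= seed$center - 3 * seed$sigma & x <= seed$center + 3 * seed$sigma
    d <- data.frame(x = x[idx], y = as.numeric(profile[idx]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gauss1(x, A, c, s, b), data = d,
        start = list(A = seed$height, c = seed$center, s = seed$sigma, b = base),
        lower = c(0, min(d$x), 0.1, -Inf),
        upper = c(Inf, max(d$x), diff(range(x)), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) seed$center else coef(fit)[["c"]]
  }

  centers <- if (!overlap) {
    vapply(seq_len(n_peaks), function(i) fit_single(seeds[i, ]), numeric(1))
  } else {
    # joint multi-Gaussian fit with a shared baseline
    d <- data.frame(x = x, y = as.numeric(profile))
    model <- function(par) {
      b <- par[1]
      y <- rep(b, length(x))
      for (i in seq_len(n_peaks)) {
        a <- par[1 + (i - 1) * 3 + 1]
        cc <- par[1 + (i - 1) * 3 + 2]
        s <- par[1 + (i - 1) * 3 + 3]
        y <- y + a * exp(-(x - cc)^2 / (2 * s^2))
      }
      y
    }
    par0 <- c(base, as.vector(rbind(seeds$height, seeds$center, seeds$sigma)))
    lower <- c(-Inf, rep(c(0, min(x), 0.1), n_peaks))
    upper <- c(Inf, rep(c(Inf, max(x), diff(range(x))), n_peaks))
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper,
      fn = function(par) as.numeric(profile) - model(par),
      control = minpack.lm::nls.lm.control(maxiter = 400)
    )
    fit$par[1 + (seq_len(n_peaks) - 1) * 3 + 2]
  }
  centers <- sort(centers) * step
  list(centers = centers,
       distances = if (n_peaks > 1) diff(centers) else numeric(0))
}
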