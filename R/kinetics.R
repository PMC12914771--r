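#' Morrison tight-binding relative velocity
#'
#' Fractional residual enzyme velocity `Vi/V0` in the presence of a
#' tight-binding competitive inhibitor:
#' `1 - (E + I + Kiapp - sqrt((E + I + Kiapp)^2 - 4 E I)) / (2 E)`.
#' All concentrations share one unit (nM here). The discriminant is clamped
#' at zero against floating-point cancellation, and the result is clipped
#' to `[0, 1]`. As `E -> 0` the expression approaches the classical
#' `Kiapp / (Kiapp + I)`.
#'
#' @param E Total enzyme concentration (nM), > 0.
#' @param I Inhibitor concentration(s) (nM), >= 0.
#' @param Kiapp Apparent inhibition constant (nM), > 0.
#' @return Relative velocities in `[0, 1]`, vectorised over `I`.
#' @export
morrison_relative_velocity <- function(E, I, Kiapp) {
  if (any(E <= 0)) stop("`E` must be positive", call. = FALSE)
  if (any(I < 0)) stop("`I` must be non-negative", call. = FALSE)
  if (any(Kiapp <= 0)) stop("`Kiapp` must be positive", call. = FALSE)
  s <- E + I + Kiapp
  disc <- pmax(s^2 - 4 * E * I, 0)
  v <- 1 - (s - sqrt(disc)) / (2 * E)
  pmin(pmax(v, 0), 1)
}

#' Convert between apparent and intrinsic inhibition constants
#'
#' For a competitive tight-binding inhibitor assayed at substrate
#' concentration `S` against an enzyme with Michaelis constant `Km`:
#' `Kiapp = Ki * (1 + S/Km)`. `Ki` and `Kiapp` are in nM; `S` and `Km`
#' share their own unit (uM in the packaged defaults) so only their ratio
#' enters.
#'
#' @param Kiapp,Ki Apparent / intrinsic inhibition constant (nM).
#' @param S Substrate concentration (same unit as `Km`).
#' @param Km Michaelis constant, > 0.
#' @return The converted constant (nM).
#' @export
kiapp_to_ki <- function(Kiapp, S, Km) {
  if (any(Km <= 0)) stop("`Km` must be positive", call. = FALSE)
  if (any(S < 0)) stop("`S` must be non-negative", call. = FALSE)
  Kiapp / (1 + S / Km)
}

#' @rdname kiapp_to_ki
#' @export
ki_to_kiapp <- function(Ki, S, Km) {
  if (any(Km <= 0)) stop("`Km` must be positive", call. = FALSE)
  if (any(S < 0)) stop("`S` must be non-negative", call. = FALSE)
  Ki * (1 + S / Km)
}

#' Initial rate from a fluorescence trace
#'
#' Least-squares slope of fluorescence against time over the linear early
#' portion of the trace. By default the window is the first 300 s;
#' `auto = TRUE` instead scans all contiguous windows of at least
#' `min_points` points and picks the one maximising R-squared (longest
#' window wins ties).
#'
#' @param times Strictly increasing time points (s).
#' @param fluorescence Fluorescence readings (arbitrary units).
#' @param window Length-2 numeric, time window `[from, to]` in seconds.
#' @param auto Use the automatic window search instead of `window`.
#' @param min_points Minimum points per window (>= 5; automatic mode uses
#'   at least 10).
#' @return The slope (units per second), with the chosen window as
#'   attribute `window`.
#' @export
initial_rate <- function(times, fluorescence, window = c(0, 300),
                         auto = FALSE, min_points = 5L) {
  stopifnot(length(times) == length(fluorescence))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  slope_of <- function(idx) {
    t <- times[idx]; f <- fluorescence[idx]
    sum((t - mean(t)) * (f - mean(f))) / sum((t - mean(t))^2)
  }
  if (!auto) {
    idx <- which(times >= window[1] & times <= window[2])
    if (length(idx) < min_points) {
      stop("fewer than ", min_points, " points in the rate window",
           call. = FALSE)
    }
    out <- slope_of(idx)
    attr(out, "window") <- range(times[idx])
    return(out)
  }
  n <- length(times)
  mp <- max(min_points, 10L)
  if (n < mp) stop("trace too short for automatic window search",
                   call. = FALSE)
  best <- NULL
  for (from in seq_len(n - mp + 1L)) {
    for (to in seq(from + mp - 1L, n)) {
      idx <- from:to
      f <- fluorescence[idx]; t <- times[idx]
      sst <- sum((f - mean(f))^2)
      b <- slope_of(idx)
      ssr <- b^2 * sum((t - mean(t))^2)
      r2 <- if (sst == 0) 1 else ssr / sst
      if (is.null(best) || r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 && length(idx) > best$len)) {
        best <- list(slope = b, r2 = r2, len = length(idx),
                     window = range(t))
      }
    }
  }
  out <- best$slope
  attr(out, "window") <- best$window
  out
}

fit_kiapp_one <- function(I, v, E, fit_v0) {
  sse_at <- function(log10k) {
    m <- morrison_relative_velocity(E, I, 10^log10k)
    v0 <- if (fit_v0) sum(m * v) / sum(m^2) else 1
    sum((v - v0 * m)^2)
  }
  opt <- stats::optimize(sse_at, interval = c(-5, 7), tol = 1e-10)
  kiapp <- 10^opt$minimum
  m <- morrison_relative_velocity(E, I, kiapp)
  v0 <- if (fit_v0) sum(m * v) / sum(m^2) else 1
  list(kiapp = kiapp, v0 = v0, sse = opt$objective)
}

#' Fit the inhibition constant from Morrison dose-response data
#'
#' Fits the apparent inhibition constant by least squares over the Morrison
#' tight-binding equation, with `Kiapp` the sole free parameter per
#' replicate (optionally an uninhibited-velocity scale `V0` when raw rates
#' are supplied), then converts to the intrinsic `Ki` with the fixed assay
#' constants `S` and `Km`. Replicates are fit independently; the reported
#' `Ki` is their mean and the SD the sample standard deviation. The
#' optimisation is a deterministic 1-D search on log10(Kiapp) over
#' `[1e-5, 1e7]` nM.
#'
#' @param data Tibble with columns `inhibitor_nM`, `velocity` (relative
#'   `Vi/V0`, or raw rates with `fit_v0 = TRUE`), and optionally
#'   `replicate`.
#' @param E Total enzyme concentration (nM).
#' @param S Substrate concentration (uM).
#' @param Km Michaelis constant (uM).
#' @param fit_v0 Co-fit a velocity scale (for raw, un-normalised rates).
#' @return An object of class `ki_fit`; see [tidy.ki_fit()] /
#'   [glance.ki_fit()].
#' @export
fit_ki <- function(data, E, S, Km, fit_v0 = FALSE) {
  stopifnot(all(c("inhibitor_nM", "velocity") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data <- tibble::as_tibble(data)

  fits <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(d, key) {
      if (length(unique(d$inhibitor_nM)) < 4L) {
        stop("under-determined fit: need >= 4 distinct inhibitor ",
             "concentrations", call. = FALSE)
      }
      vrel <- if (fit_v0) d$velocity / max(d$velocity) else d$velocity
      if (min(vrel) > 0.95) {
        stop("NO_SIGNAL: no measurable inhibition in replicate ",
             key$replicate, call. = FALSE)
      }
      one <- fit_kiapp_one(d$inhibitor_nM, d$velocity, E, fit_v0)
      tibble::tibble(replicate = key$replicate, kiapp = one$kiapp,
                     ki = kiapp_to_ki(one$kiapp, S, Km), v0 = one$v0,
                     sse = one$sse, n_points = nrow(d))
    }) |>
    dplyr::bind_rows()

  structure(
    list(replicates = fits,
         ki = mean(fits$ki),
         ki_sd = if (nrow(fits) > 1) stats::sd(fits$ki) else NA_real_,
         kiapp = mean(fits$kiapp),
         E = E, S = S, Km = Km, data = data, fit_v0 = fit_v0),
    class = "ki_fit"
  )
}

#' @export
print.ki_fit <- function(x, ...) {
  cat("<ki_fit> Ki =", format(x$ki, digits = 4), "nM")
  if (!is.na(x$ki_sd)) cat(" +/-", format(x$ki_sd, digits = 3))
  cat("  (Kiapp =", format(x$kiapp, digits = 4), "nM;",
      nrow(x$replicates), "replicate(s))\n")
  invisible(x)
}

#' Per-replicate parameters of a Ki fit
#'
#' @param x A `ki_fit`.
#' @param ... Unused.
#' @return Tibble with one row per replicate: `replicate`, `kiapp`, `ki`,
#'   `v0`, `sse`, `n_points`.
#' @method tidy ki_fit
#' @export
tidy.ki_fit <- function(x, ...) x$replicates

#' One-row summary of a Ki fit
#'
#' @param x A `ki_fit`.
#' @param ... Unused.
#' @return One-row tibble: `ki`, `ki_sd`, `kiapp`, `n_replicates`, and the
#'   fixed assay constants.
#' @method glance ki_fit
#' @export
glance.ki_fit <- function(x, ...) {
  tibble::tibble(ki = x$ki, ki_sd = x$ki_sd, kiapp = x$kiapp,
                 n_replicates = nrow(x$replicates),
                 E = x$E, S = x$S, Km = x$Km)
}

#' Selectivity profile as Ki fold changes
#'
#' Ratio of each enzyme's Ki to the reference enzyme's Ki: a fold of 100
#' means the inhibitor binds the reference enzyme 100 times more strongly.
#' `fold` is the display-rounded value (nearest integer at >= 10, two
#' significant digits below); `fold_raw` keeps the unrounded ratio.
#'
#' @param ki_table Tibble with columns `enzyme`, `ki` (nM); an optional
#'   `ki_sd` column is carried through.
#' @param reference Name of the reference enzyme (must appear in `enzyme`).
#' @return Tibble `enzyme`, `ki`, `fold_raw`, `fold` (reference row = 1).
#' @export
fold_changes <- function(ki_table, reference) {
  ki_table <- tibble::as_tibble(ki_table)
  i <- match(reference, ki_table$enzyme)
  if (is.na(i)) stop("reference enzyme not found in `ki_table`",
                     call. = FALSE)
  ref <- ki_table$ki[i]
  if (!is.finite(ref) || ref <= 0) stop("reference Ki must be positive",
                                        call. = FALSE)
  ki_table |>
    dplyr::mutate(
      fold_raw = .data$ki / ref,
      fold = ifelse(.data$fold_raw >= 10, round(.data$fold_raw),
                    signif(.data$fold_raw, 2))
    )
}

#' Correlate predicted log2 ER with measured inhibition constants
#'
#' Independent validation of an affinity model against orthogonal kinetics
#' measurements. To normalise Ki values across studies, the observed
#' quantity per variant is `log2(Ki_variant / Ki_WT)`. Returns the pairs
#' and the signed Pearson correlation; since a larger Ki means weaker
#' binding, a model predicting binding-gate enrichment is expected to
#' correlate *negatively* with log2 relative Ki.
#'
#' @param data Tibble with columns `predicted_log2_er` and `ki` (nM), and
#'   optionally `signature`.
#' @param wt_ki Wild-type Ki (nM), > 0.
#' @return List with `pairs` (tibble `predicted`, `observed`, plus
#'   `signature` when supplied) and `pearson`.
#' @export
ki_er_validation <- function(data, wt_ki) {
  stopifnot(all(c("predicted_log2_er", "ki") %in% names(data)))
  if (wt_ki <= 0) stop("`wt_ki` must be positive", call. = FALSE)
  if (nrow(data) < 3L) stop("need at least 3 variants with both quantities",
                            call. = FALSE)
  pairs <- tibble::tibble(
    predicted = data$predicted_log2_er,
    observed = log2(data$ki / wt_ki)
  )
  if ("signature" %in% names(data)) {
    pairs <- dplyr::bind_cols(tibble::tibble(signature = data$signature),
                              pairs)
  }
  list(pairs = pairs, pearson = pearson_r(pairs$predicted, pairs$observed))
}

#' Packaged assay constants
#'
#' The fixed kinetic assay constants used throughout the worked examples:
#' enzyme concentration 0.325 nM, substrate concentration 7.5 uM, and
#' per-enzyme Michaelis constants (uM) for the three matrix
#' metalloproteinase catalytic domains.
#'
#' @return A list with `E_nM`, `S_uM`, and `Km_uM` (named vector:
#'   `MMP1`, `MMP3`, `MMP9`).
#' @export
assay_constants <- function() {
  list(E_nM = 0.325, S_uM = 7.5,
       Km_uM = c(MMP1 = 3.607, MMP3 = 3.771, MMP9 = 4.75))
}
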