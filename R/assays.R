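#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_gene - Ct_ref`; per gene, `ddCt` is the mean dCt
#' of a test group minus the mean dCt of the control group and the fold
#' change is `2^-ddCt`.  Replicate Ct values of a sample/gene pair are
#' averaged arithmetically (Ct is already a log-scale quantity).
#'
#' @param ct tibble with columns `sample`, `group`, `gene`, `ct`.
#' @param reference_gene name of the normalizer gene (present for every
#'   sample).
#' @param control_group group label used as the baseline.
#' @return List with `fold_changes` (tibble: `gene`, `group`, `ddct`,
#'   `fold`) and `samples` (per-sample `dct` and relative quantity
#'   `rq = 2^-(dct - mean control dct)`).
#' @export
delta_delta_ct <- function(ct, reference_gene = "GAPDH",
                           control_group = "CTRL") {
  ct <- as_tibble(ct)
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  ref <- ct |>
    filter(.data$gene == reference_gene) |>
    group_by(.data$sample) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  d <- ct |>
    filter(.data$gene != reference_gene) |>
    group_by(.data$sample, .data$group, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    left_join(ref, by = "sample")
  if (anyNA(d$ref_ct)) abort(sprintf("missing %s Ct for some sample", reference_gene))
  d$dct <- d$ct - d$ref_ct
  ctrl <- d |>
    filter(.data$group == control_group) |>
    group_by(.data$gene) |>
    summarise(ctrl_dct = mean(.data$dct), .groups = "drop")
  if (nrow(ctrl) == 0) abort(sprintf("no samples in control group '%s'", control_group))
  d <- left_join(d, ctrl, by = "gene") |>
    mutate(rq = 2^-(.data$dct - .data$ctrl_dct))
  folds <- d |>
    group_by(.data$gene, .data$group) |>
    summarise(ddct = mean(.data$dct) - .data$ctrl_dct[1],
              fold = 2^-(mean(.data$dct) - .data$ctrl_dct[1]),
              n = dplyr::n(), .groups = "drop")
  list(fold_changes = folds,
       samples = select(d, "sample", "group", "gene", "dct", "rq"))
}

#' Colorimetric m6A percentage
#'
#' `m6A% = ((sample OD - NC OD) / S) / ((PC OD - NC OD) / p) * 100`, with
#' NC/PC the negative/positive controls, `S` the RNA input (ng) and `p`
#' the positive-control input (ng).  A sample OD below the negative
#' control clamps to 0% with a warning.
#'
#' @param sample_od,nc_od,pc_od optical densities.
#' @param s_ng sample RNA input in ng.
#' @param p_ng positive-control input in ng.
#' @return m6A percentage (vectorized over `sample_od`).
#' @export
m6a_percent <- function(sample_od, nc_od, pc_od, s_ng, p_ng) {
  if (pc_od <= nc_od) abort("positive control OD must exceed negative control")
  if (s_ng <= 0 || p_ng <= 0) abort("RNA inputs must be positive")
  num <- sample_od - nc_od
  if (any(num < 0)) {
    warn("sample OD below negative control; clamped to 0%")
    num <- pmax(num, 0)
  }
  (num / s_ng) / ((pc_od - nc_od) / p_ng) * 100
}

#' m6A/A ratio from calibrated LC-MS signals
#'
#' Fits an ordinary least-squares standard curve (signal ~ concentration,
#' with intercept) per nucleoside, inverse-predicts the concentrations of
#' the observed signals, and returns their ratio.
#'
#' @param m6a_signal,a_signal observed signals for the two nucleosides.
#' @param m6a_standards,a_standards tibbles (or data frames) with columns
#'   `conc` and `signal`, at least two rows each.
#' @return List with `ratio`, `conc_m6a`, `conc_a` and the fitted curves.
#' @export
m6a_over_a <- function(m6a_signal, a_signal, m6a_standards, a_standards) {
  calibrate <- function(std) {
    if (nrow(std) < 2) abort("need at least two standards per nucleoside")
    fit <- lm(signal ~ conc, data = as.data.frame(std))
    sl <- coef(fit)[["conc"]]
    if (!is.finite(sl) || abs(sl) < .Machine$double.eps) {
      abort("standard curve has zero slope; calibration impossible")
    }
    list(intercept = coef(fit)[["(Intercept)"]], slope = sl)
  }
  cm <- calibrate(m6a_standards)
  ca <- calibrate(a_standards)
  conc_m6a <- (m6a_signal - cm$intercept) / cm$slope
  conc_a <- (a_signal - ca$intercept) / ca$slope
  list(ratio = conc_m6a / conc_a, conc_m6a = conc_m6a, conc_a = conc_a,
       m6a_curve = cm, a_curve = ca)
}

#' Fit first-order mRNA decay from an actinomycin-D chase
#'
#' Least-squares fit of `ln(abundance) = -k t` through the origin
#' (abundance is pre-normalized to the t = 0 point); half-life is
#' `ln(2)/k`.  A non-positive decay estimate is reported as stable with
#' infinite half-life.  Non-positive abundances are dropped with a
#' warning.
#'
#' @param time time points in hours, starting at 0, strictly increasing.
#' @param abundance relative abundance (fraction of t = 0).
#' @param through_origin force the regression through `ln(1) = 0` at t = 0
#'   (default TRUE); otherwise a free intercept is fitted.
#' @return Tibble: `k` (per hour), `half_life` (hours), `r_squared`,
#'   `n_points`.
#' @export
decay_fit <- function(time, abundance, through_origin = TRUE) {
  if (any(diff(time) <= 0) || any(time < 0)) {
    abort("time points must be non-negative and strictly increasing")
  }
  ok <- abundance > 0
  if (any(!ok)) {
    warn(sprintf("%d non-positive abundance point(s) dropped", sum(!ok)))
  }
  t <- time[ok]; y <- log(abundance[ok])
  if (length(t) < 2) abort("fewer than 2 usable points")
  if (through_origin) {
    k <- if (sum(t^2) > 0) -sum(t * y) / sum(t^2) else 0
    fitted <- -k * t
  } else {
    fit <- lm(y ~ t)
    k <- -coef(fit)[["t"]]
    fitted <- stats::fitted(fit)
  }
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_res < 1e-12) 1 else 1 - ss_res / ss_tot
  tibble(
    k = k,
    half_life = if (k <= 0) Inf else log(2) / k,
    r_squared = r2,
    n_points = length(t),
    stable = k <= 0
  )
}
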