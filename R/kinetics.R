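#' First-order fit of a ligation time course
#'
#' Least-squares fit of `f(t) = A * (1 - exp(-k * t))` to ligated-fraction
#' data. The amplitude is bounded at 1.05 because ribozyme ligation reactions
#' commonly plateau below complete conversion. When the time course carries
#' essentially no curvature (maximum ligated fraction < 0.05), the fit falls
#' back to an initial-rate linear regression through the origin with an
#' assumed amplitude of 1 (`k = slope`), and flags the result.
#'
#' @param times reaction times in hours, strictly increasing.
#' @param ligated_fraction fraction ligated in \[0, 1\], same length.
#' @return list of class `kobs_fit`: `k_obs` (per hour), `amplitude`,
#'   standard errors `k_obs_se`/`amplitude_se`, `initial_rate_fallback`
#'   (logical), `fitted` values.
#' @examples
#' t <- c(0.5, 1, 2, 4, 8, 16)
#' f <- 0.8 * (1 - exp(-0.5 * t))
#' fit_first_order(t, f)$k_obs
#' @export
fit_first_order <- function(times, ligated_fraction) {
  stopifnot(length(times) == length(ligated_fraction), length(times) >= 2,
            all(diff(times) > 0))
  if (any(ligated_fraction < 0 | ligated_fraction > 1)) {
    stop("ligated_fraction must lie in [0, 1]")
  }
  if (all(ligated_fraction == 0)) stop("all-zero fractions: nothing to fit")
  fmax <- max(ligated_fraction)
  if (fmax < 0.05 || length(times) < 3) {
    # initial-rate regime: f ~ A k t with A = 1
    fit <- stats::lm(ligated_fraction ~ times + 0)
    k <- unname(stats::coef(fit)[1])
    se <- summary(fit)$coefficients[1, 2]
    return(structure(list(k_obs = k, amplitude = 1,
                          k_obs_se = se, amplitude_se = NA_real_,
                          initial_rate_fallback = TRUE,
                          fitted = unname(stats::fitted(fit))),
                     class = "kobs_fit"))
  }
  k0 <- max((ligated_fraction[2] - ligated_fraction[1]) /
              (times[2] - times[1]) / fmax, 1e-6)
  fit <- minpack.lm::nlsLM(
    ligated_fraction ~ A * (1 - exp(-k * times)),
    start = list(A = min(fmax * 1.02, 1.05), k = k0),
    lower = c(A = 1e-8, k = 0), upper = c(A = 1.05, k = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  structure(list(k_obs = est["k", "Estimate"], amplitude = est["A", "Estimate"],
                 k_obs_se = est["k", "Std. Error"],
                 amplitude_se = est["A", "Std. Error"],
                 initial_rate_fallback = FALSE,
                 fitted = unname(stats::fitted(fit))),
            class = "kobs_fit")
}

#' Rate enhancement over the uncatalyzed background
#'
#' @param k_cat catalyzed rate constant (per hour).
#' @param k_background matched background rate constant (per hour, > 0).
#' @return fold enhancement `k_cat / k_background`.
#' @examples
#' rate_enhancement(2.4e-2, 1.3e-5)  # templated AIP vs PPP background
#' @export
rate_enhancement <- function(k_cat, k_background) {
  if (any(k_background <= 0)) stop("background rate must be > 0")
  k_cat / k_background
}

#' Hill fit of a Mg2+ titration
#'
#' Least-squares fit of `k_obs(c) = k_max * c^n / (K_half^n + c^n)` to a
#' titration of the observed rate constant against divalent-ion
#' concentration. Initialization: `K_half` at the concentration whose
#' observed rate is closest to half the maximum, `n = 1`, `k_max` at the
#' maximum observed rate; bounds keep `n` in (0.2, 8] and `K_half` in
#' (0, 10 * max(c)]. The Hill coefficient is reported as a cooperativity
#' proxy for the number of bound ions, not a binding stoichiometry.
#'
#' If the fitted `K_half` reaches beyond the sampled concentration range the
#' result is flagged `unreliable_K_half` (no plateau was observed).
#'
#' @param conc concentrations in mM, positive and distinct (>= 4 points).
#' @param k_obs observed rate constants (per hour).
#' @return list of class `hill_fit`: `k_max`, `K_half` (mM), `hill_n`,
#'   standard errors, `unreliable_K_half`, `fitted`.
#' @export
fit_hill <- function(conc, k_obs) {
  stopifnot(length(conc) == length(k_obs), length(conc) >= 4,
            all(conc > 0), !anyDuplicated(conc))
  ord <- order(conc)
  conc <- conc[ord]; k_obs <- k_obs[ord]
  kmax0 <- max(k_obs)
  K0 <- conc[which.min(abs(k_obs - kmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    k_obs ~ k_max * conc^n / (K^n + conc^n),
    start = list(k_max = kmax0, K = K0, n = 1),
    lower = c(k_max = 0, K = 1e-9, n = 0.2),
    upper = c(k_max = Inf, K = 10 * max(conc), n = 8),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- summary(fit)$coefficients
  structure(list(k_max = est["k_max", "Estimate"],
                 K_half = est["K", "Estimate"],
                 hill_n = est["n", "Estimate"],
                 k_max_se = est["k_max", "Std. Error"],
                 K_half_se = est["K", "Std. Error"],
                 hill_n_se = est["n", "Std. Error"],
                 unreliable_K_half = est["K", "Estimate"] >= max(conc),
                 fitted = unname(stats::fitted(fit))),
            class = "hill_fit")
}

#' Slope of log10 k_obs versus pH
#'
#' Ordinary least squares of `log10(k_obs)` on pH restricted to a linear
#' range (default pH 6-9, the regime below the falling limb). A slope of 1
#' indicates rate-determining deprotonation of the nucleophile, as in the
#' uncatalyzed templated ligation; shallower slopes suggest a change in
#' mechanism.
#'
#' @param pH pH values.
#' @param k_obs observed rate constants (per hour), > 0 within the range.
#' @param range two-element numeric, inclusive pH window to fit.
#' @return list of class `ph_fit`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `n_points`, `range`.
#' @export
ph_log_slope <- function(pH, k_obs, range = c(6, 9)) {
  stopifnot(length(pH) == length(k_obs), length(range) == 2)
  sel <- pH >= range[1] & pH <= range[2]
  if (sum(sel) < 2) stop("need at least 2 points inside the pH range")
  if (any(k_obs[sel] <= 0)) stop("nonpositive k_obs inside the fit range")
  fit <- stats::lm(log10(k_obs[sel]) ~ pH[sel])
  # summary warns on numerically perfect fits; exact data are legitimate here
  co <- suppressWarnings(summary(fit)$coefficients)
  slope_se <- if (nrow(co) > 1 && sum(sel) > 2) co[2, 2] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = slope_se,
                 intercept_se = if (sum(sel) > 2) co[1, 2] else NA_real_,
                 n_points = sum(sel), range = range),
            class = "ph_fit")
}

#' Read a kinetic time course from CSV/TSV
#'
#' Expects columns `time_h` and `fraction` (comma- or tab-delimited,
#' auto-detected).
#'
#' @param path file path.
#' @return data frame with `time_h`, `fraction`.
#' @export
read_time_course <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("time_h", "fraction") %in% names(df)))
  df[order(df$time_h), c("time_h", "fraction")]
}
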