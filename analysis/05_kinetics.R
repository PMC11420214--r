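#!/usr/bin/env Rscript
# Ligation kinetics: first-order k_obs fits, rate enhancements, Mg2+ Hill
# binding and pH-rate slopes, demonstrated on seeded synthetic datasets whose
# truth parameters match the characterized values of the evolved
# triphosphate ligase (k_obs recovery at 5% noise; half-saturation ~14 mM
# with ~3 cooperatively bound Mg2+ ions; pH slope 0.45 for the catalyzed and
# 1 for the uncatalyzed reaction).

library(ribolandscape)
dir.create("results", showWarnings = FALSE)
seed <- 20260928L

## First-order time course ---------------------------------------------------
times <- c(0.5, 1, 2, 4, 8, 16, 24, 48)
tc <- generate_kinetics("first_order", times, list(k = 0.094, A = 0.8),
                        sigma = 0.05, seed = seed)
fit <- fit_first_order(tc$time_h, tc$fraction)
cat(sprintf("k_obs = %.4f +/- %.4f h^-1, amplitude %.2f (fallback: %s)\n",
            fit$k_obs, fit$k_obs_se, fit$amplitude, fit$initial_rate_fallback))

## Rate enhancements ----------------------------------------------------------
cat(sprintf("Templated nonenzymatic AIP vs PPP ligation: %.0f-fold faster\n",
            rate_enhancement(2.4e-2, 1.3e-5)))
cat(sprintf("Catalyzed over background (example): %.0f-fold\n",
            rate_enhancement(fit$k_obs, 9.4e-4)))

## Mg2+ Hill binding ----------------------------------------------------------
conc <- c(1, 2, 5, 10, 14, 25, 50, 100, 200)
ti <- generate_kinetics("hill", conc, list(k_max = 1, K_half = 14, n = 3),
                        sigma = 0.05, seed = seed + 1L)
hf <- fit_hill(ti$conc_mM, ti$kobs_h)
cat(sprintf("Hill fit: [Mg2+]1/2 = %.1f mM, n = %.2f, k_max = %.2f h^-1%s\n",
            hf$K_half, hf$hill_n, hf$k_max,
            if (hf$unreliable_K_half) " (K unreliable: no plateau)" else ""))

## pH-rate profiles ----------------------------------------------------------
pH <- seq(6, 9, 0.5)
cat_d <- generate_kinetics("ph", pH, list(slope = 0.45, intercept = -6),
                           sigma = 0.05, seed = seed + 2L)
unc_d <- generate_kinetics("ph", pH, list(slope = 1, intercept = -11),
                           sigma = 0.05, seed = seed + 3L)
cat(sprintf("pH slope, catalyzed: %.3f +/- %.3f; uncatalyzed: %.3f +/- %.3f\n",
            ph_log_slope(cat_d$pH, cat_d$kobs_h)$slope,
            ph_log_slope(cat_d$pH, cat_d$kobs_h)$slope_se,
            ph_log_slope(unc_d$pH, unc_d$kobs_h)$slope,
            ph_log_slope(unc_d$pH, unc_d$kobs_h)$slope_se))

summary <- data.frame(
  quantity = c("k_obs_h", "amplitude", "Mg_K_half_mM", "Mg_hill_n",
               "pH_slope_catalyzed", "pH_slope_uncatalyzed"),
  estimate = c(fit$k_obs, fit$amplitude, hf$K_half, hf$hill_n,
               ph_log_slope(cat_d$pH, cat_d$kobs_h)$slope,
               ph_log_slope(unc_d$pH, unc_d$kobs_h)$slope))
write.table(summary, "results/kinetics_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/kinetics_summary.tsv\n")
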