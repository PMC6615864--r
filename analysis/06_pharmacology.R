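#!/usr/bin/env Rscript
# Pharmacology layer: 4PL dose-response fitting with GI20/GI50 extraction
# (the screens were run at the ligand GI20), a Bliss-independence synergy
# surface with peak detection, and a one-site saturation binding fit of a
# DDX42-like G4 binding curve (Kd ~71 nM).

suppressMessages(library(dropscreen))

## 4PL + GI values: simulated CellTiter-Glo-style viability curve
doses <- 10^seq(-8, -4, length.out = 8)   # molar
d <- simulate_dose_response(top = 100, bottom = 0, logIC50 = -6, hill = 1.3,
                            doses = doses, sigma_noise = 2,
                            n_replicates = 4, seed = 7)
fit <- fit_4pl(d$dose, d$response, normalized = TRUE)
cat(sprintf("4PL fit: logIC50 %.3f (true -6), hill %.2f\n",
            fit$logIC50, fit$hill))
cat(sprintf("GI50 = %.3g M, GI20 = %.3g M (screen concentration)\n",
            gi_value(fit, 50), gi_value(fit, 20)))

## Bliss synergy surface over a 5x5 concentration matrix
set.seed(7)
Ia <- c(0, 0.05, 0.1, 0.2, 0.4)   # G4 ligand alone
Ib <- c(0, 0.04, 0.06, 0.1, 0.3)  # inhibitor alone
expected <- outer(Ia, Ib, function(a, b) a + b - a * b)
obs <- expected
obs[4, 4] <- min(expected[4, 4] + 0.35, 0.99)  # one synergistic pocket
v <- 100 * (1 - obs) + matrix(rnorm(25, 0, 0.5), 5, 5)
v[1, 1] <- 100
dimnames(v) <- list(signif(10^seq(-7, -5, length.out = 5), 2),
                    signif(10^seq(-8, -6, length.out = 5), 2))
surf <- bliss_surface(v)
cat(sprintf("peak Bliss synergy: %.1f points at dose A %s, dose B %s\n",
            surf$peak$synergy, surf$peak$dose_A, surf$peak$dose_B))
utils::write.table(round(surf$synergy, 2), "results/bliss_synergy.tsv",
                   sep = "\t", quote = FALSE)

## one-site saturation binding (ELISA-style)
b <- simulate_binding_curve(Bmax = 1, Kd = 71.1,
                            concentrations = c(0, 12.5, 25, 50, 100, 200),
                            sigma_noise = 0.02, n_replicates = 5, seed = 7)
bfit <- fit_one_site(b$conc, b$signal)
cat(sprintf("one-site fit: Kd %.1f nM (true 71.1), Bmax %.3f; y(Kd)=Bmax/2 identity holds\n",
            bfit$Kd, bfit$Bmax))
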