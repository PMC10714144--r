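#!/usr/bin/env Rscript
# Step 5 -- calibration regressions and covariate selection.
#
# Relates DLW-derived energy expenditure to VeDBA for the whole deployment
# and the at-sea period (both subtraction methods), then runs stepwise
# (forward + backward, AIC) selection over the movement and morphometric
# covariates. Requires step 1's outputs.

library(vedbacal)
stopifnot(file.exists("results/energy_table.csv"))
energy <- data.table::fread("results/energy_table.csv")

total <- calibrate_total(energy)
at_sea <- calibrate_at_sea(energy)

fits <- list(
  dee_vedba = total$dee_vedba, ee_pred = total$ee_pred,
  dee_pred = total$dee_pred, s1_vedba = at_sea$s1_vedba,
  s2_vedba = at_sea$s2_vedba)
cat("Calibration regressions:\n")
rows <- lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  cat(sprintf("  %-10s R^2 = %.2f, F(%d,%d) = %5.1f, p = %.3g, n = %d\n",
              nm, f$r_squared, f$df[1], f$df[2], f$F, f$p, f$n))
  data.frame(model = nm, r_squared = f$r_squared, F = f$F,
             df1 = f$df[1], df2 = f$df[2], p = f$p, n = f$n,
             intercept = f$coefficients[1, 1], slope = f$coefficients[2, 1])
})

step_total <- stepwise_select(
  energy, "DLW_DEE", "VeDBA_mean_T",
  candidates = c("TD", "dive_rate", "mass", "prop_at_sea", "tarsus"))
cat(sprintf("\nStepwise (total): selected {%s}, R^2 = %.2f\n",
            paste(step_total$selected, collapse = ", "),
            step_total$fit$r_squared))
step_sea <- stepwise_select(
  energy, "DLW_DEE_S1", "VeDBA_mean_S",
  candidates = c("TD", "dive_rate", "mass", "NT", "tarsus"))
cat(sprintf("Stepwise (at sea): selected {%s}, R^2 = %.2f\n",
            paste(step_sea$selected, collapse = ", "),
            step_sea$fit$r_squared))

out <- do.call(rbind, rows)
data.table::fwrite(out, "results/calibration_fits.csv")
writeLines(c(paste("total:", paste(step_total$selected, collapse = "+")),
             paste("at_sea:", paste(step_sea$selected, collapse = "+"))),
           "results/stepwise_selected.txt")
cat("Wrote results/calibration_fits.csv, stepwise_selected.txt\n")
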