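# Builds inst/extdata/synthetic_panel_90d.csv: a small fully synthetic panel
# in the layout of a London-style monitoring-site export (six pollutants with
# realistic scales and missingness, meteorology, daily CVD-like counts).
# Regenerate with: Rscript data-raw/make_synthetic_panel.R
library(multipoll)
set.seed(20110101)
T_ <- 90
cfg <- sim_config(n_days = T_, n_reps = 1)
mu <- simulate_latent(cfg, seed = 7)          # standardized latent field
Y <- simulate_measured(mu, 0.1, seed = 8)     # measured, standardized scale
# map to pollutant-like scales (center, scale) loosely matching urban levels
nm <- c("CO", "NO2", "O3", "SO2", "PCNT", "PM2.5")
center <- c(0.25, 35, 38, 1.8, 12, 11)
scale_ <- c(0.09, 16, 18, 1.4, 3.6, 7)
Yorig <- sweep(sweep(Y, 2, scale_, `*`), 2, center, `+`)
Yorig <- pmax(Yorig, 0.01)
# missing cells ~3%, completely at random
mask <- matrix(runif(T_ * 6) < 0.03, T_, 6)
Yorig[mask] <- NA
day <- seq_len(T_)
temperature <- round(8 + 7 * sin(2 * pi * (day - 20) / 365) + rnorm(T_, 0, 2), 1)
rel_humidity <- round(pmin(98, pmax(40, 75 - 0.8 * (temperature - 10) + rnorm(T_, 0, 6))), 1)
count <- simulate_outcome(mu, cfg, seed = 9)
df <- data.frame(date = as.Date("2011-01-01") + day - 1,
                 round(Yorig, 3), temperature, rel_humidity, count,
                 check.names = FALSE)
names(df)[2:7] <- nm
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
readr::write_csv(df, "inst/extdata/synthetic_panel_90d.csv", na = "")
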