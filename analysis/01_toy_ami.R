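#!/usr/bin/env Rscript
# Toy-data study: how adjusted mutual information behaves on a known
# signal pair, against shuffled surrogates and across noise levels.
# Writes results/toy_sweep.csv and results/toy_surrogates.csv.

suppressPackageStartupMessages(library(eegbp))
dir.create("results", showWarnings = FALSE)

spec <- toy_spec(n_samples = 1800L, noise_sd = 1, seed = 1)
tp <- gen_toy_sinusoid(spec)
cat(sprintf("Toy pair (n = 1800): Pearson r = %.3f, AMI = %.3f\n",
            cor(tp$y0, tp$y), toy_ami(tp$y0, tp$y)))

# surrogate null: AMI of independently shuffled copies is centred on zero
ens <- shuffle_surrogates(tp$y0, tp$y, toy_ami, n_surr = 100, seed = 2)
sig <- significance_mask(toy_ami(tp$y0, tp$y), ens, sided = "one")
cat(sprintf("Surrogate AMI: mean = %.4f, sd = %.4f; real value p = %.3f\n",
            mean(ens$values), sd(ens$values), sig$p))
write.csv(data.frame(surrogate_ami = ens$values),
          "results/toy_surrogates.csv", row.names = FALSE)

# noise sweep: correlation decays as sqrt(V/(V+s^2)), AMI decays faster
levels <- seq(0, 3, by = 0.25)
rows <- lapply(levels, function(s) {
  vals <- vapply(1:30, function(i) {
    tpi <- gen_toy_sinusoid(toy_spec(n_samples = 1800L, noise_sd = s,
                                     seed = 100 * i + match(s, levels)))
    c(cor(tpi$y0, tpi$y), toy_ami(tpi$y0, tpi$y))
  }, numeric(2))
  data.frame(noise_sd = s, mean_corr = mean(vals[1, ]),
             mean_ami = mean(vals[2, ]))
})
sweep <- do.call(rbind, rows)
write.csv(sweep, "results/toy_sweep.csv", row.names = FALSE)
near08 <- sweep[which.min(abs(sweep$mean_corr - 0.8)), ]
cat(sprintf("Noise sweep: at sd = %.2f mean r = %.3f and mean AMI = %.2f\n",
            near08$noise_sd, near08$mean_corr, near08$mean_ami))
cat("Wrote results/toy_sweep.csv and results/toy_surrogates.csv\n")
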