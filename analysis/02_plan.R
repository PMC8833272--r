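#!/usr/bin/env Rscript

# Stage 2: build the four study plans.
#
# For the small (sigma 3 mm) and large (sigma 8 mm) beam models: place SFUD
# spots (posterior + anterior fields), robustly optimize the weights over the
# nominal + 12 perturbed scenarios, normalize CTV D99 to 6930 cGy(RBE), and
# derive the five-painting alternating-order volumetric repainting plan.
# Writes plan JSONs and nominal doses under results/.

library(spotlab)

seed <- 7L
phantom <- generate_phantom(phantom_config(), seed = seed)
cfg <- default_experiment_config(seed = seed)

for (mn in c("small", "large")) {
  beam <- beam_model(mn)
  t0 <- Sys.time()
  built <- build_model_plans(phantom, beam, cfg)
  h <- dvh(built$nominal_dose, phantom$masks$CTV, organ = "CTV")
  cat(sprintf(
    "%s model: %d spots, optimized in %.0f s; nominal D99 %.0f, D95 %.0f, HI %.3f\n",
    mn, nrow(plan_spot_table(built$plan_nr)),
    difftime(Sys.time(), t0, units = "secs"),
    dose_at_volume(h, pct = 99), dose_at_volume(h, pct = 95),
    homogeneity_index(h)))
  write_plan_json(built$plan_nr, sprintf("results/plan_%sNR.json", mn))
  write_plan_json(built$plan_vr, sprintf("results/plan_%sVR.json", mn))
  write_nrrd(built$nominal_dose, sprintf("results/nominal_dose_%s.nrrd", mn))
}
cat("plans written under results/\n")
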