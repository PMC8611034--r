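#!/usr/bin/env Rscript
# Attribute the coarse ET and albedo products of the reference city to the
# land-cover classes by sub-pixel linear unmixing, exercising the blue-sky
# albedo approximation and the monthly climatology on a dated raster stack.
# Writes results/signatures.csv.

library(coolcity)

dir.create("results", showWarnings = FALSE)
truth <- truth_config(seed = 101)
city <- synth_city(truth, nrow = 300, ncol = 300, n_scenes = 0,
                   coarse_cell_size = 450, coarse_noise_sd = 0.5)
co <- city$coarse

# monthly climatology over a small multi-year stack of the ET product
years <- 2016:2018
stack <- lapply(years, function(y) co$et)
clim <- monthly_climatology(stack, as.Date(sprintf("%d-07-15", years)),
                            variable = "et")
stopifnot(identical(clim$months[["07"]]$values, co$et$values))

blue <- blue_sky_albedo(co$albedo_white, co$albedo_black)
sig <- rbind(unmix(co$et, co$fractions, variable = "et"),
             unmix(blue, co$fractions, variable = "albedo_blue"))
sig$planted <- ifelse(sig$variable == "et",
                      truth$et_signature[sig$class],
                      truth$albedo_signature[sig$class])
write.csv(sig, file.path("results", "signatures.csv"), row.names = FALSE)

for (i in seq_len(nrow(sig)))
  message(sprintf("%-12s %-25s %8.3f +- %.3f  (planted %.3f)%s",
                  sig$variable[i], sig$class[i], sig$value[i], sig$se[i],
                  sig$planted[i],
                  ifelse(isTRUE(sig$flag_negative[i]), "  [flagged]", "")))
message("ET pixels masked over urban-dominated coarse cells: ",
        sum(is.na(co$et$values)), "/", length(co$et$values))
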