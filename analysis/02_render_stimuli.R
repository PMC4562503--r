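#!/usr/bin/env Rscript
# Render demonstration stimuli: the four annulus masks, one single-transient
# random-dot sequence (animated GIF), and the contrast-decay proxy stimulus.
# A reduced 300 px matrix at the same deg/px scale keeps the files small;
# shapes and timing are unchanged.

suppressPackageStartupMessages(library(persifade))
dir.create("results/stimuli", showWarnings = FALSE, recursive = TRUE)

geom_full <- display_geometry(600, 19.15)
geom <- display_geometry(300, 19.15 / 2)  # same deg/px scale

# the four annuli, drawn as masks
for (sz in c(100, 200)) for (th in c(25, 75)) {
  spec <- annulus_spec(sz, th)
  export_frame_png(shape_mask(spec, geom),
                   sprintf("results/stimuli/annulus_%d_%d.png", sz, th))
}

# single-transient sequence: M1 for 500 ms, transition, M2 for 900 ms
tp <- transient_pair(annulus_spec(200, 75), geom, seed = 101)
frames <- c(rep(list(tp$m1 + 0), 10), rep(list(tp$m2 + 0), 18))
export_animation(frames, "results/stimuli/transient_annulus.gif",
                 frame_rate = 20)

# proxy stimulus: grey disk whose contrast follows the 600 ms decay curve
dec <- calibrate_offset(50, 0.6)
base <- random_matrix(300, seed = 102)
dk <- disk_spec(diameter_deg = 3.5)
times <- seq(0, 900, by = 50)
pf <- proxy_frames(base, dk, dec, times, t_T_ms = 100, geom = geom)
export_animation(pf, "results/stimuli/proxy_decay.gif", frame_rate = 20)

cat("Rendered", length(frames), "transient frames and", length(pf$frames),
    "proxy frames under results/stimuli/\n")
cat("Mask pixel counts (equal-area pairs):\n")
cat(" small/thick:", sum(shape_mask(annulus_spec(100, 75), geom_full)),
    " large/thin:", sum(shape_mask(annulus_spec(200, 25), geom_full)), "\n")
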