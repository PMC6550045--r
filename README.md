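# woundcyte

Quantification of leukocyte responses to tail-fin wounding in zebrafish
larvae, for labs doing live-imaging inflammation assays and small paired
RNA-seq designs.

Tail-fin amputation recruits macrophages and neutrophils to the wound
within hours. Two families of read-outs characterize that response, and
this package implements both ends to end:

**Imaging arm.** From a single-channel time-lapse stack (one maximum-
projection frame per ~minute): cells are detected as smoothed local
intensity maxima, linked into trajectories by a globally optimal
(Hungarian) assignment with gap closing, and summarized as

- cell counts inside a wound region of interest, averaged per hour;
- migration velocity (µm/min) per hour;
- an eight-bin directionality histogram of step angles relative to the
  direction toward the nearest wound point — bin 0, (−22.5°, 22.5°], is
  "toward the wound";
- cell-shape circularity `C = 4πA/P²` (Crofton perimeter), its
  distribution, the high-circularity fraction `C ∈ (0.5, 1]` (a rounded,
  M1-like morphology proxy), and two-sample Kolmogorov–Smirnov comparison
  between treatment groups.

**Transcriptome arm.** From a genes × samples count matrix with four
paired conditions (control, amputation, beclomethasone, combined):
low-count filtering (total over the contrast's six samples < 30 removed),
median-of-ratios normalization, a simplified paired negative-binomial Wald
test per contrast (`count ~ treatment + replicate`, fixed moment-estimated
dispersion floored at the across-gene median), Benjamini–Hochberg
adjustment, regulation sets at p.adj < 0.05 and |FC| > 2 with Venn
overlaps, and the attenuation statistic: the fraction of amputation-
regulated genes whose response shrinks toward zero under the combined
glucocorticoid treatment. ΔΔCt fold changes for qPCR validation are
included.

**Simulation module.** `simulate_scene()` renders movies of wound-biased
von Mises random walkers with known tracks and shapes; `simulate_counts()`
draws paired NB count matrices with planted regulation and attenuation
structure. Every claim the pipeline makes is tested against these ground
truths.

## Worked example

Simulate a wound-directed scene, run the full imaging pipeline, then the
transcriptome arm on simulated counts:

```r
library(woundcyte)

cfg <- scene_config(n_cells = 25, n_frames = 60, kappa = 2,
                    speed_mean = 3.5, min_separation = 12, seed = 42)
sc  <- simulate_scene(cfg)
det <- do.call(rbind, lapply(seq_len(cfg$n_frames), function(f) {
  d <- detect_maxima(sc$stack[, , f], sigma = 2, min_distance = 8,
                     abs_threshold = 15)
  cbind(frame = f, d)
}))
trk <- build_tracks(det, max_disp = 10, max_gap = 2)
sv  <- step_velocities(trk, pixel_size = cfg$pixel_size,
                       frame_interval = cfg$frame_interval, roi = cfg$wound)
sv$per_hour
#>   hour mean_velocity n_steps
#> 1    1      2.525531    1741
round(directionality(sv$steps)$fractions, 3)
#>  bin0  bin1  bin2  bin3  bin4  bin5  bin6  bin7
#> 0.237 0.141 0.159 0.057 0.067 0.049 0.155 0.136
```

The toward-wound bin dominates (0.237 versus 0.125 for an unbiased walk).
The mean tracked velocity sits below the drawn speed of 3.5 µm/min because
cells that reach the wound crowd and stall there — the same saturation seen
in real recruitment assays.

```r
sim   <- simulate_counts(count_sim_config(n_genes = 2000, seed = 7))
amp   <- paired_nb_test(sim$counts, "amp")
combo <- paired_nb_test(sim$counts, "amp_beclo")
reg   <- classify_regulation(list(amp = amp, amp_beclo = combo))
reg$venn
#>       contrasts n_up n_down
#> 1           amp  270    123
#> 2     amp_beclo  239    107
#> 3 amp&amp_beclo  168     79
amp_sig <- union(reg$up$amp, reg$down$amp)
af <- attenuation_fraction(amp, combo, amp_sig, tol = 0.3)
af$counts
#>   attenuated     enhanced    unchanged sign_flipped
#>          306           17           66            4
sprintf("attenuated: %.1f%% of %d amputation-regulated genes",
        100 * af$fraction_attenuated, af$n)
#> "attenuated: 77.9% of 393 amputation-regulated genes"
```

The generator planted 25% of the amputation-responsive genes as
glucocorticoid-insensitive; the pipeline recovers ~78% attenuated among the
significant genes, matching the planted fraction within its binomial
confidence interval.

See `vignettes/wound-quantification.Rmd` for the models, parameter
conventions, and the reasoning behind the numerical choices.

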