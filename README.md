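# punctacol

Automated, threshold-robust quantification of synapses in multi-channel
confocal images of neuronal cultures, with a ground-truth simulation
framework for validating the detector and utilities for multi-electrode
array (MEA) activity analysis.

## The problem

Object-based synapse counting identifies a synapse as a presynaptic punctum
(e.g. vGluT1 or vGAT staining) and a postsynaptic punctum (PSD-95 or
gephyrin) whose centroids fall within 250 nm of each other on a dendrite
(MAP2). Two things make naive counting unreliable: the detected puncta
count depends strongly on the intensity threshold chosen to separate signal
from background, and spurious staining produces *random-chance*
colocalizations that inflate the count. `punctacol` implements a
three-step procedure that addresses both:

1. **Segmentation.** Each puncta channel is rolling-ball background
   subtracted (ball radius 4 px, protected zone 9 px = 450 nm at 50 nm/px),
   median filtered (3×3), thresholded at the 45th percentile of the pixel
   intensity distribution (deliberately *below* the commonly used mean
   intensity), and its local intensity maxima grown by 2 px into 5-px-wide
   (250 nm) circular binary puncta. The dendrite channel is thresholded at
   its mean intensity and dilated by 2 px.
2. **Colocalization.** A synapse candidate is an 8-connected component of
   the binary AND of the three masks:
   `pre_mask & post_mask & dendrite_mask`.
3. **Noise correction.** The number of random-chance colocalizations is
   estimated by destroying the spatial correlation between the channels —
   either by randomizing the locations of the puncta objects within each
   image (mean of N randomizations), or from the asymptote of a spatial
   cross-correlation profile (colocalization count vs. relative mask
   shift). The corrected count is

   `corrected = total − noise_estimate`,

   reported as a density per 100 µm² of dendritic area. Because the
   correction removes whatever chance overlap a given threshold admits, the
   corrected density is insensitive to the threshold over a wide range.

Sensitivity and error behaviour are validated on simulated 1024×1024 scenes
with known ground truth: 5-px-wide dendrite lines, 800 true colocalized
pre/post pairs on the dendrites, and a calibrated number of uniformly
scattered noise puncta setting the scene's signal-to-noise ratio
(SNR = true pairs / expected chance colocalizations).

## Worked example

Simulate a validation scene at SNR 2, run the full mask-level
quantification with randomization noise correction, and print the result:

```r
library(punctacol)

scene <- simulate_scene(n_true = 800, target_snr = 2, seed = 42)
scene
#> <synthetic_scene> 1024x1024 px, 800 true pairs, noise 3083+3083 puncta,
#>   target SNR 2 (realized 2), dendrite coverage 21.0%

res <- quantify_scene(scene, n_reps = 10, seed = 7)
res
#> <coloc_result> total=1068 noise=336.70 corrected=731.30
#>   dendritic area 923.3 um^2, density 79.21 per 100 um^2 (randomization)
```

The scene carries 800 true synapses; the detector reports 1068 raw
detections (true pairs plus chance overlaps, minus fusions of adjacent
objects), estimates ~337 of them to be random-chance colocalizations, and
returns a corrected count of ~731 — a sensitivity of 91%, typical of the
detector's 86–94% range across SNR 1.5–6. For real images, use
`load_image_set()` + `quantify_synapses()` (single field) or `run_batch()`
(a manifest of fields, with SNR quality screening), and `compare_groups()`
for Wilcoxon rank-sum comparisons of densities across ages with Bonferroni
correction. A command-line front end is installed at
`inst/cli/punctacol.R` with subcommands `detect`, `batch`, `simulate`,
`validate`, `mea` and `compare`.

MEA recordings are analysed with `bandpass()` (2nd-order Butterworth,
300 Hz–1.5 kHz, zero phase), `detect_spikes()` (negative deflections beyond
5 SD), `leaky_integrate()` (50 ms time constant) and `detect_bursts()`
(4 SD of the integrated activity), summarized as spikes/sec and bursts/min
per electrode.

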