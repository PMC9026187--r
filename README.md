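# alphanft

Simulation and analysis of a closed-loop **alpha-band neurofeedback (NFT)**
experiment for motor-imagery brain–computer interfacing, in R.

## Who this is for

EEG/BCI researchers who want a fully testable, end-to-end model of an
NFT study: because the virtual subjects have known latent parameters
(individual alpha frequency, alpha amplitude, desynchronization depth,
trainability), every stage of the analysis pipeline can be validated by
parameter recovery rather than by eyeballing human data.

## What it implements

**Online engine.** The feedback statistic is the alpha relative power over
16 frontal electrodes,

    ARP = P_alpha / P_total,          dARP = (ARP_epoch - ARP_baseline) / ARP_baseline

with the alpha band anchored at the individual alpha frequency,
(IAF−2, IAF+2) Hz, and total band (1, 50) Hz, estimated by multitaper
(DPSS) spectra on 1 s epochs updated every 100 ms. A dynamic threshold
(initial 10%, stride 1%, floor 1%, ring buffer of 100 frames) governs
sparse smiley rewards; feedback pauses on EOG artifacts.

**Virtual subjects.** A Gaussian-pattern forward model mixes occipital/
frontal alpha, lateralized sensorimotor mu sources and blinks onto a
56-channel 10-10 montage with 1/f background noise. The subject's alpha
amplitude responds to positive feedback through an explicit learning ODE
`da/dt = eta*r*(a_max − a) − lam*(a − a0)`; ~30% of cohort draws are
non-responders (eta ≈ 0).

**Evaluation pipeline.** IAF estimation; IAF-anchored band powers/relative
powers; event-related desynchronization `ERD = (P_task − P_pretask) /
P_pretask`; 8–30 Hz zero-phase FIR, one-versus-rest CSP and RBF-SVM with
stratified 10-fold cross-validation (three-class and pairwise); phase lag
index and imaginary coherence on 48 lateral electrodes from 5 s baseline
segments; paired t-tests, Pearson correlation and Benjamini–Hochberg FDR.
EDF+ with annotations is the on-disk format.

## Worked example

```r
library(alphanft)

# one trainable virtual subject
p <- subject_profile(iaf = 9.5, a0 = 20, a_task = 12, eta = 0.04,
                     noise_scale = 5, blink_rate = 0, seed = 42)

# pre-NFT baselines: estimate the IAF, freeze the engine baseline
ec  <- generate_baseline(p, eyes = "closed", duration_s = 60)
eo  <- generate_baseline(p, eyes = "open",   duration_s = 60)
iaf <- estimate_iaf(ec)
st  <- init_engine(eo, iaf)

# closed-loop neurofeedback: the subject's alpha amplitude adapts online
nft <- run_nft_session(p, st, n_runs = 6, run_s = 60)

# post-NFT motor-imagery decoding at the trained amplitude
mi  <- generate_mi_session(p, alpha_amp = nft$final_amp,
                           trials_per_task = 4)
tr  <- epoch_trials(fir_bandpass(select_channels(mi, montage()$scalp)), 0, 4)

cat(sprintf("IAF %.2f Hz | baseline ARP %.3f | final amp %.1f uV\n",
            iaf, st$arp_baseline, nft$final_amp))
cat("per-run mean dARP:", round(nft$run_mean_delta_arp, 3), "\n")
cat(sprintf("three-class CV accuracy: %.3f\n",
            evaluate_cv(tr, "three_class", seed = 1)))
```

Output:

```
IAF 9.70 Hz | baseline ARP 0.665 | final amp 35.7 uV
per-run mean dARP: 0.154 0.175 0.133 0.167 0.164 0.183
three-class CV accuracy: 1.000
```

Read: the estimated IAF recovers the latent 9.5 Hz to within the grid
resolution; with a fast learner (`eta = 0.04`, time constant ~25 s) the
alpha amplitude reaches its trained level (20 → 36 µV) within the first
run, so the per-run mean deviation is already positive in run 1 and stays
elevated; at the trained amplitude the lateralized desynchronization
contrast is large, so the decoder is at ceiling. A non-responder
(`eta = 0`) shows `dARP ≈ 0` across runs, `final_amp = a0`, and unchanged
accuracy.

A whole cohort, end to end (pre/post baselines, MI sessions, NFT,
connectivity, statistics, CSV reports):

```r
res <- run_study(study_config(n_subjects = 18, seed = 1,
                              out_dir = "results/study"))
res$correlation   # Pearson r between frontal dARP and three-class dAccuracy
```

## Layout

- `R/` — recordings/EDF+, synthetic subjects, spectral estimation, NFT
  engine, MI decoding, connectivity, statistics, study orchestration
- `src/` — tridiagonal eigensolver for Slepian tapers (Rcpp)
- `inst/cli/alphanft` — command-line front end (`simulate`, `nft-run`,
  `mi-eval`, `study`)
- `vignettes/alphanft-methods.Rmd` — model, assumptions, tunables, design
  decisions, limitations
- `tests/testthat/` — unit, property and acceptance tests
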