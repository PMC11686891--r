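# mrfsynth

Synthesis of MR fingerprinting (MRF) relaxometry information from
magnitude-only T1-weighted brain MRI, in R.

MRF estimates quantitative T1 and T2 maps by varying acquisition
parameters so that each tissue traces a distinctive transient signal,
then matching every voxel's signal evolution against a dictionary of
Bloch-simulated candidates. The catch is that MRF needs a dedicated pulse
sequence and reconstruction chain — which three decades of archived
clinical MRI do not have. This package implements a pipeline that learns
to *synthesize* the compressed MRF signal from an ordinary MPRAGE volume,
so that quantitative relaxometry can be recovered from conventional
images:

1. **Forward model** — Bloch simulation of fingerprints over an
   inversion-prepared variable-flip-angle train; dictionary construction
   on a (T1, T2) grid with the physical constraint T2 ≤ T1; temporal SVD
   compression to rank 4 (seven real channels after phase normalization
   of SV1); inner-product dictionary matching
   `argmax_j |⟨d_j, s⟩|` over unit-norm atoms, returning T1, T2 and
   proton density per voxel.
2. **Network** — seven parallel U-Net image regressors (one per SV
   channel: Re SV1, Re/Im SV2–SV4), each an encoder/decoder with
   double 3×3 convolutions, ReLU + batch norm in the encoder, bilinear
   upsampling, skip concatenations growing channels by exactly 1.5×, and
   a tanh 1×1-convolution head. Implemented from scratch
   (RcppArmadillo), trained per-channel with MSE losses and ADAM, with
   best-verification-MSE checkpointing.
3. **Phantom** — a multi-subject digital brain phantom (ellipsoidal
   CSF/GM/WM shells, angular parenchymal parcels, inter-subject tissue
   variability, additive noise) producing paired MPRAGE / compressed-MRF
   volumes for download-free training and testing.
4. **Statistics** — Lin's concordance correlation coefficient
   `CCC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`, subject-clustered
   bootstrap percentile intervals, regional mean differences and
   coefficients of variation; a packaged 47-region table of acquired vs.
   synthesized T1/T2 regional statistics.

It is aimed at quantitative-MRI researchers who want a fully inspectable,
desk-scale implementation of this synthesis pipeline — every stage runs
in minutes on a laptop and is exercised end to end by the test suite.

## Worked example

```r
library(mrfsynth)

sched <- default_schedule(n_excitations = 120)
dict  <- build_dictionary(sched, t1_values = seq(400, 2000, by = 100),
                          t2_values = seq(30, 200, by = 10))
cdict <- compress_dictionary(dict, k = 4)
retained_energy(cdict)
#> 0.9996

# a scaled on-grid signal comes back exactly
sv <- project_timeseries(t(dict$atoms[, 100]) * 1.4, cdict)
m  <- match_dictionary(sv, cdict)
c(m$t1, m$t2, m$pd)
#> 900 120 1.4     (grid truth: T1 = 900 ms, T2 = 120 ms)

# regional agreement statistics from the packaged 47-region table
rep_ <- table_report(read_region_stats())
rep_$t1$mean_difference   #> 48.23  ms (acquired minus synthesized T1)
rep_$t2$mean_difference   #> 2.02   ms
rep_$t1$cov$min[1]        #> 0.066  (smallest regional CoV, acquired T1)
rep_$t1$ccc_of_means      #> 0.9159
rep_$t2$ccc_of_means      #> 0.9527
```

The mean differences say that, averaged over the 47 regions, the
synthesized maps underestimate T1 by ≈ 48 ms and T2 by ≈ 2 ms; the CCC
values quantify the concordance of the paired regional means.

Phantom training end to end:

```r
cdict <- compress_dictionary(build_dictionary(default_schedule(),
         default_grid()$t1, default_grid()$t2), k = 4)
spec  <- phantom_spec(seed = 1)                    # 6 subjects, 64^3
pairs <- lapply(1:6, function(i) generate_pair(spec, i, cdict))
net   <- build_network(network_config(input_size = 64, base_filters = 4,
                                      n_levels = 2, seed = 0))
st    <- mrf_train(net, pairs[1:4], epochs = 10,
                   verification = pairs[5], lr = 3e-3, seed = 1)
sv    <- mrf_predict(st$best_net, pairs[[6]]$mprage,
                     rescale_table_from_subjects(lapply(pairs[1:4], `[[`, "sv")))
maps  <- match_dictionary(channels_to_sv(matrix(sv, ncol = 7)), cdict,
                          mask = as.vector(pairs[[6]]$mask))
```

A command-line wrapper over the same functions is installed at
`inst/scripts/mrf-synth` (subcommands `simulate-dict`, `match`,
`make-phantom`, `preprocess`, `train`, `predict`, `evaluate`).

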