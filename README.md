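# hyperbrain

Dual-brain ("hyperscanning") EEG phase-synchronization and network
analysis in R.

When two people interact, their EEG signals can synchronize — both within
each brain and between the two brains. `hyperbrain` implements a complete
analysis chain for such two-person recordings, for researchers studying
social interaction with dual-EEG setups:

1. **Phase synchronization.** The corrected imaginary phase-locking value
   (ciPLV) measures undirected synchronization while discarding zero-lag
   (volume-conducted) coupling: with
   `z = ⟨exp(i(φᵢ − φⱼ))⟩` pooled over trials and artifact-free samples,

   ```
   ciPLV = |Im(z)| / sqrt(1 − Re(z)²)  ∈ [0, 1].
   ```

   The phase slope index (PSI) measures *directed* synchronization from
   the slope of the cross-spectrum phase across frequencies,

   ```
   Ψ̃ᵢⱼ = Im( Σ_{f∈F} C*ᵢⱼ(f) Cᵢⱼ(f + δf) ),    Ψ = Ψ̃ / std_jackknife(Ψ̃),
   ```

   where `Cᵢⱼ(f)` is the complex coherency from segment-averaged
   cross-spectra; positive `Ψᵢⱼ` means channel *i* temporally precedes
   (drives) channel *j*.

2. **Cluster-permutation inference.** Edge-wise paired t statistics
   (eye-contact vs. control) are thresholded at |t| > 2, suprathreshold
   same-sign edges are clustered into connected components, and summed
   cluster scores are tested against a max-statistic permutation null
   (family-wise error control; directed variant separates sign and
   direction).

3. **Hyperbrain networks.** Eye-contact edges are z-scored against the
   control condition per edge block (inter-brain at pair level,
   intra-brain per participant), thresholded at Z > 1 SD, and summarized
   by strength, density, degree, global/local efficiency, modularity of
   the two-brain partition, degree assortativity, rich-club structure
   against a degree-preserving null, ROI aggregates, and directed
   leader→follower flow metrics.

4. **Behavior.** Tone-reproduction statistics, partner correlation against
   a within-person shuffled null, and the leadership statistic (fraction
   of trials one partner breaks eye contact first, reflected to [0.5, 1],
   with a cohort median split into strong/weak leadership).

5. **Synthetic dyads.** A coupled phase-oscillator generator produces
   18-channel two-brain recordings with band-limited oscillations,
   condition-dependent inter-brain coupling, time-delayed
   leader→follower coupling, a zero-lag shared source
   (volume-conduction surrogate), blink artifacts and behavioral trial
   tables — so the entire chain is testable without external data.

## Worked example

```r
library(hyperbrain)

cfg <- run_config(n_dyads = 10, n_perm = 200,
                  sim = sim_config(n_trials = 40, fs = 250), seed = 11)
res <- run_pipeline(cfg)
res
#> <hyperbrain_results> 8 dyads analyzed, 2 excluded
#>    ciplv selected band(s): gamma
#>    psi selected band(s): none
#>   manifest 6dc204cb6223f80492de18f7a7e31ac7

res$cluster_tests$ciplv$gamma$inter
#> <cluster_result> 4 cluster(s), t-critical 145.89 (alpha 0.05 , 200 permutations)
#>   +1 x 103 edges  score 412.84  p 0.0100 *
#>   -1 x 1 edges  score -2.17  p 1.0000
#>   -1 x 1 edges  score -2.69  p 1.0000
#>   -1 x 3 edges  score -6.80  p 0.9602

head(res$metrics$gamma[, c("group", "strength_inter", "strength_intra",
                           "density_inter")], 3)
#>          group strength_inter strength_intra density_inter
#> dyad01 friends       6.438779       1.333027     0.3055556
#> dyad02 friends       5.725591       1.381213     0.3333333
#> dyad03 friends       6.894369       1.187900     0.4629630
```

The simulated cohort couples a right-hemisphere + midline channel set
between brains in the gamma band during eye-contact trials only; two
dyads retain fewer than five valid trials in a condition and are
excluded, as real dyads would be. Step 1 (cluster permutation per band)
finds one significant positive gamma cluster over the inter-brain
edges — its summed t score (412.8) exceeds the permutation critical
value (145.9, p = 0.01) while the stray negative single-edge components
do not — so gamma is selected and no other band is. Step 2 z-scores
each dyad's eye-contact matrix against its control condition and
thresholds at 1 SD: `strength_inter` (mean retained inter-brain z) is
far above `strength_intra`, reflecting that the simulated eye-contact
effect is specific to between-brain edges, and friend dyads (which
receive a coupling increment) show higher inter-brain strength than
strangers.

Individual stages are plain functions: `generate_dyad()`,
`rereference()`, `detect_blinks()`, `epoch_analytic()`,
`ciplv_matrix()`, `psi_matrix()`, `cluster_permutation()`,
`zscore_edges()`, `threshold_graph()`, `rich_club()`, `leadership()`, …
See the methods vignette (`vignettes/hyperbrain-methods.Rmd`) for the
model, parameter choices and limitations, and
`inst/scripts/run_pipeline.R` for a shell entry point.

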