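# abstractnav

Simulation and analysis of learning in discrete multidimensional abstract
spaces — the "grid world in feature space" paradigm used to study cognitive
maps with fMRI. Subjects navigate 1-D, 2-D and 3-D spaces (six values per
dimension) from random starts to random destinations, choosing among
options around the current location; behaviour is summarised per step by
response accuracy (RA) and response time (RT). The package is for
methodologists and cognitive-neuroimaging researchers who want a tested,
fully synthetic re-implementation of this analysis stack, with every stage
validated by parameter recovery rather than by undeposited subject data.

The pipeline has four parts:

1. **Behavioral simulation** — five spaces in fixed order (S1P, S2C, S2P,
   S1C, S3P; the first of each dimensionality is Set 1, the second Set 2),
   10 paths per space, Chebyshev step metric, a 20% chance of termination
   after any suboptimal step, and a logistic latent learning curve with a
   Set-2 transfer head start.
2. **Learning-level estimation and staging** — each path's N×2 matrix of
   (RA, RT) rows feeds a feedforward classifier (dense 64- and 32-unit ReLU
   layers, softmax head, full-batch Adam at learning rate 0.001, 100
   epochs, parameters kept at minimum test loss) trained per
   dimensionality group to discriminate early (paths 1–3) from late (paths
   8–10) phases, with two labelled paths withheld for testing (chance level
   0.25 = 0.5/2). The softmax probability P(early) is the path's learning
   level; 2-means on these scalars splits paths into exploration (higher
   mean P(early)) and exploitation stages.
3. **Behavioral statistics** — linear mixed models `Y = X β + Q γ + ε`
   with a random intercept per subject × dimensionality cell: LMM1 (early
   vs late), LMM2 (Set 1 vs Set 2), LMM3 (exploration vs exploitation),
   for both RA_path and RT_path, plus one-sample, paired-t and
   repeated-measures ANOVA auxiliaries.
4. **Searchlight RSA** — per-path volumetric pattern-estimate maps
   (synthesised with a planted, stage-dependent destination code), neural
   RDM = 1 − Pearson r, theoretical RDM = Euclidean distance between
   destinations, Spearman ρ in a 3-voxel cube sliding at stride 1, Fisher
   z, voxelwise paired t between stages, and sign-flip permutation
   inference with TFCE (H = 2, E = 0.5, dh = 0.1) for family-wise error
   control.

## Worked example

```r
library(abstractnav)

sess   <- simulate_cohort(6, agent_config(), seed = 42)  # 6 subjects, 50 paths each
staged <- stage_cohort(sess, seed = 43)                  # classifier + 2-means per subject
st     <- stage_statistics(staged)
st$lmm[, c("model", "response", "beta", "se", "t", "p")]
#>   model response   beta     se      t        p
#> 1  LMM1  RA_path -0.230 0.0488  -4.70 5.61e-06
#> 2  LMM1  RT_path  0.352 0.0595   5.92 1.96e-08
#> 3  LMM2  RA_path -0.393 0.0345 -11.38 3.83e-25
#> 4  LMM2  RT_path  0.628 0.0355  17.70 1.52e-47
#> 5  LMM3  RA_path -0.111 0.0403  -2.76 6.17e-03
#> 6  LMM3  RT_path  0.140 0.0495   2.84 4.87e-03
```

Effects are coded reference minus comparison with early / Set 1 /
exploration as reference: the negative RA betas say the agents were less
accurate early than late (LMM1), in Set 1 than Set 2 (transfer, LMM2) and
during exploration than exploitation (LMM3); the positive RT betas say they
were also slower. Stage behaviour and classifier accuracy:

```r
aggregate(RA_path ~ stage, staged_path_table(staged), mean)
#>          stage RA_path
#> 1  exploration   0.661
#> 2 exploitation   0.772
st$accuracy_vs_chance$mean   # 0.345, vs the 0.25 chance baseline
```

The neural arm runs per subject and then at the group level:

```r
geom  <- volume_geometry(c(20, 20, 20))
model <- pattern_model(list(cube_region(geom, c(3, 3, 3), 7)))
pe    <- generate_pe_maps(staged[[1]], geom, model, seed = 1)
sl    <- searchlight_rsa(pe)                    # rho and Fisher-z maps per stage
# ... collect z maps across subjects, then:
# con <- stage_contrast(z_exploit, z_explore)
# grp <- permutation_fwe(con$diff, shape = geom$shape, n_perm = 10000, seed = 1)
# peak_table(grp)
```

`run_pipeline(run_config(...), outdir = "out")` executes all stages and
writes CSV/JSON tables, NIfTI maps and a checksummed manifest.

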