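# egressr

Ligand egress path discovery and free-energy estimation, at desk scale.

Unbinding of a ligand from a deeply buried protein binding site is a rare
event: unbiased simulation essentially never sees it. A practical workflow
used in the enhanced-sampling literature chains five pieces of machinery
together:

1. **sMD–RPP discovery** — dynamics on a uniformly down-scaled potential
   (`U -> beta * U`, beta = 0.6) with a Ratchet&Pawl potential (RPP): a
   history-dependent one-sided bias on a ratcheting coordinate `s` that is
   zero while `rho(t) = (s - s_target)^2` improves on its running best and
   half-harmonic in `rho` on retreat,
   `V = k/2 (rho - rho_best)^2`, `k = 0.024 kcal/mol/A^4`.
   Many cheap replicas yield an ensemble of unbinding trajectories.
2. **Guess-path construction** — trajectories are cleaned by an RMSD
   threshold scan (save a frame when it is >= 3 A from the last saved one),
   treated as streamlines, clustered with QuickBundles under the minimum
   average direct-flip (MDF) distance, and condensed into *N* equally
   spaced reference frames per cluster (gap filling by short targeted
   ratchet runs where the frame pool is sparse).
3. **Path-CV well-tempered metadynamics** — progress and deviation
   collective variables over the reference frames,
   `S = sum_i i w_i / sum_i w_i`, `Z = -(1/lambda) log sum_i exp(-lambda
   msd(X, X_i))` with `w_i = exp(-lambda msd(X, X_i))`, biased by Gaussian
   hills (initial height 0.2 kcal/mol, widths 0.1 / 1 A^2, bias factor 15,
   one hill per 2 ps); the free-energy surface is
   `F = -gamma/(gamma-1) V_bias`.
4. **Minimum free energy paths** — on the gridded FES, the path between
   bound and unbound states minimising lexicographically (maximum node
   energy, then node-energy sum), found MEPSA-style by node-by-node
   flooding and checked against an exhaustive oracle.
5. **Alchemical FEP** — double decoupling with soft-core potentials
   (`r_eff^6 = alpha sigma^6 lambda + r^6`, alpha = 0.5, power = 1,
   sigma = 3 A) over 11 electrostatic + 20 van der Waals lambda windows,
   Bennett-acceptance-ratio estimates per window pair, a harmonic
   restraint held throughout, and the analytic Boresch standard-state
   correction (1660 A^3) on release.

`egressr` implements all five stages against configurable low-dimensional
model landscapes with analytic gradients — a bound well surrounded by a
barrier ring pierced by exit channels of declared saddle heights — so every
stage is testable against deterministic quadrature oracles, with no
molecular data needed. Units throughout: kcal/mol, Angstrom, Kelvin, ps.

## Worked example

```r
library(egressr)

# 1. discover egress paths on a three-channel landscape (50 sMD-RPP replicas)
cfg <- campaign_config()   # defaults: beta = 0.6, k = 0.024, T = 300 K
res <- cmd_discover(cfg, outdir = "egressr_out")
print(res$clusters)

# 2. metadynamics on the first guess path, FES, minimum free energy path
metad <- cmd_metad(cfg, "egressr_out", path_id = 1)
fes   <- cmd_fes(cfg, "egressr_out", path_id = 1)
mfep  <- cmd_mfep(cfg, "egressr_out", path_id = 1)
cat(sprintf("MFEP barrier along path 1: %.2f kcal/mol over %d nodes\n",
            mfep$mfep$max_energy, nrow(mfep$mfep$path)))

# 3. toy alchemical double-decoupling cycle vs. its quadrature oracle
fep <- run_fep_cycle(fep_system(), n_samples = 600, n_equil = 1000,
                     thin = 10, seed = 2)
print(fep)
cat(sprintf("quadrature oracle: %.2f kcal/mol\n",
            fep_binding_oracle(fep_system())))
```

Output (exact under these seeds):

```
<cluster_set> 3 clusters over 50 streamlines (threshold 3 A)
  cluster 1: 24 members
  cluster 2: 15 members
  cluster 3: 11 members
MFEP barrier along path 1: 9.18 kcal/mol over 117 nodes
<fep_result> deltaG_bind = -7.207 +/- 0.031 kcal/mol
      leg         dg           se
 restrain  0.7599153 0.0304237416
     coul  9.8417677 0.0002772969
      vdw  0.5087228 0.0046221548
  release -3.9036109 0.0000000000
quadrature oracle: -7.26 kcal/mol
```

Reading this: the 50 replicas cluster into exactly the three built-in exit
channels, most populated through the lowest (4 kcal/mol) saddle. The MFEP
barrier along that channel, 9.18 kcal/mol, recovers the analytic well depth
plus saddle height (5 + 4 = 9) from the metadynamics surface alone. The
alchemical cycle reproduces the quadrature binding free energy of the toy
complex within its statistical error.

Each stage is also a CLI subcommand (`discover`, `metad`, `fes`, `mfep`,
`fep`, `all`), communicating only through files:

```sh
Rscript inst/cli/egressr all --config inst/extdata/quickstart.cfg \
        --outdir egressr_out --verbose
```

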