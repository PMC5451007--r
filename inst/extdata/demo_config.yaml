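# Demonstration configuration: a small fully-synthetic two-arm run.
seed: 20240401
synthetic:
  genetics:
    loci: 150
    populations: [early, late, allopatric]
    F: 0.1
    n_per_pop: 8
    coverage: 8
    missing_rate: 0.02
  landmarks:
    groups: {early: 12, late: 12}
    effect_size: 0.03
    noise_sd: 0.01
  melanization:
    groups: {early: 20, late: 20}
    slope: 0.2
    group_offsets: {early: 8, late: -8}
    noise_sd: 3
freq_mcmc:
  steps: 800
  burnin: 200
  thin: 4
admixture:
  k_range: [1, 2, 3]
  replicates: 2
  steps: 400
  burnin: 150
  thin: 4
nmds:
  dims: 2
  restarts: 4
morpho:
  permutations: 299
out_dir: popwing_demo
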