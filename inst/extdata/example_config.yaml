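# Pipeline configuration: simulated cohort conditions.
seed: 42
n_chromosomes: 23
chrom_length: 1.0e6
het_density: 1.0e-3
crossover_rate: 2
mean_coverage: 18.37
error_rate: 1.0e-3
call_mode: even_split
modes:
  sexual: 10
  central_automixis: 10
  terminal_automixis: 10
  gamete_duplication: 10
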