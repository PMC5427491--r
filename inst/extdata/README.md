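# Example data

Both files are **synthetic**, generated from the package's own simulator
(`simulate_dataset()`) and a Bernoulli marker generator, sized for examples
and tests only.

- `toy_phenotypes.csv` — long-format counts: 3 environments x 6 lines x
  2 replicates x 2 traits (72 records), columns `env,line,rep,trait,count`.
- `toy_markers.csv` — 6 lines x 30 presence/absence markers with a few
  missing calls (`NA`), first column the line ID.
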