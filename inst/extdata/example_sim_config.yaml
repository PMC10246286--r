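# Example simulation configuration for `striatax.R simulate`.
# Omitted fields fall back to sim_config() defaults (8-class/14-subclass
# interneuron taxonomy, NB dispersion 0.3, depth spread 0.3, 5% doublets).
n_donors: 3
regions: [CN, Pu]
cells_per_sample: 400
n_genes: 2000
doublet_rate: 0.05
composition:
  CN: {PTHLH: 0.356, TAC3: 0.092, CCK: 0.071, CCK/VIP: 0.092, SST/NPY: 0.092, SST/GRIK3: 0.092, PVALB: 0.113, CHAT: 0.092}
  Pu: {PTHLH: 0.203, TAC3: 0.1, CCK: 0.121, CCK/VIP: 0.1, SST/NPY: 0.1, SST/GRIK3: 0.135, PVALB: 0.141, CHAT: 0.1}
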