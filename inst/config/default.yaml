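# Default simulation configuration. Any omitted key falls back to the
# package default; `config_show()` prints the fully resolved set.
condition:
  mode: bolus          # bolus | continuous | none
  dose: 100            # uM-equivalent (bolus) or mU/mL (continuous)
  treatment_start: 0   # hours
perturbation:
  label: control       # control | srxn1_oe | srxn1_inhibited | prdx1_ko |
                       # prdx2_kd | prdx_inhibited
params: {}             # kinetic parameter overrides, e.g. { k_srx: 0.08 }
run:
  n_cells: 200
  t_end: 24            # hours
  dt_sample: 0.333333333333333  # 20-min sampling
  seed: 1
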