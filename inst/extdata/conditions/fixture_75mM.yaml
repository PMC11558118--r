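# High-salt condition: single interaction mode, rate crossover at 7 pN.
label: "75mM"
salt_mM: 75
ligand_nM: 10
forces_pN: [4.0, 5.2, 6.4, 7.6, 8.8, 10.0]
noise_sd_nm: 5
sampling_rate_hz: 100
n_released_nt: 20
modes:
  - fc_pN: 7.0
    rate_at_fc: 1.0
    dx_bind_nm: 0.6
    dx_unbind_nm: 0.6
    weight: 1.0
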