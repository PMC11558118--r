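# Intermediate-salt condition: two coexisting interaction modes with rate
# crossovers at 10 and 15 pN and equal weights. Both modes share the Bell
# distances and differ only in their zero-force rate prefactors.
label: "42mM"
salt_mM: 42
ligand_nM: 10
forces_pN: [8.0, 9.8, 11.6, 13.4, 15.2, 17.0]
noise_sd_nm: 5
sampling_rate_hz: 100
n_released_nt: 20
modes:
  - fc_pN: 10.0
    rate_at_fc: 1.0
    dx_bind_nm: 0.6
    dx_unbind_nm: 0.6
    weight: 0.5
  - fc_pN: 15.0
    rate_at_fc: 1.0
    dx_bind_nm: 0.6
    dx_unbind_nm: 0.6
    weight: 0.5
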