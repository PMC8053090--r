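strain: rnhAB
dose: 36.0
genome_length: 9200000.0
pd_induction_rate: 41.7
pd_density_per_nt: ~
slow_pd_fraction: 0.19
repair_lag_min: 5.0
fast_half_life: 6.0
slow_half_life: 57.0
plasmid_fast_half_life: 15.0
plasmid_slow_half_life: 60.0
rdh_length_mean: 3500.0
rdh_length_shape: 12.0
rdh_baseline_nt: 45000.0
rdh_baseline_length: 300.0
rdh_fold:
  time_min:
  - -1.0
  - 0.0
  - 10.0
  - 30.0
  - 60.0
  - 120.0
  fold:
  - 1.0
  - 1.0
  - 1.0
  - 5.2
  - 13.0
  - 12.0
rdh_induced_dispersed: no
rdh_protection_nt: 1300.0
channel_gains:
  southern: 1.0
  s96: 1.0
  pd: 1.0
noise_cv: 0.15
pd_floor_frac: 0.1
pd_blot_floor_frac: 0.03
background_nicks_per_genome: 45.0
p_spec: 0.69
p_bg: 0.003
sticky_frac: 0.01
p_stick: 0.29
capture_pd_boost: 0.04
xreact_frac: 0.01
rnase_survival: 0.01
shear_mean_nt: 5500.0
digest_tail_frac: 0.006
digest_tail_mean_nt: 30000.0
survival:
  dose:
  - 0.6
  - 5.0
  - 10.0
  - 20.0
  survival:
  - 1.0
  - 0.4
  - 0.08
  - 0.004
synthesis_rate:
  time_min:
  - 0.0
  - 10.0
  - 50.0
  - 90.0
  - 120.0
  - 180.0
  rate:
  - 0.5
  - 0.02
  - 0.02
  - 0.25
  - 0.3
  - 0.3
dilution_times:
- 50.0
- 90.0
- 150.0
seed: ~
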