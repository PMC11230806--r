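costs:
  cold_storage_per_kidney_usd: 250.0
  followup_annual_usd: 2715.599999999999909
  fx_brl_per_usd: 5.39
  hd_session_usd: 40.530000000000001
  hd_sessions_per_year: 156.0
  hmp_per_kidney_usd: 1800.0
  hmp_training_annual_usd: 50000.0
  preservation_source: synthetic
  transplant_episode_usd: 8254.389999999999418
demography:
  apply_background_to_graft: no
  background_mortality: 0.0
  initial_waitlist: 27613.0
  waitlist_annual_mortality: 0.0808
  yearly_entrants:
  - 9949.0
  - 16132.0
  - 10913.0
  - 17096.0
  - 11877.0
  yearly_transplants_comparator:
  - 4994.0
  - 5117.0
  - 5242.0
  - 5370.0
  - 5502.0
donors:
  share_ecd: 0.19
  share_scd: 0.81
  util_ecd_cs: 0.62
  util_ecd_mp: 0.88
  util_scd: 0.88
econ:
  bia_start_year: 2023
  discount_outcomes: no
  discount_rate: 0.05
  discount_rate_range:
  - 0.0
  - 0.1
  horizon_years: 5
  psa_iterations: 1000
  rng_seed: 1
  threshold_1gdp_usd: 6523.506666666667115
  threshold_3gdp_usd: 19570.520000000000437
survival:
  ecd:
    annual_death_with_graft:
    - 0.031981214997519
    - 0.031981214997519
    - 0.031981214997519
    - 0.031981214997519
    - 0.031981214997519
    annual_graft_loss:
    - 0.043647500209963
    - 0.043647500209963
    - 0.043647500209963
    - 0.043647500209963
    - 0.043647500209963
  scd:
    annual_death_with_graft:
    - 0.020851637639023
    - 0.020851637639023
    - 0.020851637639023
    - 0.020851637639023
    - 0.020851637639023
    annual_graft_loss:
    - 0.025242614469208
    - 0.025242614469208
    - 0.025242614469208
    - 0.025242614469208
    - 0.025242614469208
  source: synthetic
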