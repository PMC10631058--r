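features:
  entropy:
    baseline: 2.0
    drought_slope: -0.15
    salinity_slope: -0.15
    interaction: 0.0
    time_slope: -0.02
    noise_sd: 0.15
    direction: decreasing
  energy:
    baseline: 0.2
    drought_slope: 0.02
    salinity_slope: 0.02
    interaction: 0.0
    time_slope: -0.002
    noise_sd: 0.02
    direction: increasing
  homogeneity:
    baseline: 0.55
    drought_slope: 0.03
    salinity_slope: 0.03
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 0.03
    direction: increasing
  RWC:
    baseline: 90.0
    drought_slope: -6.0
    salinity_slope: -4.0
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 4.0
    direction: decreasing
  CI:
    baseline: 35.0
    drought_slope: -2.0
    salinity_slope: -3.0
    interaction: 0.0
    time_slope: 0.3
    noise_sd: 2.0
    direction: decreasing
  CA:
    baseline: 10.0
    drought_slope: 2.5
    salinity_slope: 1.2
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 1.2
    direction: increasing
  AC:
    baseline: 5.0
    drought_slope: 0.8
    salinity_slope: 1.3
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 0.8
    direction: increasing
  PhC:
    baseline: 12.0
    drought_slope: 1.5
    salinity_slope: 2.0
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 1.5
    direction: increasing
  PC:
    baseline: 8.0
    drought_slope: 2.0
    salinity_slope: 1.0
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 1.3
    direction: increasing
  miR156a:
    baseline: 10.0
    drought_slope: 1.6
    salinity_slope: 1.0
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 1.1
    direction: increasing
  miR166i:
    baseline: 8.0
    drought_slope: -1.0
    salinity_slope: 1.6
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 1.1
    direction: mixed
  miR399g:
    baseline: 6.0
    drought_slope: 0.3
    salinity_slope: 0.2
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 0.6
    direction: increasing
  miR477b:
    baseline: 12.0
    drought_slope: 4.0
    salinity_slope: -3.0
    interaction: 0.0
    time_slope: 0.0
    noise_sd: 0.35
    direction: mixed
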