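# Registry of published group summary statistics (mean and SD, in
# percent) for the sonoporation uptake and viability experiments this
# package models: per delivered molecule (7-AAD 1.2 kDa; FITC-dextran
# 4/20/70 kDa), per metric, per timepoint, per treatment group. These
# are the targets the synthetic replicate generator reproduces; they
# are summary values, not raw replicate data.
version: 1
experiments:
  7aad_count_0h:
    molecule: 7aad
    metric: count_fraction
    timepoint_h: 0
    groups:
      sham:       {mean: 21.0,  sd: 3.0}
      us_only:    {mean: 24.0,  sd: 3.3}
      tmb_us_100: {mean: 21.5,  sd: 0.9}
      tmb_us_500: {mean: 57.7,  sd: 4.9}
      tmb_us_800: {mean: 52.0,  sd: 6.3}
  fitc4_area_24h:
    molecule: fitc4
    metric: area_fraction
    timepoint_h: 24
    groups:
      sham:       {mean: 0.77,  sd: 0.21}
      us_only:    {mean: 0.22,  sd: 0.12}
      tmb_only:   {mean: 2.05,  sd: 0.86}
      tmb_us_500: {mean: 29.39, sd: 5.07}
      tmb_us_800: {mean: 24.14, sd: 4.46}
  fitc20_area_24h:
    molecule: fitc20
    metric: area_fraction
    timepoint_h: 24
    groups:
      sham:       {mean: 0.76,  sd: 0.41}
      tmb_us_100: {mean: 4.34,  sd: 1.86}
      tmb_us_200: {mean: 5.57,  sd: 3.01}
      tmb_us_300: {mean: 8.14,  sd: 1.95}
      tmb_us_500: {mean: 10.34, sd: 1.03}
      tmb_us_800: {mean: 13.23, sd: 1.32}
  fitc70_area_24h:
    molecule: fitc70
    metric: area_fraction
    timepoint_h: 24
    groups:
      sham:       {mean: 0.24,  sd: 0.03}
      tmb_us_100: {mean: 1.40,  sd: 0.12}
      tmb_us_200: {mean: 4.22,  sd: 0.52}
      tmb_us_300: {mean: 4.33,  sd: 1.19}
      tmb_us_500: {mean: 5.30,  sd: 1.40}
      tmb_us_800: {mean: 4.32,  sd: 0.60}
  fitc4_viability_24h:
    molecule: fitc4
    metric: viability_percent
    timepoint_h: 24
    groups:
      sham:       {mean: 100.0, sd: 9.04}
      us_only:    {mean: 93.19, sd: 11.9}
      tmb_only:   {mean: 22.87, sd: 1.01}
      tmb_us_100: {mean: 22.57, sd: 3.9}
      tmb_us_500: {mean: 12.1,  sd: 0.92}
      tmb_us_800: {mean: 7.92,  sd: 0.42}
  fitc4_viability_72h:
    # sham is the normalization reference (100% by definition); its SD
    # here is the 24 h sham spread carried over as a realistic scale.
    molecule: fitc4
    metric: viability_percent
    timepoint_h: 72
    groups:
      sham:       {mean: 100.0, sd: 9.04}
      tmb_only:   {mean: 85.83, sd: 2.17}
      tmb_us_100: {mean: 85.73, sd: 1.67}
      tmb_us_500: {mean: 52.84, sd: 10.5}
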