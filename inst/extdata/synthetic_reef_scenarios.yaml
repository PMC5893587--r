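- species_id: big_snapper
  family: snapper
  max_length_mm: 800.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: exponential
    start: 0.2
    net_change: -0.1
    hump: 0.1
    rate: 3.0
  size_path:
    form: linear
    start: 520.0
    net_change: -120.0
    hump: 120.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: small_snapper
  family: snapper
  max_length_mm: 350.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.1
    net_change: 0.1
    hump: -0.1
    rate: 3.0
  size_path:
    form: constant
    start: 240.0
    net_change: 0.0
    hump: 120.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: mid_snapper
  family: snapper
  max_length_mm: 550.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.08
    net_change: 0.0
    hump: 0.04
    rate: 3.0
  size_path:
    form: linear
    start: 380.0
    net_change: -40.0
    hump: 40.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: big_grouper
  family: grouper
  max_length_mm: 900.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.15
    net_change: -0.08
    hump: 0.08
    rate: 3.0
  size_path:
    form: linear
    start: 600.0
    net_change: -80.0
    hump: 80.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: small_grouper
  family: grouper
  max_length_mm: 300.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.08
    net_change: 0.06
    hump: -0.06
    rate: 3.0
  size_path:
    form: constant
    start: 220.0
    net_change: 0.0
    hump: 110.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: mid_grouper
  family: grouper
  max_length_mm: 500.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: constant
    start: 0.07
    net_change: 0.0
    hump: 0.035
    rate: 3.0
  size_path:
    form: constant
    start: 350.0
    net_change: 0.0
    hump: 175.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: big_emperor
  family: emperor
  max_length_mm: 600.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: constant
    start: 0.12
    net_change: 0.0
    hump: 0.06
    rate: 3.0
  size_path:
    form: humped
    start: 400.0
    net_change: -60.0
    hump: 60.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: small_emperor
  family: emperor
  max_length_mm: 300.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.08
    net_change: 0.02
    hump: -0.02
    rate: 3.0
  size_path:
    form: linear
    start: 230.0
    net_change: 0.0
    hump: 115.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: mid_emperor
  family: emperor
  max_length_mm: 450.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: constant
    start: 0.05
    net_change: 0.0
    hump: 0.025
    rate: 3.0
  size_path:
    form: constant
    start: 330.0
    net_change: 0.0
    hump: 165.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: goatfish_sp
  family: goatfish
  max_length_mm: 400.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: constant
    start: 0.05
    net_change: 0.0
    hump: 0.025
    rate: 3.0
  size_path:
    form: linear
    start: 280.0
    net_change: -30.0
    hump: 30.0
    rate: 3.0
  length_cv: 0.12
  iconic: no
  lw_source_tier: 1
  sectors: ~
- species_id: giant_jack
  family: jack
  max_length_mm: 1600.0
  lw_a: 2.0e-08
  lw_b: 3.0
  contribution_path:
    form: linear
    start: 0.02
    net_change: 0.01
    hump: -0.01
    rate: 3.0
  size_path:
    form: constant
    start: 900.0
    net_change: 0.0
    hump: 450.0
    rate: 3.0
  length_cv: 0.12
  iconic: yes
  lw_source_tier: 1
  sectors: ~
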