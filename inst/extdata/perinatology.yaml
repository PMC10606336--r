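units:
- id: O3
  name: Delivery room
  beds: 6.0
  external_rate: 4.0
  service_rate: 1.0
  nurses:
    day: 3.0
    evening: 3.0
    night: 3.0
  team: obstetrics
- id: N1
  name: Neonatal IC unit
  beds: 14.0
  external_rate: 0.6
  service_rate: 0.1
  nurses:
    day: 12.0
    evening: 7.0
    night: 8.0
  team: neonatology
- id: N2
  name: Neonatal post-IC unit
  beds: 4.0
  external_rate: 0.0
  service_rate: 0.06
  nurses:
    day: 2.0
    evening: 2.0
    night: 2.0
  team: neonatology
- id: N3
  name: Neonatal HC/MC unit
  beds: 11.0
  external_rate: 0.4
  service_rate: 0.19
  nurses:
    day: 4.0
    evening: 2.0
    night: 2.0
  team: neonatology
- id: O1
  name: Nursery wards
  beds: 7.0
  external_rate: 0.0
  service_rate: 0.91
  nurses:
    day: 1.0
    evening: 1.0
    night: 1.0
  team: obstetrics
routing:
- from: O3
  to: N1
  p: 0.158
- from: N1
  to: N2
  p: 0.162337662337662
- from: O3
  to: N3
  p: 0.157
- from: O3
  to: O1
  p: 0.685
pooling_models:
  Model 1:
    groups:
      O3: O3
      N1: N1
      N2: N2
      N3: N3
      O1: O1
  Model 2:
    groups:
      O3: O3
      N1: N1
      N2: N2
      N3+O1:
      - N3
      - O1
    team:
      N3+O1: neonatology
  Model 3:
    groups:
      O3: O3
      N1: N1
      N2+N3:
      - N2
      - N3
      O1: O1
    team:
      N2+N3: neonatology
  Model 4:
    groups:
      O3: O3
      N1: N1
      N2+O1:
      - N2
      - O1
      N3: N3
    team:
      N2+O1: neonatology
simulation:
  horizon_days: 365
  seed: 1
  routing: sampled
strategies:
- hierarchy
- network
- hub
aggregated:
- yes
- no
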