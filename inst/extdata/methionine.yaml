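metabolites:
- id: Met
- id: AdoMet
- id: AdoHcy
- id: Hcy
- id: MTHF
- id: CH2THF
- id: MGA
  external: yes
- id: MGACH3
  external: yes
- id: Ade
  external: yes
- id: Bet
  external: yes
- id: DMG
  external: yes
- id: Cysta
  external: yes
reactions:
- id: MATI
  stoichiometry:
    Met: -1.0
    AdoMet: 1.0
  mechanism:
    kind: ordered
    bind:
    - Met
    release:
    - AdoMet
  allosteric:
    'n': 2
    activators: []
    inhibitors:
    - AdoMet
- id: MATIII
  stoichiometry:
    Met: -1.0
    AdoMet: 1.0
  mechanism:
    kind: ordered
    bind:
    - Met
    release:
    - AdoMet
  allosteric:
    'n': 2
    activators:
    - AdoMet
    inhibitors: []
- id: GNMT
  stoichiometry:
    AdoMet: -1.0
    AdoHcy: 1.0
  mechanism:
    kind: ordered
    bind:
    - AdoMet
    release:
    - AdoHcy
  allosteric:
    'n': 4
    activators: []
    inhibitors:
    - MTHF
- id: METH
  stoichiometry:
    AdoMet: -1.0
    AdoHcy: 1.0
    MGA: -1.0
    MGACH3: 1.0
  mechanism:
    kind: ordered
    bind:
    - AdoMet
    - MGA
    release:
    - - AdoHcy
      - MGACH3
- id: AHC
  stoichiometry:
    AdoHcy: -1.0
    Hcy: 1.0
    Ade: 1.0
  mechanism:
    kind: ordered
    bind:
    - AdoHcy
    release:
    - Ade
    - Hcy
- id: BHMT
  stoichiometry:
    Met: 1.0
    Hcy: -1.0
    Bet: -1.0
    DMG: 1.0
  mechanism:
    kind: ordered
    bind:
    - Hcy
    - Bet
    release:
    - - DMG
      - Met
- id: MS
  stoichiometry:
    Met: 1.0
    Hcy: -1.0
    MTHF: -1.0
    CH2THF: 1.0
  mechanism:
    kind: ordered
    bind:
    - MTHF
    - Hcy
    release:
    - - Met
      - CH2THF
- id: MTHFR
  stoichiometry:
    MTHF: 1.0
    CH2THF: -1.0
  mechanism:
    kind: ordered
    bind:
    - CH2THF
    release:
    - MTHF
  allosteric:
    'n': 2
    activators: []
    inhibitors:
    - AdoMet
- id: CBS
  stoichiometry:
    Hcy: -1.0
    Cysta: 1.0
  mechanism:
    kind: ordered
    bind:
    - Hcy
    release:
    - Cysta
  allosteric:
    'n': 2
    activators:
    - AdoMet
    inhibitors: []
boundary:
- id: INFLUX
  stoichiometry:
    Met: 1.0
  v_ref: 0.76
- id: PROT
  stoichiometry:
    Met: -1.0
  v_ref: 0.12
pools:
- members:
  - MTHF
  - CH2THF
  total: 0.003
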