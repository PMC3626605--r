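schema: polySI/1
alpha_level: 0.05
parents:
  - name: Dabai
    species: Pps
    haplotypes:
      - label: S1
      - label: S2
      - label: S5
      - label: S8
  - name: Taishanganying
    species: Pps
    haplotypes:
      - label: S1
      - label: S2
      - label: S4
      - label: S6
  - name: Summit
    species: Pa
    haplotypes:
      - label: S1
      - label: S2
crosses:
  # si_enabled false gives the unfiltered theoretical class ratios the
  # observed tables are tested against (all pollen classes transmitted).
  - name: dabai_self
    seed_parent: Dabai
    pollen_parent: Dabai
    si_enabled: false
  - name: taishanganying_self
    seed_parent: Taishanganying
    pollen_parent: Taishanganying
    si_enabled: false
  - name: summit_x_dabai
    seed_parent: Summit
    pollen_parent: Dabai
    si_enabled: false
  - name: summit_x_taishanganying
    seed_parent: Summit
    pollen_parent: Taishanganying
    si_enabled: false
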