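# Minimal search-space example: one protein, optional phosphorylation,
# homodimer stoichiometry.
proteins:
  - id: EXMP
    sequence: AKGLSETVDFIRKNGAVTLESK
    mods:
      - {name: phospho, max: 1}
stoichiometry:
  min: 2
  max: 2
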