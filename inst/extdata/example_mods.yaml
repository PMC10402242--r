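# Example user-extension of the modification registry (loadModConfig).
- name: succinyl
  gain: C4H4O3
  targets: [K]
- name: my-custom-tag
  mono_mass: 229.16293
  targets: [K, N-term]
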