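# Polystyrene size-standard reference set (diameters nm, RI at 405 nm)
channel: VSSC_H
beads:
  - {label: "60",  diameter: 60,  ri: 1.61}
  - {label: "80",  diameter: 80,  ri: 1.61}
  - {label: "101", diameter: 101, ri: 1.61}
  - {label: "125", diameter: 125, ri: 1.61}
  - {label: "151", diameter: 151, ri: 1.61}
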