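# Transmembrane segment definitions for bovine rhodopsin (author numbering,
# inclusive ranges; chain "*" expands to every chain of a structure).
# The middle segments TM5m (207-215, the pi-helical stretch) and TM7m
# (294-301, the 3/10 stretch around the retinal anchor Lys296) are fixed by
# the analysis they support; note that some figure renderings of the same
# segments use 208-215 and 293-300 — we deliberately keep the body ranges.
# All other boundaries are sensible defaults and user-editable.
segments:
  - {name: TM1e, chain: "*", start: 35,  end: 49}
  - {name: TM1c, chain: "*", start: 50,  end: 64}
  - {name: TM2c, chain: "*", start: 71,  end: 85}
  - {name: TM2e, chain: "*", start: 86,  end: 100}
  - {name: TM3e, chain: "*", start: 107, end: 123}
  - {name: TM3c, chain: "*", start: 124, end: 139}
  - {name: TM4c, chain: "*", start: 151, end: 162}
  - {name: TM4e, chain: "*", start: 163, end: 173}
  - {name: TM5e, chain: "*", start: 200, end: 206}
  - {name: TM5m, chain: "*", start: 207, end: 215}
  - {name: TM5c, chain: "*", start: 216, end: 225}
  - {name: TM6c, chain: "*", start: 247, end: 261}
  - {name: TM6e, chain: "*", start: 262, end: 276}
  - {name: TM7e, chain: "*", start: 286, end: 293}
  - {name: TM7m, chain: "*", start: 294, end: 301}
  - {name: TM7c, chain: "*", start: 302, end: 309}
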