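# Domain intervals for the package's synthetic stand-in constructs
# (1-based, inclusive). SYN_ADAMTS8 mimics an ADAMTS-family layout with the
# spacer (Sp) domain at 690-831; SYN_OPN_B mimics osteopontin isoform b.
SYN_ADAMTS8:
  - {name: Pro, start: 30, end: 350}
  - {name: Mp, start: 351, end: 440}
  - {name: Dis, start: 441, end: 500}
  - {name: TSR, start: 510, end: 575}
  - {name: CR, start: 580, end: 640}
  - {name: Sp, start: 690, end: 831}
SYN_OPN_B:
  - {name: AD, start: 75, end: 86}
  - {name: RGD, start: 128, end: 130}
  - {name: SVVYGLR, start: 131, end: 137}
  - {name: CBD, start: 207, end: 220}
  - {name: HBD, start: 280, end: 296}
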