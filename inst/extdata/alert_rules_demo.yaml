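# Demonstration structural-alert rule set: reactive / assay-interfering /
# promiscuity-prone motifs in the style of medicinal-chemistry triage rules.
# kind: reject  -> any match eliminates the compound
# kind: demerit -> matches accumulate points; compounds over the engine's
#                  threshold (default 100) are eliminated
name: demo-alerts
version: 0.1.0
rules:
  - name: quinone
    smarts: "O=C1C=CC(=O)C=C1"
    kind: reject
  - name: acyl_halide
    smarts: "C(=O)[Cl,Br,I]"
    kind: reject
  - name: michael_acceptor_enone
    smarts: "C=CC(=O)[#6]"
    kind: demerit
    points: 60
  - name: aldehyde
    smarts: "[CX3H1](=O)[#6]"
    kind: demerit
    points: 50
  - name: nitro_aromatic
    smarts: "[cX3][N+](=O)[O-]"
    kind: demerit
    points: 60
  - name: nitro_aliphatic
    smarts: "[CX4][N+](=O)[O-]"
    kind: demerit
    points: 40
  - name: isocyanate
    smarts: "N=C=O"
    kind: reject
  - name: epoxide_aziridine
    smarts: "[C;r3]1[O,N;r3][C;r3]1"
    kind: demerit
    points: 80
  - name: hydrazine
    smarts: "[NX3][NX3]"
    kind: demerit
    points: 50
  - name: thiol
    smarts: "[SX2H]"
    kind: demerit
    points: 40
  - name: perfluoroalkyl
    smarts: "C(F)(F)C(F)(F)C(F)F"
    kind: demerit
    points: 60
  - name: polyene_chain
    smarts: "C=CC=CC=C"
    kind: demerit
    points: 40
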