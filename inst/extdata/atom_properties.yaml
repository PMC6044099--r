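# Atomic property tables used on the Burden-matrix diagonal and in the
# simple-property block. Versioned so an alternative scheme can be swapped in.
name: default
version: 0.1.0
electronegativity:       # Pauling scale, per element
  "H": 2.20
  "B": 2.04
  "C": 2.55
  "N": 3.04
  "O": 3.44
  "F": 3.98
  "Si": 1.90
  "P": 2.19
  "S": 2.58
  "Cl": 3.16
  "Se": 2.55
  "Br": 2.96
  "I": 2.66
electronegativity_fallback: 2.00
# Simplified atomic lipophilicity increments (logP contributions), keyed by
# Sybyl atom type. A coarse Wildman--Crippen-style scheme: hydrogens are
# implicit, so each value absorbs the attached-hydrogen contribution.
lipophilicity:
  "C.3": 0.14
  "C.2": 0.11
  "C.1": 0.13
  "C.ar": 0.29
  "C.cat": 0.20
  "N.4": -1.95
  "N.3": -0.96
  "N.2": -0.49
  "N.1": -0.23
  "N.ar": -0.44
  "N.am": -0.60
  "N.pl3": -0.82
  "O.3": -0.36
  "O.2": -0.12
  "O.co2": -0.63
  "F": 0.42
  "Cl": 0.69
  "Br": 0.85
  "I": 0.89
  "S.3": 0.60
  "S.2": 0.50
  "S.o": -0.70
  "S.o2": -0.70
  "P.3": 0.86
lipophilicity_fallback: 0.0
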